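## Row-wise Welch t-tests. Returns per-row mean difference (group1 - group2),
## t statistic, Welch-Satterthwaite df and two-sided (or one-sided) p. Rows
## with zero variance in both groups and equal means get p = 1; zero variance
## with unequal means gives p = 0.
.welch_rows <- function(m, idx1, idx2, alternative = "two.sided") {
    n1 <- length(idx1); n2 <- length(idx2)
    if (n1 < 2L || n2 < 2L)
        stop("analysis error: each group needs at least 2 samples")
    x1 <- m[, idx1, drop = FALSE]; x2 <- m[, idx2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    diff <- m1 - m2
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    degenerate <- se2 == 0
    tstat[degenerate & diff == 0] <- 0
    df[degenerate] <- n1 + n2 - 2
    p <- switch(alternative,
        two.sided = 2 * stats::pt(-abs(tstat), df),
        less = stats::pt(tstat, df),
        greater = stats::pt(tstat, df, lower.tail = FALSE),
        stop("unknown alternative"))
    p[degenerate & diff == 0] <- 1
    p[degenerate & diff != 0] <- if (alternative == "two.sided") 0 else NA
    if (alternative != "two.sided") {
        onesided_sign <- if (alternative == "less") -1 else 1
        p[degenerate & diff != 0] <-
            ifelse(sign(diff[degenerate & diff != 0]) == onesided_sign, 0, 1)
    }
    data.frame(diff = diff, t = tstat, df = df, p = pmin(p, 1),
               row.names = rownames(m))
}

.group_idx <- function(sample_ids, groups) {
    g <- groups[sample_ids]
    list(h = which(g == "CIMP-H"), n = which(g == "Non-CIMP"))
}

#' Differential promoter methylation
#'
#' Per gene, the difference of group-mean promoter-average betas
#' (\eqn{\Delta\beta} = mean CIMP-H minus mean Non-CIMP) with a two-sided
#' Welch t-test p-value.
#'
#' @param promoter_avg promoter-average beta matrix (genes x samples).
#' @param groups named character vector sample -> "CIMP-H"/"Non-CIMP"; samples
#'   with other labels are excluded.
#' @return data.frame with \code{gene}, \code{delta_beta}, \code{p}.
#' @export
diffMethylation <- function(promoter_avg, groups) {
    idx <- .group_idx(colnames(promoter_avg), groups)
    w <- .welch_rows(promoter_avg, idx$h, idx$n)
    data.frame(gene = rownames(promoter_avg), delta_beta = w$diff, p = w$p,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression on log2-CPM
#'
#' Per gene, the log2 fold change defined as the difference of group-mean
#' log2-CPM (CIMP-H minus Non-CIMP) with a two-sided Welch t-test p-value.
#'
#' @param log2cpm normalized expression matrix (genes x samples).
#' @param groups named character vector sample -> "CIMP-H"/"Non-CIMP".
#' @return data.frame with \code{gene}, \code{log2fc}, \code{p}.
#' @export
diffExpression <- function(log2cpm, groups) {
    idx <- .group_idx(colnames(log2cpm), groups)
    w <- .welch_rows(log2cpm, idx$h, idx$n)
    data.frame(gene = rownames(log2cpm), log2fc = w$diff, p = w$p,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: with p-values sorted ascending,
#' \code{adj[i] = min over j >= i of m * p[j] / j}, capped at 1, returned in
#' the original input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (\code{NA} allowed and
#'   propagated; missing values are excluded from the multiplicity m).
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
    ok <- !is.na(pvals)
    p <- pvals[ok]
    if (any(p < 0 | p > 1))
        stop("validation error: p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(pvals))
    m <- length(p)
    if (m) {
        o <- order(p, decreasing = TRUE)
        ro <- order(o)
        adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
        out[ok] <- adj
    }
    out
}

#' Five-way methylation-expression classification
#'
#' A gene falls in a significant category only when both BH-adjusted p-values
#' are below \code{alpha} and both effect sizes clear their thresholds
#' (\eqn{|\Delta\beta| \ge} \code{delta_beta_min},
#' \eqn{|log_2FC| \ge} \code{abs_log2fc_min}); the sign pattern then selects
#' hyper-down, hyper-up, hypo-down or hypo-up. All other genes are
#' not-significant.
#'
#' @param delta_beta,log2fc effect sizes per gene.
#' @param meth_adj_p,expr_adj_p BH-adjusted p-values per gene.
#' @param cfg an [analysisConfig()].
#' @return character vector of categories.
#' @export
classifyGenes <- function(delta_beta, log2fc, meth_adj_p, expr_adj_p,
                          cfg = analysisConfig()) {
    sig <- !is.na(meth_adj_p) & !is.na(expr_adj_p) &
        meth_adj_p < cfg$alpha & expr_adj_p < cfg$alpha &
        abs(delta_beta) >= cfg$delta_beta_min &
        abs(log2fc) >= cfg$abs_log2fc_min
    cat <- rep("not-significant", length(delta_beta))
    cat[sig & delta_beta > 0 & log2fc < 0] <- "hyper-down"
    cat[sig & delta_beta > 0 & log2fc > 0] <- "hyper-up"
    cat[sig & delta_beta < 0 & log2fc < 0] <- "hypo-down"
    cat[sig & delta_beta < 0 & log2fc > 0] <- "hypo-up"
    cat
}

#' Integrated differential methylation and expression
#'
#' Runs [diffMethylation()] and [diffExpression()] on the genes common to both
#' matrices, applies BH adjustment separately within each analysis across all
#' tested genes, and classifies every gene with [classifyGenes()].
#'
#' @param promoter_avg promoter-average beta matrix (genes x samples).
#' @param log2cpm normalized expression matrix (genes x samples).
#' @param groups named character vector sample -> CIMP label.
#' @param cfg an [analysisConfig()].
#' @return data.frame with one row per gene: \code{gene}, \code{delta_beta},
#'   \code{meth_p}, \code{meth_adj_p}, \code{log2fc}, \code{expr_p},
#'   \code{expr_adj_p}, \code{category}.
#' @export
runDifferential <- function(promoter_avg, log2cpm, groups,
                            cfg = analysisConfig()) {
    genes <- intersect(rownames(promoter_avg), rownames(log2cpm))
    if (!length(genes)) stop("no genes shared between methylation and expression")
    dm <- diffMethylation(promoter_avg[genes, , drop = FALSE], groups)
    de <- diffExpression(log2cpm[genes, , drop = FALSE], groups)
    rec <- data.frame(gene = genes,
                      delta_beta = dm$delta_beta,
                      meth_p = dm$p,
                      meth_adj_p = bhAdjust(dm$p),
                      log2fc = de$log2fc,
                      expr_p = de$p,
                      expr_adj_p = bhAdjust(de$p),
                      stringsAsFactors = FALSE)
    rec$category <- classifyGenes(rec$delta_beta, rec$log2fc,
                                  rec$meth_adj_p, rec$expr_adj_p, cfg)
    rec
}
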