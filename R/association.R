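#' Tie-aware Spearman correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks, with the p-value from
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom
#' (two-sided); \eqn{|\rho| = 1} gives p = 0.
#'
#' @param x,y numeric vectors of equal length, n >= 5, no missing values.
#' @return list with \code{rho} and \code{p}; both \code{NA} when either
#'   vector has zero variance.
#' @export
spearmanRho <- function(x, y) {
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (n < 5L) stop("spearmanRho requires n >= 5")
    if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        return(list(rho = NA_real_, p = NA_real_))
    rho <- stats::cor(rank(x), rank(y))
    if (abs(rho) >= 1) return(list(rho = sign(rho), p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

## Fisher's combination of k independent p-values: -2 sum(log p) ~ chisq(2k).
.fisher_combine <- function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    p <- pmax(p, .Machine$double.xmin)
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Ordinary least squares promoter regression
#'
#' Fits expression on promoter methylation predictors with an intercept.
#' Rank-deficient predictor sets are reduced to an independent column basis
#' (\code{k_eff} = effective rank). Returns the adjusted R-squared
#' \eqn{1 - (1-R^2)(n-1)/(n-k_{eff}-1)} and the overall model p-value from
#' the F statistic \eqn{(R^2/k_{eff}) / ((1-R^2)/(n-k_{eff}-1))}. A perfect
#' fit reports p = 0.
#'
#' @param predictors numeric matrix (samples x k), finite columns.
#' @param response numeric vector of expression values (log2-CPM).
#' @return list with \code{adj_r2}, \code{model_p}, \code{k_eff}, \code{r2}
#'   and \code{status} (\code{"ok"}, \code{"underdetermined"} when
#'   \code{k >= n - 2}, \code{"insufficient_df"} with fewer than 3 residual
#'   degrees of freedom, or \code{"degenerate"} when no predictor varies).
#' @export
fitPromoterRegression <- function(predictors, response) {
    X <- as.matrix(predictors)
    y <- as.numeric(response)
    n <- length(y)
    if (nrow(X) != n) stop("predictor rows must match response length")
    if (!all(is.finite(X))) stop("predictors must be finite")
    if (stats::var(y) == 0) stop("zero-variance response")
    k <- ncol(X)
    na_out <- list(adj_r2 = NA_real_, model_p = NA_real_,
                   k_eff = NA_integer_, r2 = NA_real_)
    if (n < k + 3L) return(c(na_out, status = "underdetermined"))
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    k_eff <- fit$rank - 1L
    if (k_eff < 1L) return(c(na_out, status = "degenerate"))
    df_res <- n - k_eff - 1L
    if (df_res < 3L) return(c(na_out, status = "insufficient_df"))
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
    if (rss <= tss * .Machine$double.eps^0.9) {
        model_p <- 0
    } else {
        fstat <- (r2 / k_eff) / ((1 - r2) / df_res)
        model_p <- stats::pf(fstat, k_eff, df_res, lower.tail = FALSE)
    }
    list(adj_r2 = adj_r2, model_p = model_p, k_eff = k_eff, r2 = r2,
         status = "ok")
}

.method_family <- function(method) {
    ifelse(grepl("^spearman", method), "spearman", "regression")
}

.assoc_methods <- c("spearman-single", "spearman-average", "spearman-ratio",
                    "regression-single", "regression-average",
                    "regression-ratio")

#' Score methylation-expression association for a gene set
#'
#' Computes, for each candidate gene and requested method, the association
#' between promoter methylation and expression across the CIMP-H and Non-CIMP
#' samples:
#' \describe{
#'   \item{spearman-single}{Spearman rho of each promoter CpG's beta against
#'     the gene's log2-CPM; the score is the mean of the signed rhos and the
#'     p-value Fisher's combination of the per-CpG p-values (promoter CpGs are
#'     correlated, so this combination is anti-conservative; it is reported as
#'     method metadata).}
#'   \item{spearman-average / spearman-ratio}{Spearman rho of the promoter
#'     average / methylated-CpG ratio summary against log2-CPM.}
#'   \item{regression-single}{adjusted R-squared of OLS with all promoter CpG
#'     betas as predictors.}
#'   \item{regression-average / regression-ratio}{adjusted R-squared with the
#'     single summary column as predictor.}
#' }
#' Adjusted p-values are BH across genes within each method (for regression
#' methods the BH-adjusted model p is reported alongside, though selection
#' uses the raw model p).
#'
#' @param betas filtered beta matrix (probes x samples).
#' @param map promoter map ([buildPromoterMap()]).
#' @param log2cpm normalized expression matrix.
#' @param groups named character vector sample -> CIMP label; scoring is
#'   restricted to CIMP-H and Non-CIMP samples.
#' @param genes candidate genes (typically the significant differential
#'   categories); defaults to all mapped genes with expression.
#' @param methods subset of the six method names.
#' @param cfg an [analysisConfig()] (methylated-CpG cutoff for the ratio).
#' @return data.frame with \code{gene}, \code{method}, \code{score}, \code{p},
#'   \code{adj_p}, \code{n_cpgs}, \code{n_samples}, \code{status}.
#' @export
scoreAssociations <- function(betas, map, log2cpm, groups, genes = NULL,
                              methods = .assoc_methods,
                              cfg = analysisConfig()) {
    methods <- match.arg(methods, .assoc_methods, several.ok = TRUE)
    use <- colnames(log2cpm)[groups[colnames(log2cpm)] %in%
                             c("CIMP-H", "Non-CIMP")]
    use <- intersect(use, colnames(betas))
    if (length(use) < 5L) stop("fewer than 5 usable samples")
    if (is.null(genes)) genes <- intersect(names(map), rownames(log2cpm))
    genes <- intersect(genes, intersect(names(map), rownames(log2cpm)))
    if (!length(genes))
        return(data.frame(gene = character(), method = character(),
                          score = numeric(), p = numeric(), adj_p = numeric(),
                          n_cpgs = integer(), n_samples = integer(),
                          status = character(), stringsAsFactors = FALSE))
    b <- betas[, use, drop = FALSE]
    e <- log2cpm[genes, use, drop = FALSE]
    avg <- summarizePromoter(b, map[genes], "average")
    rat <- summarizePromoter(b, map[genes], "ratio",
                             beta_min = cfg$meth_cpg_beta_min)
    rows <- vector("list", length(genes) * length(methods))
    ri <- 0L
    for (g in genes) {
        probes <- map[[g]]
        y <- e[g, ]
        for (meth in methods) {
            ri <- ri + 1L
            score <- NA_real_; p <- NA_real_; status <- "ok"
            if (meth == "spearman-single") {
                per <- lapply(probes, function(pr) spearmanRho(b[pr, ], y))
                rhos <- vapply(per, `[[`, numeric(1L), "rho")
                if (all(is.na(rhos))) status <- "degenerate"
                else {
                    score <- mean(rhos, na.rm = TRUE)
                    p <- .fisher_combine(vapply(per, `[[`, numeric(1L), "p"))
                }
            } else if (meth %in% c("spearman-average", "spearman-ratio")) {
                xv <- if (meth == "spearman-average") avg[g, ] else rat[g, ]
                sr <- spearmanRho(xv, y)
                if (is.na(sr$rho)) status <- "degenerate"
                score <- sr$rho; p <- sr$p
            } else {
                X <- switch(meth,
                    `regression-single` = t(b[probes, , drop = FALSE]),
                    `regression-average` = matrix(avg[g, ], ncol = 1L),
                    `regression-ratio` = matrix(rat[g, ], ncol = 1L))
                fit <- fitPromoterRegression(X, y)
                status <- fit$status
                if (status == "ok") { score <- fit$adj_r2; p <- fit$model_p }
            }
            rows[[ri]] <- data.frame(
                gene = g, method = meth, score = score, p = p,
                n_cpgs = length(probes), n_samples = length(use),
                status = status, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$adj_p <- NA_real_
    for (meth in methods) {
        i <- out$method == meth
        out$adj_p[i] <- bhAdjust(out$p[i])
    }
    out[, c("gene", "method", "score", "p", "adj_p", "n_cpgs", "n_samples",
            "status")]
}

#' Select and rank scored genes
#'
#' Spearman methods select genes with \eqn{|\rho|} strictly above
#' \code{spearman_abs_min} and BH-adjusted p below \code{alpha}; regression
#' methods select genes with adjusted R-squared strictly above
#' \code{adj_r2_min} and raw model p below \code{alpha}. Selected genes are
#' ranked per method by descending \eqn{|\rho|} (Spearman) or adjusted
#' R-squared (regression), ties broken lexicographically by gene symbol.
#'
#' @param scores table from [scoreAssociations()].
#' @param cfg an [analysisConfig()].
#' @return \code{scores} with added logical \code{selected} and integer
#'   \code{rank} (\code{NA} for unselected genes).
#' @export
selectGenes <- function(scores, cfg = analysisConfig()) {
    fam <- .method_family(scores$method)
    sel <- ifelse(fam == "spearman",
        !is.na(scores$score) & abs(scores$score) > cfg$spearman_abs_min &
            !is.na(scores$adj_p) & scores$adj_p < cfg$alpha,
        !is.na(scores$score) & scores$score > cfg$adj_r2_min &
            !is.na(scores$p) & scores$p < cfg$alpha)
    scores$selected <- sel
    scores$rank <- NA_integer_
    for (meth in unique(scores$method)) {
        i <- which(scores$method == meth & sel)
        if (!length(i)) next
        key <- if (.method_family(meth) == "spearman")
            abs(scores$score[i]) else scores$score[i]
        scores$rank[i][order(-key, scores$gene[i])] <- seq_along(i)
    }
    scores
}

#' Compare scoring methods within each family
#'
#' For the Spearman family (on \eqn{|\rho|}) and the regression family (on
#' adjusted R-squared): a Kruskal-Wallis test across the three score
#' distributions over the genes scored by every method in the family; per-gene
#' argmax counts, crediting every method tied at the maximum; and the
#' selected-gene overlap as a gene x method membership matrix.
#'
#' @param scores table from [selectGenes()] (must carry \code{selected}).
#' @return list with one element per family, each holding \code{kw_statistic},
#'   \code{kw_p}, \code{argmax_counts}, \code{n_genes}, \code{overlap}
#'   (logical gene x method matrix over genes selected by any method) and
#'   \code{selected_sets}.
#' @export
compareMethods <- function(scores) {
    if (!"selected" %in% names(scores))
        scores <- selectGenes(scores)
    out <- list()
    for (family in c("spearman", "regression")) {
        sc <- scores[.method_family(scores$method) == family, , drop = FALSE]
        meths <- sort(unique(sc$method))
        if (length(meths) < 2L) next
        wide <- stats::reshape(
            sc[, c("gene", "method", "score")], idvar = "gene",
            timevar = "method", direction = "wide")
        val <- as.matrix(wide[, -1L, drop = FALSE])
        colnames(val) <- sub("^score\\.", "", colnames(val))
        val <- val[, meths, drop = FALSE]
        complete <- stats::complete.cases(val)
        if (!any(complete)) stop("no gene scored by every ", family, " method")
        cmp_val <- val[complete, , drop = FALSE]
        if (family == "spearman") cmp_val <- abs(cmp_val)
        kw <- stats::kruskal.test(
            x = as.vector(cmp_val),
            g = factor(rep(meths, each = nrow(cmp_val))))
        argmax <- colSums(cmp_val == apply(cmp_val, 1L, max))
        sel_sets <- lapply(meths, function(m)
            sort(sc$gene[sc$method == m & sc$selected]))
        names(sel_sets) <- meths
        union_genes <- sort(unique(unlist(sel_sets)))
        overlap <- vapply(sel_sets, function(s) union_genes %in% s,
                          logical(length(union_genes)))
        if (length(union_genes) == 1L)
            overlap <- matrix(overlap, nrow = 1L,
                              dimnames = list(union_genes, meths))
        else rownames(overlap) <- union_genes
        out[[family]] <- list(
            kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
            argmax_counts = argmax, n_genes = nrow(cmp_val),
            overlap = overlap, selected_sets = sel_sets)
    }
    out
}
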