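#' Epigenetic silencing calls and the perc.diff consistency metric
#'
#' Implements an external study's silencing definition. Per gene, expression
#' is standardized to z-scores over all samples. A promoter probe is silenced
#' when (i) its beta exceeds 0.3 (strict) in at least
#' \code{silencing_sample_frac} of the samples, (ii) the mean expression
#' z-score of those methylated samples is below \code{silencing_z_max}, and
#' (iii) a one-sided Welch test (methylated group expression lower) survives
#' BH adjustment across all tested probes at \code{silencing_alpha}. A gene is
#' silenced when a strict majority of its promoter probes are. A sample is
#' silenced for a silenced gene when more than half of that gene's promoter
#' probes have beta > 0.3 in the sample. The consistency metric
#' \code{perc_diff} is the percentage of CIMP-H samples silenced minus the
#' percentage of Non-CIMP samples silenced.
#'
#' @param betas filtered beta matrix (probes x samples).
#' @param map promoter map ([buildPromoterMap()]).
#' @param log2cpm normalized expression matrix.
#' @param groups named character vector sample -> CIMP label; calls use all
#'   CIMP-H and Non-CIMP samples.
#' @param cfg an [analysisConfig()].
#' @param beta_cut methylated-sample beta cutoff (strict inequality).
#' @return data.frame with one row per gene: \code{gene}, \code{n_probes},
#'   \code{n_probes_silenced}, \code{gene_silenced}, \code{pct_cimp_h},
#'   \code{pct_non_cimp}, \code{perc_diff}.
#' @export
silencingCalls <- function(betas, map, log2cpm, groups,
                           cfg = analysisConfig(), beta_cut = 0.3) {
    use <- colnames(log2cpm)[groups[colnames(log2cpm)] %in%
                             c("CIMP-H", "Non-CIMP")]
    use <- intersect(use, colnames(betas))
    if (length(use) < 10L) stop("silencing calls require >= 10 samples")
    genes <- intersect(names(map), rownames(log2cpm))
    b <- betas[, use, drop = FALSE]
    e <- log2cpm[genes, use, drop = FALSE]
    z <- t(scale(t(e)))
    n <- length(use)
    min_meth <- ceiling(cfg$silencing_sample_frac * n)

    ## probe-level statistics across all genes, then one global BH pass
    probe_tab <- do.call(rbind, lapply(genes, function(g) {
        probes <- map[[g]]
        data.frame(gene = g, probe = probes, stringsAsFactors = FALSE)
    }))
    meth_mat <- b[probe_tab$probe, , drop = FALSE] > beta_cut
    n_meth <- rowSums(meth_mat)
    mean_z <- rep(NA_real_, nrow(probe_tab))
    p_raw <- rep(NA_real_, nrow(probe_tab))
    for (i in seq_len(nrow(probe_tab))) {
        ms <- meth_mat[i, ]
        if (n_meth[i] < 1L || n_meth[i] >= n) next  # no contrast
        zg <- z[probe_tab$gene[i], ]
        mean_z[i] <- mean(zg[ms])
        if (n_meth[i] >= 2L && (n - n_meth[i]) >= 2L) {
            eg <- e[probe_tab$gene[i], ]
            w <- .welch_rows(matrix(eg, nrow = 1L), which(ms), which(!ms),
                             alternative = "less")
            p_raw[i] <- w$p
        }
    }
    p_adj <- bhAdjust(p_raw)
    silenced <- !is.na(mean_z) & n_meth >= min_meth &
        mean_z < cfg$silencing_z_max & !is.na(p_adj) &
        p_adj < cfg$silencing_alpha

    grp <- groups[use]
    res <- lapply(genes, function(g) {
        i <- which(probe_tab$gene == g)
        n_probes <- length(i)
        n_sil <- sum(silenced[i])
        gene_sil <- n_sil > n_probes / 2
        if (gene_sil) {
            sample_sil <- colSums(meth_mat[i, , drop = FALSE]) > n_probes / 2
        } else sample_sil <- rep(FALSE, n)
        pct_h <- 100 * mean(sample_sil[grp == "CIMP-H"])
        pct_n <- 100 * mean(sample_sil[grp == "Non-CIMP"])
        data.frame(gene = g, n_probes = n_probes, n_probes_silenced = n_sil,
                   gene_silenced = gene_sil, pct_cimp_h = pct_h,
                   pct_non_cimp = pct_n, perc_diff = pct_h - pct_n,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Upper-quartile consistency of identified genes
#'
#' Compares the perc.diff values of an identified gene set against the
#' overall gene population: reports the population upper quartile (Q3), the
#' fraction of identified genes whose perc.diff is at or above Q3, and
#' five-number summaries of both distributions.
#'
#' @param perc_diffs named numeric vector of perc.diff values for all genes.
#' @param identified character vector of identified genes (subset of the
#'   names of \code{perc_diffs}).
#' @return list with \code{q3}, \code{fraction_at_or_above_q3} (\code{NA} for
#'   an empty identified set), \code{overall_fivenum},
#'   \code{identified_fivenum}, \code{n_overall}, \code{n_identified}.
#' @export
quartileConsistency <- function(perc_diffs, identified) {
    if (!all(identified %in% names(perc_diffs)))
        stop("identified genes must be a subset of the scored population")
    q3 <- unname(stats::quantile(perc_diffs, 0.75))
    idv <- perc_diffs[identified]
    list(q3 = q3,
         fraction_at_or_above_q3 = if (length(idv)) mean(idv >= q3) else NA_real_,
         overall_fivenum = stats::fivenum(perc_diffs),
         identified_fivenum = if (length(idv)) stats::fivenum(idv)
                              else rep(NA_real_, 5L),
         n_overall = length(perc_diffs),
         n_identified = length(idv))
}
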