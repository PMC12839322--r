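#' Analysis configuration
#'
#' All tunable thresholds of the pipeline in one validated list. Defaults are
#' the study settings: promoters are differentially methylated at
#' \eqn{\Delta\beta \ge 0.2}, genes differentially expressed at
#' \eqn{|log_2FC| \ge 1.3} (both with BH-adjusted p < \code{alpha}); a CpG
#' counts as methylated for the ratio summary at beta \eqn{\ge} 0.3; Spearman
#' methods select at \eqn{|\rho| > 0.4} with adjusted p < \code{alpha};
#' regression methods select at adjusted \eqn{R^2 > 0.5} with model p <
#' \code{alpha}; the standardized CIMP-index is thresholded at \eqn{\pm 0.5};
#' the external silencing definition requires beta > 0.3 in at least 1\% of
#' samples, mean expression z-score of the methylated group below \eqn{-1.65}
#' and FDR < 0.001.
#'
#' @param delta_beta_min minimum |group-mean promoter beta difference| for
#'   differential methylation.
#' @param abs_log2fc_min minimum |log2 fold change| for differential
#'   expression (log2-CPM units).
#' @param meth_cpg_beta_min beta cutoff defining a methylated CpG for the
#'   ratio summary (inclusive).
#' @param spearman_abs_min minimum |Spearman rho| for selection (exclusive).
#' @param adj_r2_min minimum adjusted R-squared for selection (exclusive).
#' @param alpha significance level for adjusted (differential, Spearman) and
#'   model (regression) p-values.
#' @param cimp_index_hi,cimp_index_lo standardized CIMP-index thresholds for
#'   CIMP-H (inclusive at \code{hi}) and Non-CIMP (inclusive at \code{lo}).
#' @param silencing_sample_frac minimum fraction of samples methylated for a
#'   probe silencing call.
#' @param silencing_z_max upper bound (exclusive) on the methylated group's
#'   mean expression z-score.
#' @param silencing_alpha FDR level for the probe silencing test.
#' @param rng_seed integer seed recorded for pipeline runs.
#'
#' @return A named list of class \code{"promethyl_config"}.
#' @examples
#' cfg <- analysisConfig(alpha = 0.01)
#' cfg$delta_beta_min
#' @export
analysisConfig <- function(delta_beta_min = 0.2,
                           abs_log2fc_min = 1.3,
                           meth_cpg_beta_min = 0.3,
                           spearman_abs_min = 0.4,
                           adj_r2_min = 0.5,
                           alpha = 0.05,
                           cimp_index_hi = 0.5,
                           cimp_index_lo = -0.5,
                           silencing_sample_frac = 0.01,
                           silencing_z_max = -1.65,
                           silencing_alpha = 0.001,
                           rng_seed = 1L) {
    cfg <- list(delta_beta_min = delta_beta_min,
                abs_log2fc_min = abs_log2fc_min,
                meth_cpg_beta_min = meth_cpg_beta_min,
                spearman_abs_min = spearman_abs_min,
                adj_r2_min = adj_r2_min,
                alpha = alpha,
                cimp_index_hi = cimp_index_hi,
                cimp_index_lo = cimp_index_lo,
                silencing_sample_frac = silencing_sample_frac,
                silencing_z_max = silencing_z_max,
                silencing_alpha = silencing_alpha,
                rng_seed = as.integer(rng_seed))
    probs <- c("meth_cpg_beta_min", "spearman_abs_min", "adj_r2_min",
               "alpha", "silencing_sample_frac", "silencing_alpha")
    for (p in probs) {
        v <- cfg[[p]]
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
            stop("config field '", p, "' must be a single value in (0, 1)")
    }
    if (!cfg$cimp_index_lo < cfg$cimp_index_hi)
        stop("cimp_index_lo must be strictly below cimp_index_hi")
    if (cfg$delta_beta_min < 0 || cfg$abs_log2fc_min < 0)
        stop("effect-size thresholds must be non-negative")
    class(cfg) <- "promethyl_config"
    cfg
}
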