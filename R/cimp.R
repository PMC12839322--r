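#' Compute the per-sample CIMP-index
#'
#' Island-level methylation is the mean beta across all probes mapping to a
#' CpG island; the raw CIMP-index of a sample is the fraction of islands
#' whose mean beta is at least \code{beta_min}. Because the published
#' thresholds (\eqn{\pm 0.5}) apply to a centered index, the raw proportion is
#' standardized across the cohort (sample z-score, ddof = 1; if the cohort has
#' zero spread all standardized indices are 0). Probes without an island
#' assignment are ignored.
#'
#' @param betas beta matrix (probes x samples).
#' @param island_of named character vector mapping probe id -> island id
#'   (\code{NA} for unassigned probes).
#' @param beta_min island mean-beta cutoff.
#' @return data.frame with \code{sample_id}, \code{raw_index},
#'   \code{std_index} and \code{n_islands} (attribute
#'   \code{"ignored_probes"} counts probes without an island).
#' @export
cimpIndex <- function(betas, island_of, beta_min = 0.3) {
    isl <- island_of[rownames(betas)]
    has <- !is.na(isl)
    ignored <- sum(!has)
    if (!any(has)) stop("cimpIndex requires at least one island with a probe")
    b <- betas[has, , drop = FALSE]
    island_mean <- rowsum(b, group = isl[has]) /
        as.vector(table(isl[has])[sort(unique(isl[has]))])
    raw <- colMeans(island_mean >= beta_min)
    s <- stats::sd(raw)
    std <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
    structure(data.frame(sample_id = colnames(betas), raw_index = raw,
                         std_index = std, n_islands = nrow(island_mean),
                         row.names = NULL, stringsAsFactors = FALSE),
              ignored_probes = ignored)
}

#' Assign CIMP classes from the standardized index
#'
#' \code{std_index >= hi} is CIMP-H (boundary inclusive), \code{<= lo} is
#' Non-CIMP (boundary inclusive), anything between is CIMP-L.
#'
#' @param records data.frame from [cimpIndex()].
#' @param hi,lo standardized-index thresholds, \code{lo < hi}.
#' @return \code{records} with an added \code{assigned_class} column.
#' @export
assignCimpClass <- function(records, hi = 0.5, lo = -0.5) {
    if (!lo < hi) stop("lo must be strictly below hi")
    cls <- ifelse(records$std_index >= hi, "CIMP-H",
           ifelse(records$std_index <= lo, "Non-CIMP", "CIMP-L"))
    records$assigned_class <- cls
    records
}
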