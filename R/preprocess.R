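#' Filter methylation probes
#'
#' Removes probes on the sex chromosomes (X, Y), probes overlapping common
#' SNPs, and probes with a missing beta value in at least one sample. A probe
#' failing several criteria is removed once but counted under every reason.
#'
#' @param annot probe annotation \code{DataFrame} (see [readManifest()])
#'   covering every row of \code{betas}.
#' @param betas beta matrix (probes x samples).
#' @return list with \code{betas} (the filtered matrix) and \code{report}, a
#'   data.frame of removal counts per reason (\code{sex_chromosome},
#'   \code{snp_overlap}, \code{missing_values}) plus totals.
#' @export
filterProbes <- function(annot, betas) {
    idx <- match(rownames(betas), annot$probe_id)
    if (anyNA(idx))
        stop("validation error: beta rows without annotation: ",
             paste(utils::head(rownames(betas)[is.na(idx)], 5L),
                   collapse = ", "))
    ann <- annot[idx, , drop = FALSE]
    sex <- ann$chrom %in% c("X", "Y")
    snp <- ann$snp_overlap
    nas <- rowSums(is.na(betas)) > 0L
    drop <- sex | snp | nas
    report <- data.frame(
        reason = c("sex_chromosome", "snp_overlap", "missing_values",
                   "removed_total", "kept"),
        n = c(sum(sex), sum(snp), sum(nas), sum(drop), sum(!drop)),
        stringsAsFactors = FALSE)
    list(betas = betas[!drop, , drop = FALSE], report = report)
}

#' Build the gene-to-promoter-probe map
#'
#' A probe belongs to the promoter of gene G when its manifest annotation for
#' G is TSS1500 or TSS200, or when the probe carries the promoter-associated
#' regulatory flag and lists G among its genes. Only probes in
#' \code{kept_probes} (i.e. surviving [filterProbes()]) are mapped; genes with
#' no surviving promoter probe are absent from the map.
#'
#' @param annot probe annotation \code{DataFrame}.
#' @param kept_probes character vector of probe ids that passed filtering.
#' @param tss_groups promoter-defining TSS annotations; the default unions
#'   TSS1500 and TSS200 to realize "within 1500 bp of a TSS".
#' @return named \code{CharacterList}: gene -> ordered promoter probe ids.
#' @export
buildPromoterMap <- function(annot, kept_probes,
                             tss_groups = c("TSS1500", "TSS200")) {
    stopifnot(all(kept_probes %in% annot$probe_id))
    ann <- annot[match(kept_probes, annot$probe_id), , drop = FALSE]
    glist <- as.list(ann$genes)
    tlist <- as.list(ann$tss_groups)
    pa <- ann$promoter_associated
    probe <- rep(ann$probe_id, lengths(glist))
    gene <- unlist(glist, use.names = FALSE)
    tss <- unlist(tlist, use.names = FALSE)
    in_prom <- rep(pa, lengths(glist)) | tss %in% tss_groups
    keep <- in_prom & !is.na(gene) & nzchar(gene)
    if (!any(keep)) return(IRanges::CharacterList())
    pairs <- unique(data.frame(gene = gene[keep], probe = probe[keep],
                               stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$gene, match(pairs$probe, kept_probes)), ]
    IRanges::CharacterList(split(pairs$probe, pairs$gene))
}

#' Summarize promoter methylation per gene
#'
#' Two promoter-level summaries of the member CpG betas, per sample:
#' \code{"average"} is the arithmetic mean; \code{"ratio"} is the fraction of
#' member CpGs whose beta is at least \code{beta_min} (a CpG with beta exactly
#' at the cutoff counts as methylated).
#'
#' @param betas filtered beta matrix (probes x samples).
#' @param map promoter map from [buildPromoterMap()].
#' @param metric \code{"average"} or \code{"ratio"}.
#' @param beta_min methylated-CpG beta cutoff for the ratio summary.
#' @return numeric matrix (genes x samples) with values in \[0, 1\]; genes
#'   whose probe list is empty or absent from \code{betas} are dropped.
#' @export
summarizePromoter <- function(betas, map, metric = c("average", "ratio"),
                              beta_min = 0.3) {
    metric <- match.arg(metric)
    probes <- as.list(map)
    ok <- lengths(probes) > 0L &
        vapply(probes, function(p) all(p %in% rownames(betas)), logical(1L))
    if (!all(ok)) {
        bad <- names(probes)[!ok]
        missing_probe <- vapply(probes, function(p)
            !all(p %in% rownames(betas)), logical(1L))
        if (any(missing_probe))
            stop("validation error: promoter probes absent from beta matrix ",
                 "for gene(s) ", paste(names(probes)[missing_probe],
                                       collapse = ", "))
        message("summarizePromoter: dropping ", length(bad),
                " gene(s) with empty probe lists")
        probes <- probes[ok]
    }
    out <- matrix(NA_real_, length(probes), ncol(betas),
                  dimnames = list(names(probes), colnames(betas)))
    for (i in seq_along(probes)) {
        b <- betas[probes[[i]], , drop = FALSE]
        out[i, ] <- if (metric == "average") colMeans(b)
                    else colMeans(b >= beta_min)
    }
    out
}

## Scaling factor for one library against the reference: inverse-variance
## weighted mean of gene-wise M values after double trimming (30% on M, 5% on
## A), as in the published trimmed-mean-of-M-values method.
.tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                             trim_m = 0.30, trim_a = 0.05) {
    logR <- log2((obs / n_obs) / (ref / n_ref))
    absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
    v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) )
        return(NA_real_)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- (rank(logR) >= loM & rank(logR) <= hiM) &
            (rank(absE) >= loA & rank(absE) <= hiA)
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (is.na(f)) f <- 0
    2^f
}

#' TMM normalization and log2-CPM
#'
#' Trimmed mean of M-values: for each library, gene-wise log2
#' relative-proportion ratios (M) and mean log2 abundances (A) against a
#' reference library are doubly trimmed (\code{trim_m} on M, \code{trim_a} on
#' A) and the surviving M values combined by inverse-variance weighting into a
#' log2 scaling factor. The reference is the library whose upper-quartile /
#' library-size ratio is closest to the cohort mean of that statistic, and the
#' factors are rescaled to geometric mean 1. Expression is returned as
#' \code{log2cpm = log2((count + 0.5) / (libsize * factor + 1) * 1e6)}.
#'
#' @param counts raw count matrix (genes x samples), >= 2 samples, no
#'   all-zero library.
#' @param trim_m two-sided trim fraction on M values.
#' @param trim_a two-sided trim fraction on A values.
#' @return list with \code{tmm_factors} (named, geometric mean 1),
#'   \code{lib_sizes}, \code{log2cpm} (genes x samples) and \code{ref_sample}.
#' @export
tmmNormalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
    if (ncol(counts) < 2L) stop("TMM requires at least two samples")
    lib <- colSums(counts)
    if (any(lib == 0)) stop("normalization error: zero library size")
    expressed <- rowSums(counts > 0) > 0L
    x <- counts[expressed, , drop = FALSE]
    uq <- apply(x, 2L, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(x)), function(j)
        .tmm_pair_factor(x[, j], x[, ref], lib[j], lib[ref],
                         trim_m = trim_m, trim_a = trim_a), numeric(1L))
    if (anyNA(f))
        stop("normalization error: sample '",
             colnames(counts)[which(is.na(f))[1L]],
             "' shares no positive-count gene with the reference")
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(counts)
    eff <- lib * f
    log2cpm <- log2(sweep(counts + 0.5, 2L, eff + 1, "/") * 1e6)
    list(tmm_factors = f, lib_sizes = lib, log2cpm = log2cpm,
         ref_sample = colnames(counts)[ref])
}
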