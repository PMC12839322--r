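#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
NULL

#' MethExpCohort: paired methylation and expression data for one cohort
#'
#' An S4 container holding a probe-level methylation
#' \linkS4class{SummarizedExperiment} (assay \code{"beta"}, probe annotation in
#' \code{rowData}) and a gene-level expression \code{SummarizedExperiment}
#' (assay \code{"counts"}, later also \code{"log2cpm"}), sharing one set of
#' samples. Sample metadata (CIMP status, sample type) lives in the
#' \code{colData} of both experiments; planted ground truth from the synthetic
#' generator, when present, is stored in \code{metadata(x)$ground_truth}.
#'
#' @slot meth \code{SummarizedExperiment} of promoter-array beta values
#'   (probes x samples).
#' @slot expr \code{SummarizedExperiment} of RNA-seq counts (genes x samples).
#'
#' @seealso [MethExpCohort()] for construction, [simulateCohort()] for
#'   synthetic cohorts.
#' @export
setClass("MethExpCohort",
    slots = c(meth = "SummarizedExperiment", expr = "SummarizedExperiment"))

setValidity("MethExpCohort", function(object) {
    msg <- character()
    if (!identical(colnames(object@meth), colnames(object@expr)))
        msg <- c(msg, "methylation and expression sample ids differ")
    if (!"beta" %in% SummarizedExperiment::assayNames(object@meth))
        msg <- c(msg, "methylation experiment lacks a 'beta' assay")
    if (!"counts" %in% SummarizedExperiment::assayNames(object@expr))
        msg <- c(msg, "expression experiment lacks a 'counts' assay")
    b <- SummarizedExperiment::assay(object@meth, "beta")
    if (any(b <= 0 | b >= 1, na.rm = TRUE))
        msg <- c(msg, "beta values must lie strictly within (0, 1)")
    cts <- SummarizedExperiment::assay(object@expr, "counts")
    if (any(cts < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a MethExpCohort
#'
#' @param betas numeric matrix of beta values (probes x samples), entries in
#'   (0,1) or \code{NA}; boundary values should be clamped beforehand (see
#'   [readBetaMatrix()]).
#' @param counts non-negative integer matrix (genes x samples) with the same
#'   column names as \code{betas}.
#' @param probeAnno probe annotation \code{DataFrame} as returned by
#'   [readManifest()]; rows must match \code{rownames(betas)}.
#' @param sampleInfo data.frame with columns \code{sample_id},
#'   \code{cimp_status}, \code{sample_type} covering every sample.
#' @param truth optional ground-truth table from the synthetic generator.
#'
#' @return A \linkS4class{MethExpCohort}.
#' @examples
#' cohort <- workedExampleFixture()
#' cohort
#' @export
MethExpCohort <- function(betas, counts, probeAnno, sampleInfo, truth = NULL) {
    if (!identical(colnames(betas), colnames(counts)))
        stop("betas and counts must share identical sample columns")
    sampleInfo <- as.data.frame(sampleInfo)
    if (!all(c("sample_id", "cimp_status") %in% names(sampleInfo)))
        stop("sampleInfo needs columns sample_id and cimp_status")
    idx <- match(colnames(betas), sampleInfo$sample_id)
    if (anyNA(idx))
        stop("sampleInfo is missing samples: ",
             paste(setdiff(colnames(betas), sampleInfo$sample_id), collapse = ", "))
    cd <- S4Vectors::DataFrame(sampleInfo[idx, , drop = FALSE],
                               row.names = colnames(betas))
    pa <- probeAnno
    if (!is.null(pa)) {
        m <- match(rownames(betas), pa$probe_id)
        if (anyNA(m))
            stop("probe annotation missing for: ",
                 paste(utils::head(rownames(betas)[is.na(m)], 5L), collapse = ", "))
        pa <- pa[m, , drop = FALSE]
        rownames(pa) <- rownames(betas)
    }
    meth <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = betas), rowData = pa, colData = cd)
    expr <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    obj <- new("MethExpCohort", meth = meth, expr = expr)
    if (!is.null(truth)) S4Vectors::metadata(obj@expr)$ground_truth <- truth
    obj
}

#' @describeIn MethExpCohort-class beta-value matrix (probes x samples).
#' @param x,object a \code{MethExpCohort}.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @export
setMethod("betaValues", "MethExpCohort",
    function(x) SummarizedExperiment::assay(x@meth, "beta"))

#' @describeIn MethExpCohort-class raw count matrix (genes x samples).
#' @export
setGeneric("countValues", function(x) standardGeneric("countValues"))

#' @export
setMethod("countValues", "MethExpCohort",
    function(x) SummarizedExperiment::assay(x@expr, "counts"))

#' @describeIn MethExpCohort-class probe annotation DataFrame.
#' @export
setGeneric("probeAnno", function(x) standardGeneric("probeAnno"))

#' @export
setMethod("probeAnno", "MethExpCohort",
    function(x) SummarizedExperiment::rowData(x@meth))

#' @describeIn MethExpCohort-class sample sheet as a data.frame.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @export
setMethod("sampleInfo", "MethExpCohort",
    function(x) as.data.frame(SummarizedExperiment::colData(x@meth)))

#' @describeIn MethExpCohort-class named vector of CIMP labels per sample.
#' @export
setGeneric("cimpGroups", function(x) standardGeneric("cimpGroups"))

#' @export
setMethod("cimpGroups", "MethExpCohort", function(x) {
    si <- sampleInfo(x)
    stats::setNames(as.character(si$cimp_status), si$sample_id)
})

#' @describeIn MethExpCohort-class planted ground truth (or NULL).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setMethod("groundTruth", "MethExpCohort",
    function(x) S4Vectors::metadata(x@expr)$ground_truth)

#' @export
setMethod("show", "MethExpCohort", function(object) {
    grp <- table(factor(cimpGroups(object)))
    cat("MethExpCohort\n",
        " methylation: ", nrow(object@meth), " probes x ",
        ncol(object@meth), " samples\n",
        " expression:  ", nrow(object@expr), " genes x ",
        ncol(object@expr), " samples\n",
        " CIMP groups: ",
        paste(names(grp), grp, sep = "=", collapse = ", "), "\n",
        " ground truth: ",
        if (is.null(groundTruth(object))) "absent" else "present", "\n",
        sep = "")
})
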