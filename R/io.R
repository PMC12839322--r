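## TSV interchange: 450K-style manifest, beta/count matrices, sample sheet,
## result tables. Tab-separated, "NA" for missing, full-precision reals.

.read_tsv <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = NA,
                      na.strings = "NA", quote = "", comment.char = "")
}

.fmt_num <- function(x) {
    # %.17g round-trips IEEE doubles through read.delim exactly
    out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1L))
    out
}

#' Read a 450K-style probe manifest
#'
#' Parses a tab-separated manifest with the documented columns \code{IlmnID},
#' \code{CHR}, \code{MAPINFO}, \code{UCSC_RefGene_Name},
#' \code{UCSC_RefGene_Group}, \code{Regulatory_Feature_Group},
#' \code{SNP_Overlap} and \code{Islands_Name}. Semicolon-separated multi-gene
#' fields are split so a probe may belong to several gene promoters; empty
#' island / regulatory fields become missing / non-promoter-associated.
#'
#' @param path path to the manifest TSV.
#' @return A \code{DataFrame} with columns \code{probe_id}, \code{chrom},
#'   \code{pos}, \code{genes} (CharacterList), \code{tss_groups}
#'   (CharacterList, parallel to \code{genes}), \code{promoter_associated},
#'   \code{snp_overlap}, \code{island_id}.
#' @export
readManifest <- function(path) {
    df <- .read_tsv(path)
    required <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
                  "UCSC_RefGene_Group", "Regulatory_Feature_Group",
                  "SNP_Overlap", "Islands_Name")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols))
        stop("manifest format error: missing column(s) ",
             paste(missing_cols, collapse = ", "))
    if (nrow(df) == 0L) {
        return(S4Vectors::DataFrame(
            probe_id = character(), chrom = character(), pos = integer(),
            genes = IRanges::CharacterList(),
            tss_groups = IRanges::CharacterList(),
            promoter_associated = logical(), snp_overlap = logical(),
            island_id = character()))
    }
    if (anyDuplicated(df$IlmnID))
        stop("manifest validation error: duplicate probe_id ",
             paste(unique(df$IlmnID[duplicated(df$IlmnID)]), collapse = ", "))
    pos <- suppressWarnings(as.integer(df$MAPINFO))
    if (anyNA(pos) || any(pos < 1L))
        stop("manifest validation error: MAPINFO must be positive integers")
    split_field <- function(x) {
        x <- ifelse(is.na(x), "", x)
        strsplit(x, ";", fixed = TRUE)
    }
    genes <- split_field(df$UCSC_RefGene_Name)
    tss <- split_field(df$UCSC_RefGene_Group)
    bad <- lengths(genes) != lengths(tss)
    if (any(bad))
        stop("manifest validation error: gene/TSS-group lists differ in ",
             "length for probe(s) ", paste(df$IlmnID[bad], collapse = ", "))
    reg <- ifelse(is.na(df$Regulatory_Feature_Group), "",
                  df$Regulatory_Feature_Group)
    snp <- df$SNP_Overlap
    snp_flag <- if (is.logical(snp)) snp else {
        as.character(snp) %in% c("1", "TRUE", "True", "true", "yes")
    }
    island <- as.character(df$Islands_Name)
    island[!is.na(island) & island == ""] <- NA_character_
    ann <- S4Vectors::DataFrame(
        probe_id = as.character(df$IlmnID),
        chrom = as.character(df$CHR),
        pos = pos,
        genes = IRanges::CharacterList(genes),
        tss_groups = IRanges::CharacterList(tss),
        promoter_associated = grepl("Promoter_Associated", reg, fixed = TRUE),
        snp_overlap = snp_flag,
        island_id = island)
    rownames(ann) <- ann$probe_id
    ann
}

.read_numeric_matrix <- function(path, what) {
    df <- .read_tsv(path)
    if (ncol(df) < 2L)
        stop(what, " format error: expected row-id column plus >=1 sample")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop(what, " validation error: duplicate row ids ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    samp <- names(df)[-1L]
    if (anyDuplicated(samp))
        stop(what, " validation error: duplicate sample ids")
    m <- matrix(NA_real_, nrow(df), length(samp), dimnames = list(ids, samp))
    for (j in seq_along(samp)) {
        col <- df[[j + 1L]]
        if (!is.numeric(col)) {
            num <- suppressWarnings(as.numeric(col))
            bad <- which(is.na(num) & !is.na(col) & col != "NA")
            if (length(bad))
                stop(what, " format error: non-numeric cell at row '",
                     ids[bad[1L]], "', column '", samp[j], "'")
            col <- num
        }
        m[, j] <- col
    }
    m
}

#' Read a beta-value matrix
#'
#' TSV with probe ids in the first column and one column per sample. Entries
#' must lie in \[0, 1\] or be \code{NA}; values at exactly 0 or 1 (a file
#' rounding artifact — array betas are open-interval) are clamped to
#' \code{eps} / \code{1 - eps} and counted in the \code{"clamped"} attribute.
#'
#' @param path path to the TSV.
#' @param eps clamping margin for boundary values.
#' @return numeric matrix (probes x samples) with attribute \code{clamped},
#'   the number of boundary cells adjusted.
#' @export
readBetaMatrix <- function(path, eps = 1e-6) {
    m <- .read_numeric_matrix(path, "beta matrix")
    out_of_range <- which(m < 0 | m > 1)
    if (length(out_of_range)) {
        rc <- arrayInd(out_of_range[1L], dim(m))
        stop("beta matrix validation error: value outside [0, 1] at row '",
             rownames(m)[rc[1L]], "', column '", colnames(m)[rc[2L]], "'")
    }
    clamp_lo <- !is.na(m) & m == 0
    clamp_hi <- !is.na(m) & m == 1
    m[clamp_lo] <- eps
    m[clamp_hi] <- 1 - eps
    structure(m, clamped = sum(clamp_lo) + sum(clamp_hi))
}

#' Read a raw count matrix
#'
#' TSV with gene ids in the first column; entries must be non-negative
#' integers and every library (column) sum must be positive.
#'
#' @param path path to the TSV.
#' @return integer-valued numeric matrix (genes x samples).
#' @export
readCountMatrix <- function(path) {
    m <- .read_numeric_matrix(path, "count matrix")
    if (anyNA(m))
        stop("count matrix validation error: missing values not allowed")
    neg <- which(m < 0)
    if (length(neg)) {
        rc <- arrayInd(neg[1L], dim(m))
        stop("count matrix validation error: negative count at row '",
             rownames(m)[rc[1L]], "', column '", colnames(m)[rc[2L]], "'")
    }
    if (any(abs(m - round(m)) > 0))
        stop("count matrix validation error: non-integer counts present")
    if (any(colSums(m) == 0))
        stop("count matrix validation error: zero library size in sample(s) ",
             paste(colnames(m)[colSums(m) == 0], collapse = ", "))
    m
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{cimp_status} (one of CIMP-H,
#' CIMP-L, Non-CIMP, unknown) and \code{sample_type}.
#'
#' @param path path to the TSV.
#' @return data.frame with validated unique sample ids.
#' @export
readSampleSheet <- function(path) {
    df <- .read_tsv(path)
    required <- c("sample_id", "cimp_status", "sample_type")
    miss <- setdiff(required, names(df))
    if (length(miss))
        stop("sample sheet format error: missing column(s) ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("sample sheet validation error: duplicate sample_id")
    allowed <- c("CIMP-H", "CIMP-L", "Non-CIMP", "unknown")
    bad <- !df$cimp_status %in% allowed
    if (any(bad))
        stop("sample sheet validation error: unknown cimp_status '",
             df$cimp_status[which(bad)[1L]], "'")
    df
}

#' Write a result table as TSV
#'
#' Writes any result data.frame with a stable column order, literal
#' \code{"NA"} for missing values, and full-precision reals (17 significant
#' digits) so that numeric values round-trip exactly through
#' [readResultTable()].
#'
#' @param records data.frame to write (zero rows allowed: header-only file).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(records, path) {
    records <- as.data.frame(records)
    out <- records
    for (j in seq_along(out)) {
        if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
    }
    tryCatch(
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE, na = "NA"),
        error = function(e) stop("IO error writing '", path, "': ",
                                 conditionMessage(e)))
    invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readResultTable <- function(path) .read_tsv(path)

#' Write a numeric matrix as TSV
#'
#' First column carries row ids under the header \code{id}; numeric entries
#' are written at full precision so they round-trip exactly.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
    df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- .fmt_num(m[, j])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

#' Write a probe annotation table in manifest layout
#'
#' Inverse of [readManifest()]: list columns are re-joined with semicolons.
#'
#' @param ann probe annotation \code{DataFrame}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(ann, path) {
    join <- function(x) vapply(x, paste, character(1L), collapse = ";")
    df <- data.frame(
        IlmnID = ann$probe_id,
        CHR = ann$chrom,
        MAPINFO = ann$pos,
        UCSC_RefGene_Name = join(as.list(ann$genes)),
        UCSC_RefGene_Group = join(as.list(ann$tss_groups)),
        Regulatory_Feature_Group = ifelse(ann$promoter_associated,
                                          "Promoter_Associated", ""),
        SNP_Overlap = as.integer(ann$snp_overlap),
        Islands_Name = ifelse(is.na(ann$island_id), "", ann$island_id),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    invisible(path)
}

#' Read a key=value configuration file
#'
#' One \code{key = value} pair per line; blank lines and \code{#} comments
#' ignored. Keys must be valid [analysisConfig()] fields or generator /
#' pipeline settings; unknown keys raise an error.
#'
#' @param path path to the config file.
#' @param known character vector of accepted keys.
#' @return named list of parsed values (numerics converted).
#' @export
readConfigFile <- function(path,
                           known = c(names(analysisConfig()),
                                     names(cohortParams()),
                                     "outdir", "seed")) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    out <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L)
            stop("config format error: expected 'key = value', got '", ln, "'")
        key <- trimws(kv[1L]); val <- trimws(kv[2L])
        if (!key %in% known)
            stop("config error: unknown key '", key, "'")
        num <- suppressWarnings(as.numeric(val))
        out[[key]] <- if (!is.na(num)) num else val
    }
    out
}
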