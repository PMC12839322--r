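## Stage-wise pipeline. Stages communicate only through TSV files in outdir,
## so any stage can be re-run or replaced; rerunning with the same config and
## seed reproduces byte-identical outputs.

.stage_order <- c("simulate", "preprocess", "stratify", "differential",
                  "associate", "silence", "report")

.pipe_log <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
}

.need <- function(outdir, files, stage, wanted_by) {
    paths <- file.path(outdir, files)
    missing <- !file.exists(paths)
    if (any(missing))
        stop("stage-dependency error: '", wanted_by, "' requires output of ",
             "stage '", stage, "' (missing ",
             paste(files[missing], collapse = ", "), ")")
    invisible(paths)
}

.write_promoter_map <- function(map, path) {
    df <- data.frame(gene = names(map),
                     probes = vapply(as.list(map), paste, character(1L),
                                     collapse = ","),
                     stringsAsFactors = FALSE)
    writeResultTable(df, path)
}

.read_promoter_map <- function(path) {
    df <- readResultTable(path)
    IRanges::CharacterList(stats::setNames(
        strsplit(df$probes, ",", fixed = TRUE), df$gene))
}

.split_config <- function(config) {
    if (is.character(config)) config <- readConfigFile(config)
    if (is.null(config)) config <- list()
    a_keys <- names(formals(analysisConfig))
    g_keys <- names(formals(cohortParams))
    bad <- setdiff(names(config), c(a_keys, g_keys, "outdir", "seed"))
    if (length(bad)) stop("config error: unknown key(s) ",
                          paste(bad, collapse = ", "))
    list(analysis = do.call(analysisConfig,
                            config[intersect(names(config), a_keys)]),
         generator = do.call(cohortParams,
                             config[intersect(names(config), g_keys)]),
         seed = if (!is.null(config$seed)) as.integer(config$seed) else NULL,
         outdir = config$outdir)
}

.effective_groups <- function(outdir) {
    g <- readResultTable(file.path(outdir, "groups.tsv"))
    stats::setNames(g$group, g$sample_id)
}

#' Run the analysis pipeline
#'
#' Executes the workflow stage by stage, reading and writing TSV files under
#' \code{outdir}: \code{simulate} (synthetic cohort), \code{preprocess}
#' (probe filtering, promoter map and summaries, TMM/log2-CPM),
#' \code{stratify} (CIMP-index; sample-sheet CIMP labels take precedence over
#' assigned classes), \code{differential} (integrated DM/DE with the five-way
#' classification), \code{associate} (six association scorers, selection,
#' method comparison), \code{silence} (external-definition silencing calls
#' and perc.diff), and \code{report} (ranked-gene table and run manifest with
#' file digests). \code{stage = "all"} runs everything in order. All
#' randomness derives from \code{seed}.
#'
#' @param config path to a \code{key = value} config file, or a named list of
#'   [analysisConfig()] / [cohortParams()] keys (plus \code{seed},
#'   \code{outdir}); unknown keys raise an error.
#' @param stage one of \code{"all"}, \code{"simulate"}, \code{"preprocess"},
#'   \code{"stratify"}, \code{"differential"}, \code{"associate"},
#'   \code{"silence"}, \code{"report"}.
#' @param outdir output directory (created if absent); overrides any
#'   \code{outdir} config key.
#' @param seed integer seed; overrides any \code{seed} config key.
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config = NULL, stage = "all", outdir = NULL,
                        seed = NULL) {
    stage <- match.arg(stage, c("all", .stage_order))
    cfgs <- .split_config(config)
    if (is.null(outdir)) outdir <- cfgs$outdir
    if (is.null(outdir)) stop("config error: no output directory given")
    if (is.null(seed)) seed <- cfgs$seed
    if (is.null(seed)) seed <- cfgs$analysis$rng_seed
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    stages <- if (stage == "all") .stage_order else stage
    for (s in stages) {
        t0 <- proc.time()[["elapsed"]]
        switch(s,
            simulate = .stage_simulate(outdir, cfgs$generator, seed),
            preprocess = .stage_preprocess(outdir, cfgs$analysis),
            stratify = .stage_stratify(outdir, cfgs$analysis),
            differential = .stage_differential(outdir, cfgs$analysis),
            associate = .stage_associate(outdir, cfgs$analysis),
            silence = .stage_silence(outdir, cfgs$analysis),
            report = .stage_report(outdir, cfgs, seed))
        .pipe_log(s, sprintf("done in %.2fs", proc.time()[["elapsed"]] - t0))
    }
    invisible(outdir)
}

.stage_simulate <- function(outdir, params, seed) {
    cohort <- simulateCohort(params, seed = seed)
    writeManifest(probeAnno(cohort), file.path(outdir, "manifest.tsv"))
    writeMatrixTSV(betaValues(cohort), file.path(outdir, "betas.tsv"))
    writeMatrixTSV(countValues(cohort), file.path(outdir, "counts.tsv"))
    writeResultTable(sampleInfo(cohort), file.path(outdir, "samples.tsv"))
    writeResultTable(groundTruth(cohort),
                     file.path(outdir, "ground_truth.tsv"))
    .pipe_log("simulate", nrow(betaValues(cohort)), " probes, ",
              nrow(countValues(cohort)), " genes, ",
              ncol(betaValues(cohort)), " samples (seed ", seed, ")")
}

.stage_preprocess <- function(outdir, cfg) {
    .need(outdir, c("manifest.tsv", "betas.tsv", "counts.tsv"),
          "simulate", "preprocess")
    annot <- readManifest(file.path(outdir, "manifest.tsv"))
    betas <- readBetaMatrix(file.path(outdir, "betas.tsv"))
    counts <- readCountMatrix(file.path(outdir, "counts.tsv"))
    fl <- filterProbes(annot, betas)
    map <- buildPromoterMap(annot, rownames(fl$betas))
    norm <- tmmNormalize(counts)
    writeResultTable(fl$report, file.path(outdir, "filter_report.tsv"))
    writeMatrixTSV(fl$betas, file.path(outdir, "filtered_betas.tsv"))
    .write_promoter_map(map, file.path(outdir, "promoter_map.tsv"))
    writeMatrixTSV(summarizePromoter(fl$betas, map, "average"),
                   file.path(outdir, "promoter_avg.tsv"))
    writeMatrixTSV(summarizePromoter(fl$betas, map, "ratio",
                                     beta_min = cfg$meth_cpg_beta_min),
                   file.path(outdir, "promoter_ratio.tsv"))
    writeMatrixTSV(norm$log2cpm, file.path(outdir, "log2cpm.tsv"))
    writeResultTable(data.frame(sample_id = names(norm$tmm_factors),
                                tmm_factor = unname(norm$tmm_factors),
                                lib_size = unname(norm$lib_sizes)),
                     file.path(outdir, "tmm_factors.tsv"))
    .pipe_log("preprocess", sum(fl$report$n[fl$report$reason == "kept"]),
              " probes kept, ", length(map), " promoters mapped")
}

.stage_stratify <- function(outdir, cfg) {
    .need(outdir, c("manifest.tsv", "filtered_betas.tsv", "samples.tsv"),
          "preprocess", "stratify")
    annot <- readManifest(file.path(outdir, "manifest.tsv"))
    betas <- readBetaMatrix(file.path(outdir, "filtered_betas.tsv"))
    sheet <- readSampleSheet(file.path(outdir, "samples.tsv"))
    island_of <- stats::setNames(annot$island_id, annot$probe_id)
    idx <- cimpIndex(betas, island_of, beta_min = cfg$meth_cpg_beta_min)
    idx <- assignCimpClass(idx, hi = cfg$cimp_index_hi, lo = cfg$cimp_index_lo)
    writeResultTable(idx, file.path(outdir, "cimp_index.tsv"))
    provided <- sheet$cimp_status %in% c("CIMP-H", "CIMP-L", "Non-CIMP")
    grp <- if (all(provided)) sheet$cimp_status else
        idx$assigned_class[match(sheet$sample_id, idx$sample_id)]
    writeResultTable(data.frame(sample_id = sheet$sample_id, group = grp,
                                source = if (all(provided)) "sample_sheet"
                                         else "cimp_index",
                                stringsAsFactors = FALSE),
                     file.path(outdir, "groups.tsv"))
    .pipe_log("stratify", sum(grp == "CIMP-H"), " CIMP-H vs ",
              sum(grp == "Non-CIMP"), " Non-CIMP (labels from ",
              if (all(provided)) "sample sheet)" else "CIMP-index)")
}

.stage_differential <- function(outdir, cfg) {
    .need(outdir, c("promoter_avg.tsv", "log2cpm.tsv"),
          "preprocess", "differential")
    .need(outdir, "groups.tsv", "stratify", "differential")
    avg <- .read_numeric_matrix(file.path(outdir, "promoter_avg.tsv"),
                                "promoter average")
    l2c <- .read_numeric_matrix(file.path(outdir, "log2cpm.tsv"), "log2cpm")
    groups <- .effective_groups(outdir)
    rec <- runDifferential(avg, l2c, groups, cfg)
    writeResultTable(rec, file.path(outdir, "differential.tsv"))
    .pipe_log("differential", sum(rec$category != "not-significant"),
              " of ", nrow(rec), " genes in significant categories")
}

.stage_associate <- function(outdir, cfg) {
    .need(outdir, c("filtered_betas.tsv", "promoter_map.tsv", "log2cpm.tsv"),
          "preprocess", "associate")
    .need(outdir, "differential.tsv", "differential", "associate")
    betas <- readBetaMatrix(file.path(outdir, "filtered_betas.tsv"))
    map <- .read_promoter_map(file.path(outdir, "promoter_map.tsv"))
    l2c <- .read_numeric_matrix(file.path(outdir, "log2cpm.tsv"), "log2cpm")
    groups <- .effective_groups(outdir)
    rec <- readResultTable(file.path(outdir, "differential.tsv"))
    candidates <- rec$gene[rec$category != "not-significant"]
    if (!length(candidates)) {
        writeResultTable(data.frame(gene = character(), method = character(),
                                    score = numeric(), p = numeric(),
                                    adj_p = numeric(), n_cpgs = integer(),
                                    n_samples = integer(),
                                    status = character(),
                                    selected = logical(), rank = integer()),
                         file.path(outdir, "scores.tsv"))
        .pipe_log("associate", "no candidate genes; empty score table")
        return(invisible())
    }
    scores <- selectGenes(scoreAssociations(betas, map, l2c, groups,
                                            genes = candidates, cfg = cfg),
                          cfg)
    writeResultTable(scores, file.path(outdir, "scores.tsv"))
    cmp <- compareMethods(scores)
    cmp_df <- do.call(rbind, lapply(names(cmp), function(fam) {
        data.frame(family = fam, method = names(cmp[[fam]]$argmax_counts),
                   kw_statistic = cmp[[fam]]$kw_statistic,
                   kw_p = cmp[[fam]]$kw_p,
                   argmax_count = unname(cmp[[fam]]$argmax_counts),
                   n_selected = lengths(cmp[[fam]]$selected_sets),
                   n_genes_compared = cmp[[fam]]$n_genes,
                   stringsAsFactors = FALSE)
    }))
    writeResultTable(cmp_df, file.path(outdir, "comparison.tsv"))
    sel_genes <- sort(unique(scores$gene[scores$selected]))
    ov <- data.frame(gene = sel_genes, stringsAsFactors = FALSE)
    for (meth in sort(unique(scores$method)))
        ov[[gsub("-", "_", meth)]] <- sel_genes %in%
            scores$gene[scores$method == meth & scores$selected]
    writeResultTable(ov, file.path(outdir, "overlap.tsv"))
    .pipe_log("associate", length(candidates), " candidates scored by ",
              length(unique(scores$method)), " methods")
}

.stage_silence <- function(outdir, cfg) {
    .need(outdir, c("filtered_betas.tsv", "promoter_map.tsv", "log2cpm.tsv"),
          "preprocess", "silence")
    .need(outdir, "scores.tsv", "associate", "silence")
    betas <- readBetaMatrix(file.path(outdir, "filtered_betas.tsv"))
    map <- .read_promoter_map(file.path(outdir, "promoter_map.tsv"))
    l2c <- .read_numeric_matrix(file.path(outdir, "log2cpm.tsv"), "log2cpm")
    groups <- .effective_groups(outdir)
    calls <- silencingCalls(betas, map, l2c, groups, cfg)
    writeResultTable(calls, file.path(outdir, "silencing.tsv"))
    scores <- readResultTable(file.path(outdir, "scores.tsv"))
    identified <- unique(scores$gene[scores$method == "regression-single" &
                                     scores$selected %in% TRUE])
    identified <- intersect(identified, calls$gene)
    qc <- quartileConsistency(stats::setNames(calls$perc_diff, calls$gene),
                              identified)
    writeResultTable(data.frame(
        q3 = qc$q3, fraction_at_or_above_q3 = qc$fraction_at_or_above_q3,
        n_overall = qc$n_overall, n_identified = qc$n_identified),
        file.path(outdir, "consistency.tsv"))
    .pipe_log("silence", sum(calls$gene_silenced), " of ", nrow(calls),
              " genes called silenced")
}

.stage_report <- function(outdir, cfgs, seed) {
    .need(outdir, c("differential.tsv", "scores.tsv", "silencing.tsv"),
          "silence", "report")
    rec <- readResultTable(file.path(outdir, "differential.tsv"))
    scores <- readResultTable(file.path(outdir, "scores.tsv"))
    calls <- readResultTable(file.path(outdir, "silencing.tsv"))
    rep_df <- rec[rec$category != "not-significant",
                  c("gene", "category", "delta_beta", "log2fc")]
    for (meth in unique(scores$method)) {
        sc <- scores[scores$method == meth, ]
        i <- match(rep_df$gene, sc$gene)
        safe <- gsub("-", "_", meth)
        rep_df[[paste0("score_", safe)]] <- sc$score[i]
        rep_df[[paste0("selected_", safe)]] <- sc$selected[i]
    }
    i <- match(rep_df$gene, calls$gene)
    rep_df$perc_diff <- calls$perc_diff[i]
    key <- rep_df$score_regression_single
    rep_df <- rep_df[order(-ifelse(is.na(key), -Inf, key), rep_df$gene), ]
    writeResultTable(rep_df, file.path(outdir, "report.tsv"))
    snap <- c(cfgs$analysis[names(cfgs$analysis) != "rng_seed"],
              cfgs$generator[!vapply(cfgs$generator, is.character,
                                     logical(1L)) |
                             names(cfgs$generator) == "effect_mode"])
    snap_df <- data.frame(key = names(snap),
                          value = vapply(snap, function(v)
                              paste(format(v), collapse = ","),
                              character(1L)),
                          stringsAsFactors = FALSE)
    writeResultTable(snap_df, file.path(outdir, "config_snapshot.tsv"))
    outputs <- sort(setdiff(list.files(outdir, pattern = "\\.tsv$"),
                            "run_manifest.tsv"))
    manifest <- data.frame(
        file = outputs,
        md5 = unname(tools::md5sum(file.path(outdir, outputs))),
        stringsAsFactors = FALSE)
    manifest <- rbind(manifest,
                      data.frame(file = c("__seed__", "__version__"),
                                 md5 = c(as.character(seed),
                                         as.character(utils::packageVersion(
                                             "promethyl"))),
                                 stringsAsFactors = FALSE))
    writeResultTable(manifest, file.path(outdir, "run_manifest.tsv"))
    .pipe_log("report", nrow(rep_df), " ranked genes reported")
}
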