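## Shared builders for small in-code fixtures.

# minimal manifest data.frame in file layout
manifest_lines <- function(rows) {
    header <- paste("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
                    "UCSC_RefGene_Group", "Regulatory_Feature_Group",
                    "SNP_Overlap", "Islands_Name", sep = "\t")
    c(header, rows)
}

write_manifest_lines <- function(rows) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeLines(manifest_lines(rows), path)
    path
}

# annotation DataFrame for ad-hoc probe sets
make_annot <- function(probe_id, chrom = "1", gene = "GENE1",
                       tss = "TSS1500", promoter_associated = FALSE,
                       snp = FALSE, island = NA_character_) {
    n <- length(probe_id)
    S4Vectors::DataFrame(
        probe_id = probe_id,
        chrom = rep_len(chrom, n),
        pos = seq_len(n) * 100L,
        genes = IRanges::CharacterList(as.list(rep_len(gene, n))),
        tss_groups = IRanges::CharacterList(as.list(rep_len(tss, n))),
        promoter_associated = rep_len(promoter_associated, n),
        snp_overlap = rep_len(snp, n),
        island_id = rep_len(island, n),
        row.names = probe_id)
}

# run the analysis chain in memory on a simulated cohort
run_cohort_analysis <- function(cohort, cfg = analysisConfig(),
                                score = TRUE) {
    ann <- probeAnno(cohort)
    fl <- filterProbes(ann, betaValues(cohort))
    map <- buildPromoterMap(ann, rownames(fl$betas))
    norm <- tmmNormalize(countValues(cohort))
    grp <- cimpGroups(cohort)
    avg <- summarizePromoter(fl$betas, map, "average")
    rec <- runDifferential(avg, norm$log2cpm, grp, cfg)
    out <- list(betas = fl$betas, map = map, norm = norm, groups = grp,
                promoter_avg = avg, differential = rec,
                truth = groundTruth(cohort))
    if (score) {
        cand <- rec$gene[rec$category != "not-significant"]
        out$scores <- selectGenes(
            scoreAssociations(fl$betas, map, norm$log2cpm, grp,
                              genes = cand, cfg = cfg), cfg)
    }
    out
}
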