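#' Generator settings for synthetic cohorts
#'
#' Defaults emulate a CIMP-stratified 450K + RNA-seq tumor cohort at desk
#' scale: 200 genes with promoters of 2 + Poisson(4) CpGs (truncated at 30),
#' 40 CIMP-H and 40 Non-CIMP samples, 10\% of genes methylation-driven
#' (promoter hypermethylated in CIMP-H with log2 expression decreasing by
#' \code{effect_slope} per unit promoter-mean beta), 10\% DM-only and 10\%
#' DE-only decoy genes, Beta(2,10) baseline and Beta(10,2) hypermethylated
#' promoter states, negative-binomial counts (dispersion 0.1) with library
#' sizes log-uniform in 0.5-2x of \code{base_depth}, and decoy probes on the
#' sex chromosomes, SNP-flagged, or carrying missing values.
#'
#' @param n_genes number of genes.
#' @param n_cimp_h,n_non_cimp samples per CIMP group.
#' @param promoter_lambda Poisson rate for promoter size (added to 2).
#' @param promoter_max maximum promoter size.
#' @param frac_meth_driven,frac_dm_only,frac_de_only role fractions; the
#'   remainder are null genes.
#' @param effect_slope log2-CPM change per unit promoter-mean beta for
#'   methylation-driven genes (negative for silencing).
#' @param de_log2fc planted expression shift of DE-only genes in CIMP-H.
#' @param meth_penetrance probability that a CIMP-H sample is hypermethylated
#'   for a planted gene; 1 means every CIMP-H sample. Partial penetrance
#'   emulates silencing that hits a minority of tumors.
#' @param beta_base,beta_hyper,beta_background Beta shape pairs for baseline,
#'   hypermethylated and background-shifted promoter states.
#' @param background_shift_frac fraction of non-planted genes whose promoters
#'   are mildly hypermethylated in CIMP-H (the global CIMP-H hypermethylation
#'   that drives the CIMP-index).
#' @param probe_noise_sd sd of probe-level noise around the promoter state.
#' @param effect_mode \code{"mean"} couples expression to the promoter-mean
#'   beta; \code{"opposing"} adds per-CpG deviations with alternating-sign
#'   coefficients so that promoter summaries cancel part of the signal.
#' @param opposing_noise_sd probe-level noise sd in opposing mode.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param base_depth nominal library size.
#' @param libsize_log2_range log2 range of per-sample depth multipliers.
#' @param baseline_log2_range range of per-gene baseline log2 relative
#'   expression.
#' @param frac_xy,frac_snp,frac_na decoy probe fractions (relative to the
#'   number of promoter probes) for sex-chromosome, SNP-flagged and
#'   missing-value probes.
#' @return named list of validated settings.
#' @export
cohortParams <- function(n_genes = 200L,
                         n_cimp_h = 40L, n_non_cimp = 40L,
                         promoter_lambda = 4, promoter_max = 30L,
                         frac_meth_driven = 0.10, frac_dm_only = 0.10,
                         frac_de_only = 0.10,
                         effect_slope = -3, de_log2fc = -2,
                         meth_penetrance = 1,
                         beta_base = c(2, 10), beta_hyper = c(10, 2),
                         beta_background = c(3.5, 6.5),
                         background_shift_frac = 0.3,
                         probe_noise_sd = 0.05,
                         effect_mode = c("mean", "opposing"),
                         opposing_noise_sd = 0.15,
                         nb_dispersion = 0.1,
                         base_depth = 2e5,
                         libsize_log2_range = c(-1, 1),
                         baseline_log2_range = c(4, 10),
                         frac_xy = 0.05, frac_snp = 0.05, frac_na = 0.02) {
    effect_mode <- match.arg(effect_mode)
    if (frac_meth_driven + frac_dm_only + frac_de_only > 1)
        stop("parameter error: role fractions sum to more than 1")
    if (meth_penetrance <= 0 || meth_penetrance > 1)
        stop("parameter error: meth_penetrance must lie in (0, 1]")
    as.list(environment())
}

.with_seed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    expr
}

#' Simulate a CIMP-stratified methylation + expression cohort
#'
#' Generates a paired beta/count cohort with planted ground truth under the
#' settings of [cohortParams()]. Methylation-driven genes are promoter
#' hypermethylated in (a \code{meth_penetrance} fraction of) CIMP-H samples
#' and their log2 relative expression is \code{baseline + effect_slope *
#' promoter-mean beta}; DM-only genes are hypermethylated with independent
#' expression; DE-only genes are expression-shifted with baseline
#' methylation; a \code{background_shift_frac} fraction of the remaining
#' genes carries mild CIMP-H promoter hypermethylation so that the cohort
#' exhibits the global CIMP-H methylation excess measured by the CIMP-index.
#' Counts are negative binomial around per-sample expected proportions times
#' the library size. Identical \code{seed} and \code{params} give
#' bit-identical cohorts; the caller's RNG state is left untouched.
#'
#' @param params generator settings from [cohortParams()].
#' @param seed integer seed for the cohort's RNG stream.
#' @return A \linkS4class{MethExpCohort}; [groundTruth()] returns the planted
#'   roles (\code{gene}, \code{role}, \code{effect_slope},
#'   \code{planted_delta_beta}, \code{planted_log2fc}).
#' @examples
#' cohort <- simulateCohort(cohortParams(n_genes = 50L, n_cimp_h = 10L,
#'                                       n_non_cimp = 10L), seed = 7)
#' table(groundTruth(cohort)$role)
#' @export
simulateCohort <- function(params = cohortParams(), seed = 1L) .with_seed(seed, {
    p <- params
    ng <- as.integer(p$n_genes)
    nh <- as.integer(p$n_cimp_h); nn <- as.integer(p$n_non_cimp)
    ns <- nh + nn
    samples <- c(sprintf("H%02d", seq_len(nh)), sprintf("N%02d", seq_len(nn)))
    is_h <- c(rep(TRUE, nh), rep(FALSE, nn))
    genes <- sprintf("G%03d", seq_len(ng))

    n_md <- round(p$frac_meth_driven * ng)
    n_dm <- round(p$frac_dm_only * ng)
    n_de <- round(p$frac_de_only * ng)
    role <- rep("null", ng)
    planted <- sample.int(ng, n_md + n_dm + n_de)
    role[planted[seq_len(n_md)]] <- "methylation-driven"
    if (n_dm) role[planted[n_md + seq_len(n_dm)]] <- "dm-only"
    if (n_de) role[planted[n_md + n_dm + seq_len(n_de)]] <- "de-only"
    bg_pool <- which(role == "null")
    n_bg <- round(p$background_shift_frac * length(bg_pool))
    background <- rep(FALSE, ng)
    if (n_bg) background[sample(bg_pool, n_bg)] <- TRUE

    k <- 2L + pmin(stats::rpois(ng, p$promoter_lambda),
                   p$promoter_max - 2L)

    ## per-gene, per-sample promoter methylation state
    hyper <- role %in% c("methylation-driven", "dm-only")
    m <- matrix(stats::rbeta(ng * ns, p$beta_base[1], p$beta_base[2]),
                ng, ns, dimnames = list(genes, samples))
    for (g in which(hyper)) {
        pen <- is_h & stats::runif(ns) <= p$meth_penetrance
        m[g, pen] <- stats::rbeta(sum(pen), p$beta_hyper[1], p$beta_hyper[2])
    }
    for (g in which(background)) {
        m[g, is_h] <- stats::rbeta(nh, p$beta_background[1],
                                   p$beta_background[2])
    }

    noise_sd <- if (p$effect_mode == "opposing") p$opposing_noise_sd
                else p$probe_noise_sd
    gene_of_probe <- rep(seq_len(ng), k)
    n_prom <- length(gene_of_probe)
    betas <- m[gene_of_probe, , drop = FALSE] +
        matrix(stats::rnorm(n_prom * ns, sd = noise_sd), n_prom, ns)
    betas <- pmin(pmax(betas, 1e-4), 1 - 1e-4)
    probe_ids <- sprintf("cg%06d", seq_len(n_prom))
    rownames(betas) <- probe_ids

    ## expression: log2 relative abundance per gene and sample
    b0 <- stats::runif(ng, p$baseline_log2_range[1], p$baseline_log2_range[2])
    prom_mean <- rowsum(betas, gene_of_probe) / as.vector(k)
    eff <- matrix(0, ng, ns)
    for (g in which(role == "methylation-driven")) {
        eff[g, ] <- p$effect_slope * prom_mean[g, ]
        if (p$effect_mode == "opposing") {
            rows <- which(gene_of_probe == g)
            w <- abs(p$effect_slope) * (-1)^(seq_along(rows) + 1)
            dev <- betas[rows, , drop = FALSE] -
                matrix(m[g, ], length(rows), ns, byrow = TRUE)
            eff[g, ] <- eff[g, ] + colSums(dev * w)
        }
    }
    for (g in which(role == "de-only")) eff[g, is_h] <- p$de_log2fc
    rel <- 2^(b0 + eff)
    prop <- sweep(rel, 2L, colSums(rel), "/")
    lib <- round(p$base_depth *
                 2^stats::runif(ns, p$libsize_log2_range[1],
                                p$libsize_log2_range[2]))
    mu <- sweep(prop, 2L, lib, "*")
    counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                    size = 1 / p$nb_dispersion),
                     ng, ns, dimnames = list(genes, samples))

    ## promoter probe annotation
    chrom <- as.character(sample.int(22L, ng, replace = TRUE))[gene_of_probe]
    pos <- 10000L + 50L * seq_len(n_prom)
    grp_pool <- c("TSS1500", "TSS200")
    tss <- sample(grp_pool, n_prom, replace = TRUE)
    prom_assoc <- stats::runif(n_prom) < 0.10
    tss[prom_assoc] <- "Body"  # mapped only via the promoter-associated flag
    ann <- data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
                      gene = genes[gene_of_probe], tss = tss,
                      promoter_associated = prom_assoc,
                      snp = FALSE,
                      island = paste0("isl_", genes[gene_of_probe]),
                      stringsAsFactors = FALSE)

    ## decoy probes: sex-chromosome, SNP-flagged, NA-bearing
    add_decoys <- function(n, chrom_pool, snp, island = NA_character_) {
        if (n <= 0L) return(NULL)
        data.frame(probe_id = NA_character_,
                   chrom = sample(chrom_pool, n, replace = TRUE),
                   pos = 0L, gene = "", tss = "",
                   promoter_associated = FALSE, snp = snp, island = island,
                   stringsAsFactors = FALSE)
    }
    dec <- rbind(add_decoys(round(p$frac_xy * n_prom), c("X", "Y"), FALSE),
                 add_decoys(round(p$frac_snp * n_prom), as.character(1:22),
                            TRUE),
                 add_decoys(round(p$frac_na * n_prom), as.character(1:22),
                            FALSE))
    if (!is.null(dec) && nrow(dec)) {
        n_dec <- nrow(dec)
        dec$probe_id <- sprintf("cg9%05d", seq_len(n_dec))
        dec$pos <- 500000L + 50L * seq_len(n_dec)
        db <- matrix(stats::rbeta(n_dec * ns, p$beta_base[1], p$beta_base[2]),
                     n_dec, ns, dimnames = list(dec$probe_id, samples))
        n_na <- round(p$frac_na * n_prom)
        if (n_na > 0L) {
            na_rows <- n_dec - n_na + seq_len(n_na)
            db[cbind(na_rows, sample.int(ns, n_na, replace = TRUE))] <- NA
        }
        betas <- rbind(betas, db)
        ann <- rbind(ann, dec)
    }

    annot <- S4Vectors::DataFrame(
        probe_id = ann$probe_id,
        chrom = ann$chrom,
        pos = as.integer(ann$pos),
        genes = IRanges::CharacterList(lapply(ann$gene, function(g)
            if (nzchar(g)) g else character())),
        tss_groups = IRanges::CharacterList(lapply(ann$tss, function(t)
            if (nzchar(t)) t else character())),
        promoter_associated = ann$promoter_associated,
        snp_overlap = ann$snp,
        island_id = ann$island)
    rownames(annot) <- annot$probe_id

    mu_b <- p$beta_base[1] / sum(p$beta_base)
    mu_h <- p$beta_hyper[1] / sum(p$beta_hyper)
    planted_db <- ifelse(hyper, p$meth_penetrance * (mu_h - mu_b), 0)
    planted_fc <- ifelse(role == "methylation-driven",
                         p$effect_slope * planted_db,
                  ifelse(role == "de-only", p$de_log2fc, 0))
    truth <- data.frame(gene = genes, role = role,
                        effect_slope = ifelse(role == "methylation-driven",
                                              p$effect_slope, 0),
                        planted_delta_beta = planted_db,
                        planted_log2fc = planted_fc,
                        background_shift = background,
                        stringsAsFactors = FALSE)
    sheet <- data.frame(sample_id = samples,
                        cimp_status = ifelse(is_h, "CIMP-H", "Non-CIMP"),
                        sample_type = "primary tumor",
                        stringsAsFactors = FALSE)
    MethExpCohort(betas, counts, annot, sheet, truth = truth)
})

#' Tiny deterministic worked-example cohort
#'
#' A 12-gene, 10+10-sample cohort with hand-checkable values, used by the
#' unit tests and the pipeline worked example. Gene F01's promoter carries
#' betas 0.1 / 0.35 / 0.6 in sample H01 (ratio summary 2/3 at the 0.3
#' cutoff); one decoy probe sits on chromosome X; gene F02 is constructed
#' with expression equal to \code{-3 *} (promoter-mean beta) plus Gaussian
#' noise of sd 0.1 so its regression-average fit is near-perfect. Genes
#' F02-F03 are methylation-driven, F04 is DM-only, F05 is DE-only.
#'
#' @return A \linkS4class{MethExpCohort}.
#' @export
workedExampleFixture <- function() .with_seed(20240601L, {
    nh <- 10L; nn <- 10L; ns <- nh + nn
    samples <- c(sprintf("H%02d", 1:nh), sprintf("N%02d", 1:nn))
    is_h <- c(rep(TRUE, nh), rep(FALSE, nn))
    genes <- sprintf("F%02d", 1:12)
    k <- c(3L, 4L, 3L, 3L, 2L, 2L, 3L, 2L, 3L, 2L, 2L, 3L)
    role <- c("null", "methylation-driven", "methylation-driven", "dm-only",
              "de-only", rep("null", 7L))
    hyper <- role %in% c("methylation-driven", "dm-only")
    m <- matrix(stats::rbeta(12L * ns, 2, 10), 12L, ns,
                dimnames = list(genes, samples))
    for (g in which(hyper)) m[g, is_h] <- stats::rbeta(nh, 10, 2)
    gene_of_probe <- rep(1:12, k)
    n_prom <- length(gene_of_probe)
    betas <- m[gene_of_probe, ] +
        matrix(stats::rnorm(n_prom * ns, sd = 0.03), n_prom, ns)
    betas <- pmin(pmax(betas, 1e-4), 1 - 1e-4)
    probe_ids <- sprintf("cg%06d", seq_len(n_prom))
    rownames(betas) <- probe_ids
    betas[gene_of_probe == 1L, "H01"] <- c(0.1, 0.35, 0.6)

    prom_mean <- rowsum(betas, gene_of_probe) / as.vector(k)
    b0 <- c(8, 12, 9, 8, 9, rep(8, 7L))
    eff <- matrix(0, 12L, ns)
    eff[2L, ] <- -3 * prom_mean[2L, ] + stats::rnorm(ns, sd = 0.1)
    eff[3L, ] <- -3 * prom_mean[3L, ] + stats::rnorm(ns, sd = 0.2)
    eff[5L, is_h] <- -2
    rel <- 2^(b0 + eff)
    prop <- sweep(rel, 2L, colSums(rel), "/")
    counts <- matrix(stats::rnbinom(12L * ns, mu = sweep(prop, 2L, 5e4, "*"),
                                    size = 200), 12L, ns,
                     dimnames = list(genes, samples))

    ann <- data.frame(probe_id = probe_ids,
                      chrom = as.character(rep(1:12, k)),
                      pos = 1000L + 50L * seq_len(n_prom),
                      gene = genes[gene_of_probe],
                      tss = rep("TSS1500", n_prom),
                      promoter_associated = FALSE, snp = FALSE,
                      island = paste0("isl_", genes[gene_of_probe]),
                      stringsAsFactors = FALSE)
    decoy <- data.frame(probe_id = "cg900001", chrom = "X", pos = 99000L,
                        gene = "", tss = "", promoter_associated = FALSE,
                        snp = FALSE, island = NA_character_,
                        stringsAsFactors = FALSE)
    ann <- rbind(ann, decoy)
    betas <- rbind(betas, cg900001 = stats::rbeta(ns, 2, 10))
    annot <- S4Vectors::DataFrame(
        probe_id = ann$probe_id, chrom = ann$chrom, pos = as.integer(ann$pos),
        genes = IRanges::CharacterList(lapply(ann$gene, function(g)
            if (nzchar(g)) g else character())),
        tss_groups = IRanges::CharacterList(lapply(ann$tss, function(t)
            if (nzchar(t)) t else character())),
        promoter_associated = ann$promoter_associated,
        snp_overlap = ann$snp, island_id = ann$island)
    rownames(annot) <- annot$probe_id
    truth <- data.frame(gene = genes, role = role,
                        effect_slope = ifelse(role == "methylation-driven",
                                              -3, 0),
                        planted_delta_beta = ifelse(hyper, 10/12 - 2/12, 0),
                        planted_log2fc = ifelse(role == "methylation-driven",
                                                -3 * (10/12 - 2/12),
                                         ifelse(role == "de-only", -2, 0)),
                        background_shift = FALSE, stringsAsFactors = FALSE)
    sheet <- data.frame(sample_id = samples,
                        cimp_status = ifelse(is_h, "CIMP-H", "Non-CIMP"),
                        sample_type = "primary tumor",
                        stringsAsFactors = FALSE)
    MethExpCohort(betas, counts, annot, sheet, truth = truth)
})
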