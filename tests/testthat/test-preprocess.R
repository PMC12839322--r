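make_filter_fixture <- function() {
    ids <- paste0("cg", 1:10)
    ann <- make_annot(ids)
    ann$chrom <- c("X", "X", rep("1", 8))
    ann$snp_overlap <- c(rep(FALSE, 2), TRUE, rep(FALSE, 7))
    set.seed(5)
    b <- matrix(runif(40, 0.05, 0.95), 10, 4,
                dimnames = list(ids, paste0("s", 1:4)))
    b["cg4", "s2"] <- NA
    list(ann = ann, betas = b)
}

test_that("probe filtering removes sex-chromosome, SNP and missing probes", {
    fx <- make_filter_fixture()
    fl <- filterProbes(fx$ann, fx$betas)
    expect_equal(nrow(fl$betas), 6L)
    expect_false(any(c("cg1", "cg2", "cg3", "cg4") %in% rownames(fl$betas)))
    rpt <- setNames(fl$report$n, fl$report$reason)
    expect_equal(rpt[["sex_chromosome"]], 2)
    expect_equal(rpt[["snp_overlap"]], 1)
    expect_equal(rpt[["missing_values"]], 1)
    expect_equal(rpt[["removed_total"]], 4)
})

test_that("a probe failing several filters is removed once, counted per reason", {
    fx <- make_filter_fixture()
    fx$betas["cg1", "s1"] <- NA  # X probe that also has a missing value
    fl <- filterProbes(fx$ann, fx$betas)
    rpt <- setNames(fl$report$n, fl$report$reason)
    expect_equal(rpt[["sex_chromosome"]], 2)
    expect_equal(rpt[["missing_values"]], 2)
    expect_equal(rpt[["removed_total"]], 4)
    expect_equal(nrow(fl$betas), 6L)
})

test_that("filtering is an identity on clean input and idempotent", {
    ids <- paste0("cg", 1:5)
    ann <- make_annot(ids)
    set.seed(6)
    b <- matrix(runif(20, 0.1, 0.9), 5, 4, dimnames = list(ids, paste0("s", 1:4)))
    fl <- filterProbes(ann, b)
    expect_identical(fl$betas, b)
    fx <- make_filter_fixture()
    once <- filterProbes(fx$ann, fx$betas)
    twice <- filterProbes(fx$ann, once$betas)
    expect_identical(twice$betas, once$betas)
    expect_error(filterProbes(fx$ann[1:3, ], fx$betas), "without annotation")
})

test_that("promoter map follows TSS1500/TSS200 and the promoter-associated flag", {
    ann <- rbind(
        make_annot("cg1", gene = "MLH1", tss = "TSS1500"),
        make_annot("cg2", gene = "GENE2", tss = "Body"),
        make_annot("cg3", gene = "GENE3", tss = "Body",
                   promoter_associated = TRUE),
        make_annot("cg4", gene = "MLH1", tss = "TSS200"))
    map <- buildPromoterMap(ann, ann$probe_id)
    expect_equal(sort(map[["MLH1"]]), c("cg1", "cg4"))
    expect_equal(map[["GENE3"]], "cg3")
    expect_false("GENE2" %in% names(map))
    # probes dropped by filtering never enter the map
    map2 <- buildPromoterMap(ann, c("cg2", "cg3"))
    expect_equal(names(map2), "GENE3")
})

test_that("promoter summaries match the average and ratio definitions", {
    ann <- make_annot(paste0("cg", 1:3), gene = "F1")
    b <- matrix(c(0.1, 0.35, 0.6), 3, 1,
                dimnames = list(paste0("cg", 1:3), "s1"))
    map <- buildPromoterMap(ann, rownames(b))
    expect_equal(summarizePromoter(b, map, "average")["F1", "s1"], 0.35)
    expect_equal(summarizePromoter(b, map, "ratio", beta_min = 0.3)["F1", "s1"],
                 2 / 3)
    # boundary beta counts as methylated (>= cutoff)
    b1 <- matrix(0.3, 1, 1, dimnames = list("cg1", "s1"))
    map1 <- buildPromoterMap(make_annot("cg1", gene = "F1"), "cg1")
    expect_equal(summarizePromoter(b1, map1, "ratio", beta_min = 0.3)[1, 1], 1)
})

test_that("promoter summaries are order-invariant and monotone in any beta", {
    set.seed(7)
    ids <- paste0("cg", 1:6)
    ann <- make_annot(ids, gene = "G")
    b <- matrix(runif(24, 0.05, 0.95), 6, 4, dimnames = list(ids, paste0("s", 1:4)))
    map <- buildPromoterMap(ann, ids)
    for (metric in c("average", "ratio")) {
        ref <- summarizePromoter(b, map, metric)
        perm <- b[sample(ids), , drop = FALSE]
        expect_equal(summarizePromoter(perm, map, metric), ref)
        for (k in 1:10) {
            b2 <- b
            i <- sample(6, 1); j <- sample(4, 1)
            b2[i, j] <- min(1, b2[i, j] + runif(1, 0, 0.5))
            expect_true(all(summarizePromoter(b2, map, metric) >= ref - 1e-12))
        }
    }
    expect_error(summarizePromoter(b[1:3, ], map, "average"), "absent")
})

test_that("TMM factors are 1 for proportional or identical libraries", {
    set.seed(8)
    a <- rnbinom(150, mu = 100, size = 10) + 1L
    counts <- cbind(s1 = a, s2 = 3L * a)
    rownames(counts) <- paste0("g", seq_along(a))
    norm <- tmmNormalize(counts)
    expect_equal(unname(norm$tmm_factors), c(1, 1))
    same <- cbind(s1 = a, s2 = a, s3 = a)
    rownames(same) <- rownames(counts)
    expect_equal(unname(tmmNormalize(same)$tmm_factors), c(1, 1, 1))
    expect_error(tmmNormalize(counts[, 1, drop = FALSE]), "two samples")
})

test_that("TMM matches the reference implementation on an NB fixture", {
    skip_if_not_installed("edgeR")
    set.seed(4242)
    counts <- matrix(rnbinom(800, mu = 200, size = 10), 200, 4,
                     dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
    infl <- sample(200, 20)
    counts[infl, 1] <- counts[infl, 1] * 4L
    mine <- tmmNormalize(counts)$tmm_factors
    ref <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
    expect_lt(max(abs(unname(mine) - ref)), 1e-6)
})

test_that("TMM factor product is 1 and scaling one library barely moves factors", {
    skip_if_not_installed("edgeR")
    set.seed(9)
    for (rep in 1:5) {
        counts <- matrix(rnbinom(600, mu = exp(runif(150, 3, 7)), size = 8),
                         150, 4,
                         dimnames = list(paste0("g", 1:150), paste0("s", 1:4)))
        counts <- counts + 1L
        f <- tmmNormalize(counts)$tmm_factors
        expect_equal(prod(f), 1, tolerance = 1e-12)
        scaled <- counts
        j <- sample(4, 1)
        scaled[, j] <- scaled[, j] * 5L
        f2 <- tmmNormalize(scaled)$tmm_factors
        # exact invariance is broken only by the inverse-variance weights;
        # the reference implementation agrees bit-for-bit
        expect_lt(max(abs(f2 - f)), 0.02)
        ref2 <- edgeR::calcNormFactors(edgeR::DGEList(scaled))$samples$norm.factors
        expect_lt(max(abs(unname(f2) - ref2)), 1e-9)
    }
})

test_that("log2-CPM follows the contracted transform and is finite", {
    set.seed(10)
    counts <- matrix(rnbinom(300, mu = 150, size = 10), 75, 4,
                     dimnames = list(paste0("g", 1:75), paste0("s", 1:4)))
    norm <- tmmNormalize(counts)
    expect_true(all(is.finite(norm$log2cpm)))
    g <- "g1"; s <- "s2"
    expected <- log2((counts[g, s] + 0.5) /
                     (norm$lib_sizes[s] * norm$tmm_factors[s] + 1) * 1e6)
    expect_equal(norm$log2cpm[g, s], unname(expected))
})
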