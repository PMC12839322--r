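groups_2x3 <- c(a1 = "CIMP-H", a2 = "CIMP-H", a3 = "CIMP-H",
                b1 = "Non-CIMP", b2 = "Non-CIMP", b3 = "Non-CIMP")

test_that("delta beta and log2FC are group-mean differences with Welch p-values", {
    m <- rbind(G = c(0.6, 0.7, 0.65, 0.2, 0.25, 0.3),
               H = c(0.5, 0.55, 0.6, 0.5, 0.55, 0.6))
    colnames(m) <- names(groups_2x3)
    dm <- diffMethylation(m, groups_2x3)
    expect_equal(dm$delta_beta[1], mean(c(0.6, 0.7, 0.65)) - mean(c(0.2, 0.25, 0.3)))
    # independent oracle: direct Welch formula
    x <- c(0.6, 0.7, 0.65); y <- c(0.2, 0.25, 0.3)
    tt <- t.test(x, y)
    expect_equal(dm$p[1], tt$p.value, tolerance = 1e-12)
    expect_equal(dm$delta_beta[2], 0)
    expect_equal(dm$p[2], 1)

    e <- rbind(G = c(5, 5.2, 4.8, 6.5, 6.4, 6.6))
    colnames(e) <- names(groups_2x3)
    de <- diffExpression(e, groups_2x3)
    expect_equal(de$log2fc[1], mean(c(5, 5.2, 4.8)) - mean(c(6.5, 6.4, 6.6)))
    expect_equal(de$p[1], t.test(c(5, 5.2, 4.8), c(6.5, 6.4, 6.6))$p.value,
                 tolerance = 1e-12)
    expect_error(diffMethylation(m[, 1:3, drop = FALSE],
                                 groups_2x3[1:3]), "at least 2 samples")
})

test_that("row-wise Welch matches t.test across random matrices", {
    set.seed(31)
    m <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    grp <- setNames(rep(c("CIMP-H", "Non-CIMP"), each = 5), colnames(m))
    dm <- diffMethylation(m, grp)
    for (i in 1:20) {
        tt <- t.test(m[i, 1:5], m[i, 6:10])
        expect_equal(dm$p[i], tt$p.value, tolerance = 1e-12)
        expect_equal(dm$delta_beta[i], unname(diff(rev(tt$estimate))),
                     tolerance = 1e-12)
    }
})

test_that("swapping group labels negates effects and preserves p-values", {
    set.seed(32)
    m <- matrix(runif(60, 0.1, 0.9), 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    grp <- setNames(rep(c("CIMP-H", "Non-CIMP"), each = 5), colnames(m))
    swapped <- setNames(rep(c("Non-CIMP", "CIMP-H"), each = 5), colnames(m))
    a <- diffMethylation(m, grp); b <- diffMethylation(m, swapped)
    expect_equal(a$delta_beta, -b$delta_beta)
    expect_equal(a$p, b$p)
})

test_that("BH adjustment reproduces hand and brute-force step-up results", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.5), 0.5)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_error(bhAdjust(c(0.1, 1.3)), "\\[0, 1\\]")
    # brute-force oracle: adj_i = min_{j >= rank(i)} m * p_(j) / j
    brute_bh <- function(p) {
        m <- length(p); o <- order(p); adj <- numeric(m)
        for (r in seq_len(m)) {
            vals <- vapply(r:m, function(j) m * p[o[j]] / j, numeric(1))
            adj[o[r]] <- min(1, min(vals))
        }
        adj
    }
    set.seed(33)
    for (rep in 1:50) {
        p <- runif(sample(1:12, 1))
        expect_equal(bhAdjust(p), brute_bh(p), tolerance = 1e-15)
        expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-15)
    }
    # NA propagation
    p <- c(0.01, NA, 0.04)
    adj <- bhAdjust(p)
    expect_true(is.na(adj[2]))
    expect_equal(adj[c(1, 3)], p.adjust(p, "BH")[c(1, 3)])
})

test_that("five-way classification reproduces the worked cases", {
    cfg <- analysisConfig()
    # strongly hypermethylated, downregulated mismatch-repair gene
    expect_equal(classifyGenes(0.2696, -1.6650, 1.005e-18, 4.159e-21, cfg),
                 "hyper-down")
    # hypermethylated but upregulated
    expect_equal(classifyGenes(0.2325, 1.3267, 2.510e-30, 5.290e-13, cfg),
                 "hyper-up")
    # differentially methylated but flat expression stays not-significant
    expect_equal(classifyGenes(0.26, 0.09, 1e-6, 0.4, cfg),
                 "not-significant")
    expect_equal(classifyGenes(-0.25, -1.5, 1e-4, 1e-4, cfg), "hypo-down")
    expect_equal(classifyGenes(-0.25, 1.5, 1e-4, 1e-4, cfg), "hypo-up")
    # boundary: effects at the threshold count, p at alpha does not
    expect_equal(classifyGenes(0.2, -1.3, 0.049, 0.049, cfg), "hyper-down")
    expect_equal(classifyGenes(0.2, -1.3, 0.05, 0.01, cfg), "not-significant")
})

test_that("each gene lands in exactly one category and significance needs both omics", {
    set.seed(34)
    n <- 300
    db <- runif(n, -0.5, 0.5); fc <- runif(n, -3, 3)
    mp <- runif(n); ep <- runif(n)
    cat <- classifyGenes(db, fc, mp, ep)
    expect_equal(length(cat), n)
    expect_true(all(cat %in% c("hyper-down", "hyper-up", "hypo-down",
                               "hypo-up", "not-significant")))
    sig <- cat != "not-significant"
    expect_true(all(mp[sig] < 0.05 & ep[sig] < 0.05))
    expect_true(all(abs(db[sig]) >= 0.2 & abs(fc[sig]) >= 1.3))
})

test_that("planted silenced genes are detected as differentially expressed", {
    cohort <- simulateCohort(cohortParams(), seed = 11)
    res <- run_cohort_analysis(cohort, score = FALSE)
    md <- res$truth$gene[res$truth$role == "methylation-driven"]
    rec <- res$differential[match(md, res$differential$gene), ]
    expect_true(all(rec$log2fc <= -1.3))
    expect_true(all(rec$expr_adj_p < 0.05))
    expect_true(all(rec$category == "hyper-down"))
    # adjusted p never below raw p
    expect_true(all(res$differential$meth_adj_p >= res$differential$meth_p))
    expect_true(all(res$differential$expr_adj_p >= res$differential$expr_p))
})
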