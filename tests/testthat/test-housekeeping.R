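test_that("distribution statistics follow textbook formulas", {
    st <- hkStats(rbind(t1 = rep(100, 10), t2 = 1:10))
    expect_equal(st$sd[1], 0)
    expect_equal(st$cv_percent[1], 0)
    expect_equal(st$mean[2], 5.5)
    expect_equal(st$sd[2], 3.02765, tolerance = 1e-5)
    expect_equal(st$median[2], 5.5)
    expect_equal(st$minimum[2], 1)
    expect_equal(st$maximum[2], 10)
    expect_equal(st$cv_percent[2], 100 * sd(1:10) / 5.5)
    expect_error(hkStats(rbind(a = 1:4), candidates = c("a", "zz")), "zz")
})

test_that("CV% is scale invariant", {
    set.seed(2)
    x <- matrix(rgamma(40, 20, 0.1), nrow = 4,
                dimnames = list(paste0("t", 1:4), NULL))
    for (c in c(0.01, 1, 250))
        expect_equal(hkStats(c * x)$cv_percent, hkStats(x)$cv_percent,
                     tolerance = 1e-12)
})

test_that("the published reference-gene table reproduces its CV column", {
    tab <- hk_reference_table()
    st <- hkStatsFromSummary(tab)
    cv <- setNames(round(st$cv_percent, 2), st$transcript_id)
    expect_equal(unname(cv["ef1a0"]), 8.00)
    expect_equal(unname(cv["ef1d"]), 10.66)
    expect_equal(unname(cv["tubb"]), 13.58)
    expect_equal(unname(cv["tuba"]), 7.81)
    expect_equal(unname(cv["ef1g-a"]), 8.45)
})

test_that("CV threshold selection is strict, sorted and warns when empty", {
    st <- hkStatsFromSummary(hk_reference_table())
    sel <- selectHK(st, cv_max = 20)
    expect_equal(nrow(sel), 9)
    expect_setequal(setdiff(st$transcript_id, sel$transcript_id),
                    c("tuba1", "g3pdh", "acta4"))
    expect_true(all(diff(sel$cv_percent) >= 0))

    sel10 <- selectHK(st, cv_max = 10)
    expect_equal(sel10$transcript_id, c("tuba", "ef1a0", "ef1g-a"))

    zero <- data.frame(transcript_id = c("a", "b"), mean = c(1, 2),
                       sd = c(0, 0), cv_percent = c(0, 0))
    expect_equal(nrow(selectHK(zero)), 2)
    expect_warning(out <- selectHK(st, cv_max = 5), "no transcript")
    expect_equal(nrow(out), 0)
})

test_that("standardization factors follow the hand-computed ratios", {
    # HK1: control mean 100, sample value 120; HK2: control mean 50, value 55
    x <- rbind(hk1 = c(100, 100, 120), hk2 = c(50, 50, 55),
               g1 = c(10, 12, 23))
    colnames(x) <- c("c1", "c2", "t1")
    d <- data.frame(sample_id = colnames(x),
                    treatment = c("control", "control", "trt"))
    out <- standardize(x, c("hk1", "hk2"), d)
    expect_equal(out$factors$factor[3], (1.2 + 1.1) / 2)  # 1.15
    expect_equal(out$standardized["g1", "t1"], 23 / 1.15)
    # control factors average exactly 1
    expect_equal(mean(out$factors$factor[1:2]), 1, tolerance = 1e-12)
    # relative-to-control column is 1 for every row
    expect_true(all(out$relative[, "control"] == 1))
})

test_that("constant housekeeping genes leave the matrix untouched", {
    x <- rbind(hk = rep(42, 6), g = c(1, 2, 3, 4, 5, 6))
    colnames(x) <- paste0("s", 1:6)
    d <- data.frame(sample_id = colnames(x),
                    treatment = rep(c("control", "a", "b"), each = 2))
    out <- standardize(x, "hk", d)
    expect_equal(out$factors$factor, rep(1, 6))
    expect_equal(out$standardized, x)
})

test_that("standardization guards its degenerate inputs", {
    x <- rbind(hk = c(0, 0, 5, 5), g = c(1, 2, 3, 4))
    colnames(x) <- paste0("s", 1:4)
    d <- data.frame(sample_id = colnames(x),
                    treatment = c("control", "control", "t", "t"))
    expect_error(standardize(x, "hk", d), "zero control mean")
    d2 <- d; d2$treatment <- c("a", "a", "b", "b")
    expect_error(standardize(x, "hk", d2), "control")
    expect_error(standardize(x, character(0), d), "empty")
})

test_that("per-treatment mode averages factors over replicates", {
    x <- rbind(hk = c(100, 100, 110, 130), g = c(9, 11, 30, 50))
    colnames(x) <- paste0("s", 1:4)
    d <- data.frame(sample_id = colnames(x),
                    treatment = c("control", "control", "t", "t"))
    out <- standardize(x, "hk", d, mode = "per_treatment")
    expect_equal(out$factors$factor[3], out$factors$factor[4])
    expect_equal(out$factors$factor[3], (1.1 + 1.3) / 2)
})

test_that("selection recovers designated housekeeping genes in simulation", {
    s <- tiny_sim(n_genes = 600, seed = 15)
    fe <- tmmNormalize(s$experiment)
    gt <- collapseFragments(SummarizedExperiment::assay(fe, "tmm"),
                            fragmentGenes(fe))
    sel <- selectHK(hkStats(gt), cv_max = 20)
    true_hk <- s$truth$gene_id[s$truth$is_hk]
    expect_gte(length(intersect(sel$transcript_id, true_hk)) /
               length(true_hk), 0.9)
    non_hk <- setdiff(s$truth$gene_id, true_hk)
    expect_lte(length(intersect(sel$transcript_id, non_hk)) /
               length(non_hk), 0.1)
})

test_that("housekeeping relative expression stays near 1 after standardization", {
    s <- tiny_sim(n_genes = 400, seed = 23)
    fe <- tmmNormalize(s$experiment)
    gt <- collapseFragments(SummarizedExperiment::assay(fe, "tmm"),
                            fragmentGenes(fe))
    hk <- s$truth$gene_id[s$truth$is_hk]
    out <- standardize(gt, hk, s$design)
    for (t in setdiff(colnames(out$relative), "control"))
        expect_equal(mean(out$relative[hk, t]), 1, tolerance = 0.05)
})
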