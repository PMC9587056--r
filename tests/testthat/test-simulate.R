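test_that("design table matches the experimental layout", {
    cfg <- tiny_config()
    d <- generateDesign(cfg)
    expect_equal(nrow(d), 10)  # 5 groups x 2 replicates
    expect_equal(as.character(unique(d$treatment)),
                 c("control", "AZM6", "AZM24", "CPF6", "CPF24"))
    expect_false(anyDuplicated(d$sample_id) > 0)

    d2 <- generateDesign(simulationConfig(
        treatments = c("control", "T1"), n_replicates = 3, seed = 1))
    expect_equal(nrow(d2), 6)

    # byte-identical under a fixed seed
    f1 <- tempfile(); f2 <- tempfile()
    writeSampleDesign(generateDesign(cfg), f1)
    writeSampleDesign(generateDesign(cfg), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid configurations are rejected naming the field", {
    expect_error(simulationConfig(n_replicates = 1), "n_replicates")
    expect_error(simulationConfig(frac_affected = 1.2), "frac_affected")
    expect_error(simulationConfig(fragments_per_gene = c(0, 3)),
                 "fragments_per_gene")
    expect_error(simulationConfig(treatments = c("a", "b"), control = "c"),
                 "control")
    expect_error(simulationConfig(nb_dispersion = 0), "nb_dispersion")
})

test_that("counts are reproducible nonnegative integers with full truth coverage", {
    s1 <- tiny_sim(seed = 7)
    s2 <- tiny_sim(seed = 7)
    c1 <- SummarizedExperiment::assay(s1$experiment, "counts")
    expect_identical(c1, SummarizedExperiment::assay(s2$experiment, "counts"))
    expect_identical(s1$truth, s2$truth)
    expect_true(all(c1 >= 0))
    expect_true(all(c1 == round(c1)))
    expect_setequal(s1$truth$gene_id,
                    unique(fragmentGenes(s1$experiment)))
    expect_false(anyDuplicated(s1$truth$gene_id) > 0)
})

test_that("null configuration plants no effects", {
    s <- tiny_sim(frac_affected = 0)
    effcols <- grep("^log2_effect_", colnames(s$truth))
    expect_true(all(s$truth[, effcols] == 0))
})

test_that("housekeeping genes have zero effect and bad fragments belong to their gene", {
    s <- tiny_sim(n_genes = 100, seed = 12)
    effcols <- grep("^log2_effect_", colnames(s$truth))
    expect_true(all(s$truth[s$truth$is_hk, effcols] == 0))
    bad <- s$truth$bad_fragment_ids
    for (i in which(bad != "")) {
        ids <- strsplit(bad[i], ",")[[1]]
        expect_true(all(fragmentGenes(s$experiment)[ids] ==
                        s$truth$gene_id[i]))
    }
    # rowData flags agree with the truth table
    flagged <- rownames(s$experiment)[
        SummarizedExperiment::rowData(s$experiment)$is_bad]
    expect_setequal(flagged,
                    unlist(strsplit(bad[bad != ""], ",")))
})

test_that("planted down:up proportion follows the configured 3:1 odds", {
    cfg <- simulationConfig(n_genes = 2000, frac_affected = 0.3,
                            down_up_ratio = 3, seed = 42)
    sim <- generateCounts(generateDesign(cfg), cfg)
    eff <- sim$truth$log2_effect_AZM6
    n_down <- sum(eff < 0); n_up <- sum(eff > 0)
    # binomial tolerance around p = 3/4
    p_hat <- n_down / (n_down + n_up)
    se <- sqrt(0.75 * 0.25 / (n_down + n_up))
    expect_lt(abs(p_hat - 0.75), 4 * se)
})

test_that("per-gene empirical means track the configured NB means", {
    cfg <- simulationConfig(n_genes = 500, nb_dispersion = 0.05,
                            frac_affected = 0, n_hk_genes = 0,
                            library_size_cv = 0, frac_bad_fragments = 0,
                            fragments_per_gene = c(1, 1), seed = 9)
    d <- generateDesign(cfg)
    sim <- generateCounts(d, cfg)
    counts <- SummarizedExperiment::assay(sim$experiment, "counts")
    # one fragment per gene, no effects/library variation: every sample
    # shares the configured mean mu = baseline abundance
    mu <- sim$truth$baseline_abundance
    se <- sqrt((mu + 0.05 * mu^2) / ncol(counts))
    ok <- abs(rowMeans(counts) - mu) <= 3 * se
    expect_gte(mean(ok), 0.95)
})

test_that("housekeeping genes realize their CV target after normalization", {
    s <- tiny_sim(n_genes = 400, seed = 5)
    fe <- tmmNormalize(s$experiment)
    gene_tmm <- collapseFragments(SummarizedExperiment::assay(fe, "tmm"),
                                  fragmentGenes(fe))
    hk <- s$truth$gene_id[s$truth$is_hk]
    st <- hkStats(gene_tmm, hk)
    expect_gte(mean(st$cv_percent < s$config@hk_cv_target), 0.9)
})

test_that("alignment hits respect the configured confirmation rate", {
    cfg <- tiny_config(n_genes = 80, seed = 2)
    frags <- sprintf("f%03d", 1:225)
    genes <- sprintf("g%03d", rep(1:75, each = 3))
    ah <- generateAlignmentHits(frags, genes, confirm_rate = 0.938,
                                config = cfg)
    rep_conf <- confirmAnnotation(ah)
    expect_equal(rep_conf$summary$n_pass, round(0.938 * 225))  # 211
    expect_equal(round(rep_conf$summary$percent_pass, 1), 93.8)

    ah1 <- generateAlignmentHits(frags, genes, confirm_rate = 1, config = cfg)
    expect_equal(confirmAnnotation(ah1)$summary$percent_pass, 100)
    ah0 <- generateAlignmentHits(frags, genes, confirm_rate = 0, config = cfg)
    expect_equal(confirmAnnotation(ah0)$summary$percent_pass, 0)
})

test_that("qPCR generator encodes effects and noise on the Ct scale", {
    cfg <- tiny_config(n_genes = 60, seed = 8, frac_affected = 0.5,
                       effect_log2_range = c(log2(3), log2(3)))
    d <- generateDesign(cfg)
    sim <- generateCounts(d, cfg)
    ct <- generateQpcr(d, sim$truth, efficiency = 2, ct_noise_sd = 0,
                       config = cfg)
    tgt <- unique(ct$gene_id[ct$role == "target"])[1]
    ct_ctrl <- ct$ct[ct$gene_id == tgt & grepl("^control", ct$sample_id)][1]
    ct_trt <- ct$ct[ct$gene_id == tgt & grepl("^AZM6", ct$sample_id)][1]
    eff <- sim$truth$log2_effect_AZM6[sim$truth$gene_id == tgt]
    expect_equal(ct_ctrl - ct_trt, eff, tolerance = 1e-12)
    # an induced 3x gene is ~1.585 cycles earlier
    expect_equal(abs(ct_ctrl - ct_trt), log2(3), tolerance = 1e-12)

    hk <- unique(ct$gene_id[ct$role == "hk"])[1]
    expect_equal(length(unique(ct$ct[ct$gene_id == hk])), 1L)

    expect_error(generateQpcr(d, sim$truth, efficiency = 1, config = cfg),
                 "efficiency")

    # noisy draws: empirical SD about the requested value
    cfgN <- tiny_config(n_genes = 60, seed = 8, frac_affected = 0.5,
                        n_replicates = 500,
                        effect_log2_range = c(log2(3), log2(3)))
    dN <- generateDesign(cfgN)
    ctN <- generateQpcr(dN, sim$truth, efficiency = 2, ct_noise_sd = 0.2,
                        config = cfgN,
                        target_genes = tgt, hk_genes = hk)
    v <- ctN$ct[ctN$gene_id == hk & grepl("^control", ctN$sample_id)]
    expect_equal(sd(v), 0.2, tolerance = 0.05)
})
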