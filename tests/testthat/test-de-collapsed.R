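test_that("common dispersion recovery brackets the simulated truth", {
    set.seed(41)
    d <- data.frame(sample_id = paste0("s", 1:10),
                    treatment = rep(c("c", "a", "b", "d", "e"), each = 2))
    # Poisson counts: estimate collapses to ~0
    mu <- rep(exp(rnorm(2000, 5, 1)), each = 1)
    pois <- matrix(rpois(2000 * 10, mu), nrow = 2000,
                   dimnames = list(paste0("g", 1:2000), d$sample_id))
    expect_lte(estimateCommonDispersion(pois, d), 0.02)

    # NB with phi = 0.1
    nb <- matrix(rnbinom(2000 * 10, mu = mu, size = 10), nrow = 2000,
                 dimnames = list(paste0("g", 1:2000), d$sample_id))
    phi_hat <- estimateCommonDispersion(nb, d)
    expect_gte(phi_hat, 0.05)
    expect_lte(phi_hat, 0.2)

    # constant single gene: zero variance
    flat <- matrix(100, 1, 10, dimnames = list("g1", d$sample_id))
    expect_equal(estimateCommonDispersion(flat, d, min_mean = 0), 0)

    d_norep <- data.frame(sample_id = paste0("s", 1:2),
                          treatment = c("a", "b"))
    expect_error(estimateCommonDispersion(flat[, 1:2, drop = FALSE],
                                          d_norep), "replication")
})

test_that("NB exact test matches the exhaustive split oracle", {
    # worked case: total 20 split 15 vs 5, equal libraries, phi = 0.1
    r <- nbExactTest(c(8, 7), c(3, 2), phi = 0.1)
    expect_equal(r$p, oracle_nb_p(15, 5, 2, 2, 0.1), tolerance = 1e-10)

    set.seed(55)
    for (i in 1:60) {
        n1 <- sample(1:3, 1); n2 <- sample(1:3, 1)
        T <- sample(0:50, 1)
        s1 <- sample(0:T, 1)
        phi <- sample(c(0, 0.05, 0.2, 1), 1)
        y1 <- c(s1, rep(0, n1 - 1))
        y2 <- c(T - s1, rep(0, n2 - 1))
        r <- nbExactTest(y1, y2, phi = phi)
        expect_equal(r$p, oracle_nb_p(s1, T - s1, n1, n2, phi),
                     tolerance = 1e-10,
                     info = sprintf("T=%d s1=%d n1=%d n2=%d phi=%g",
                                    T, s1, n1, n2, phi))
    }
})

test_that("NB exact test is symmetric, antisymmetric, and guarded", {
    r0 <- nbExactTest(c(5, 5), c(5, 5), phi = 0.1)
    expect_equal(r0$p, 1)
    expect_equal(r0$log2FC, 0)

    a <- nbExactTest(c(9, 6), c(3, 2), phi = 0.1)
    b <- nbExactTest(c(3, 2), c(9, 6), phi = 0.1)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)

    z <- nbExactTest(c(0, 0), c(0, 0), phi = 0.1)
    expect_equal(z$p, 1)
    expect_equal(z$log2FC, 0)
})

test_that("windowed large-total computation agrees with full enumeration", {
    y1 <- c(3100, 2900); y2 <- c(2400, 2500)
    full <- nbExactTest(y1, y2, phi = 0.08, max_enumerate = 1e6)
    win <- nbExactTest(y1, y2, phi = 0.08, max_enumerate = 100)
    expect_equal(win$p, full$p, tolerance = 1e-9)
})

test_that("null NB p-values are super-uniform", {
    set.seed(66)
    n_sim <- 2000
    p <- numeric(n_sim)
    for (i in seq_len(n_sim)) {
        y1 <- rnbinom(2, mu = 100, size = 10)
        y2 <- rnbinom(2, mu = 100, size = 10)
        p[i] <- nbExactTest(y1, y2, phi = 0.1)$p
    }
    expect_lte(mean(p <= 0.01), 0.01 + 0.01)
    expect_lte(mean(p <= 0.05), 0.05 + 0.01)
})

test_that("DEG calling obeys both thresholds and is monotone", {
    res <- data.frame(gene_id = paste0("g", 1:4),
                      log2FC = c(1.5, 0.8, -1.2, -1.2),
                      p = c(0.01, 0.001, 0.06, 0.04))
    out <- callDEGs(res)
    expect_equal(out$call, c("up", "none", "none", "down"))
    # tightening thresholds never adds calls
    loose <- callDEGs(res, fc_threshold = 1.5, p_max = 0.1)
    tight <- callDEGs(res, fc_threshold = 4, p_max = 0.01)
    expect_true(all(tight$call == "none" | tight$call == loose$call))
    expect_lte(sum(tight$call != "none"), sum(loose$call != "none"))
})

test_that("ranking orders by |log2FC| and assigns the published bins", {
    set.seed(77)
    res <- data.frame(gene_id = sprintf("g%04d", 1:700),
                      log2FC = rnorm(700, 0, 2),
                      p = runif(700, 0, 0.05))
    res <- rankDEGs(callDEGs(res, fc_threshold = 1.1))
    called <- res[!is.na(res$rank), ]
    called <- called[order(called$rank), ]
    expect_true(all(diff(abs(called$log2FC)) <= 1e-12))
    expect_equal(sort(called$rank), seq_len(nrow(called)))
    expect_equal(called$bin[called$rank == 7], "top-10")
    if (any(called$rank == 600))
        expect_equal(called$bin[called$rank == 600], "500-1500")
    expect_true(all(res$bin[res$call == "none"] == "NS"))
})

test_that("collapsing then testing equals testing a one-fragment matrix directly", {
    cfg <- simulationConfig(n_genes = 60, fragments_per_gene = c(1, 1),
                            frac_bad_fragments = 0, seed = 19)
    d <- generateDesign(cfg)
    sim <- generateCounts(d, cfg)
    counts <- SummarizedExperiment::assay(sim$experiment, "counts")
    gc <- collapseFragments(counts, fragmentGenes(sim$experiment))
    expect_equal(unname(gc[order(rownames(gc)), ]),
                 unname(counts[order(fragmentGenes(sim$experiment)), ]))
})

test_that("the collapsed pipeline recovers 4-fold effects with correct direction", {
    cfg <- simulationConfig(n_genes = 300, fragments_per_gene = c(3, 3),
                            effect_log2_range = c(2, 2),
                            frac_affected = 0.4, seed = 27)
    d <- generateDesign(cfg)
    sim <- generateCounts(d, cfg)
    nb <- nbDE(sim$experiment)
    eff <- sim$truth$log2_effect_AZM6
    affected <- sim$truth$gene_id[eff != 0]
    res <- nb$results[nb$results$pair == "AZM6", ]
    res <- res[match(affected, res$gene_id), ]
    truth_dir <- ifelse(eff[eff != 0] > 0, "up", "down")
    expect_gte(mean(res$call == truth_dir), 0.8)
    expect_lte(abs(median(res$log2FC - eff[eff != 0])), 0.5)
})
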