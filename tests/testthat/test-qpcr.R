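qpcr_design <- function() {
    data.frame(sample_id = c("c1", "c2", "t1", "t2"),
               treatment = c("control", "control", "CPF6", "CPF6"))
}

test_that("a target tracking the HK gene self-normalizes to FC 1", {
    d <- qpcr_design()
    ct <- expand.grid(sample_id = d$sample_id,
                      gene_id = c("tgt", "hk1"),
                      stringsAsFactors = FALSE)
    ct$role <- ifelse(ct$gene_id == "hk1", "hk", "target")
    ct$ct <- rep(c(24, 25, 23, 26), 2)  # target Ct == HK Ct per sample
    out <- relativeExpression(ct, d)
    expect_true(all(abs(out$fc$fold_change[out$fc$gene_id == "tgt"] - 1)
                    < 1e-12))
})

test_that("noise-free planted inductions are inverted exactly", {
    cfg <- tiny_config(n_genes = 80, seed = 44, frac_affected = 0.5)
    d <- generateDesign(cfg)
    sim <- generateCounts(d, cfg)
    ct <- generateQpcr(d, sim$truth, ct_noise_sd = 0, config = cfg)
    out <- relativeExpression(ct, d)
    for (g in unique(ct$gene_id[ct$role == "target"])) {
        for (t in c("AZM6", "CPF24")) {
            planted <- 2^sim$truth[[paste0("log2_effect_", t)]][
                sim$truth$gene_id == g]
            got <- out$fc$fold_change[out$fc$gene_id == g &
                                      out$fc$treatment == t]
            expect_equal(got, planted, tolerance = 1e-9)
        }
    }
})

test_that("an induced and a repressed target recover their directions", {
    # a CPF-induction scenario: ~3x up on one target, down on another
    cfg <- tiny_config(n_genes = 80, seed = 44, frac_affected = 0.5)
    d <- generateDesign(cfg)
    sim <- generateCounts(d, cfg)
    eff <- sim$truth$log2_effect_CPF6
    up_gene <- sim$truth$gene_id[which(eff > 1)[1]]
    dn_gene <- sim$truth$gene_id[which(eff < 0)[1]]
    ct <- generateQpcr(d, sim$truth, target_genes = c(up_gene, dn_gene),
                       ct_noise_sd = 0, config = cfg)
    fc <- relativeExpression(ct, d)$fc
    expect_gt(fc$fold_change[fc$gene_id == up_gene &
                             fc$treatment == "CPF6"], 1)
    expect_lt(fc$fold_change[fc$gene_id == dn_gene &
                             fc$treatment == "CPF6"], 1)
})

test_that("one HK gene at efficiency 2 reduces to the classic ddCt formula", {
    d <- qpcr_design()
    ct <- data.frame(
        sample_id = rep(d$sample_id, 2),
        gene_id = rep(c("tgt", "hk1"), each = 4),
        role = rep(c("target", "hk"), each = 4),
        ct = c(24, 24.4, 22.3, 22.7,   20, 20.2, 20.1, 19.9))
    out <- relativeExpression(ct, d)
    dct <- c(24, 24.4, 22.3, 22.7) - c(20, 20.2, 20.1, 19.9)
    ddct_fc <- 2^-(mean(dct[3:4]) - mean(dct[1:2]))
    expect_equal(out$fc$fold_change[out$fc$gene_id == "tgt" &
                                    out$fc$treatment == "CPF6"],
                 ddct_fc, tolerance = 1e-12)
})

test_that("per-sample Ct shifts cancel out", {
    d <- qpcr_design()
    base <- data.frame(
        sample_id = rep(d$sample_id, 2),
        gene_id = rep(c("tgt", "hk1"), each = 4),
        role = rep(c("target", "hk"), each = 4),
        ct = c(24, 25, 22, 23,  20, 21, 20.5, 19.5))
    shifted <- base
    shift <- c(c1 = 1.3, c2 = -0.7, t1 = 0.4, t2 = 2.0)
    shifted$ct <- shifted$ct + shift[shifted$sample_id]
    f0 <- relativeExpression(base, d)$fc
    f1 <- relativeExpression(shifted, d)$fc
    expect_equal(f1$fold_change, f0$fold_change, tolerance = 1e-12)
})

test_that("technical replicates are averaged and errors are informative", {
    d <- qpcr_design()
    ct <- data.frame(
        sample_id = rep(d$sample_id, 2),
        gene_id = rep(c("tgt", "hk1"), each = 4),
        role = rep(c("target", "hk"), each = 4),
        ct = c(24, 25, 22, 23,  20, 21, 20.5, 19.5))
    dup <- rbind(ct, ct[1, ])  # a technical replicate row
    dup$ct[9] <- 24.2
    out <- relativeExpression(dup, d)
    rq <- out$rq
    expect_equal(nrow(rq[rq$gene_id == "tgt", ]), 4)

    missing_hk <- ct[-(5), ]  # drop hk in sample c1
    expect_error(relativeExpression(missing_hk, d), "c1")
    bad_eff <- ct; bad_eff$efficiency <- 1
    expect_error(relativeExpression(bad_eff, d), "efficiency")
})

test_that("noisy qPCR recovers planted fold changes within 15% median error", {
    cfg <- tiny_config(n_genes = 80, seed = 44, frac_affected = 0.5)
    d <- generateDesign(cfg)
    sim <- generateCounts(d, cfg)
    tgt <- unique(generateQpcr(d, sim$truth, config = cfg)$gene_id)
    errs <- numeric(100)
    for (i in seq_len(100)) {
        cfg_i <- tiny_config(n_genes = 80, seed = 44 + 1000 * i,
                             frac_affected = 0.5)
        ct <- generateQpcr(d, sim$truth, ct_noise_sd = 0.2, config = cfg_i)
        fc <- relativeExpression(ct, d)$fc
        g <- fc$gene_id[fc$treatment == "CPF6"][1]
        planted <- 2^sim$truth$log2_effect_CPF6[sim$truth$gene_id == g]
        got <- fc$fold_change[fc$gene_id == g & fc$treatment == "CPF6"]
        errs[i] <- abs(got - planted) / planted
    }
    expect_lte(median(errs), 0.15)
})
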