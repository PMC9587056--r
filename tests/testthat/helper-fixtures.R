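# Small shared fixtures, built in code.

tiny_config <- function(n_genes = 40, seed = 101, ...) {
    simulationConfig(n_genes = n_genes, seed = seed, ...)
}

tiny_sim <- function(...) {
    cfg <- tiny_config(...)
    design <- generateDesign(cfg)
    sim <- generateCounts(design, cfg)
    list(config = cfg, design = design, experiment = sim$experiment,
         truth = sim$truth)
}

# Table of reference-gene stability statistics shipped as plain text
hk_reference_table <- function() {
    path <- system.file("extdata", "hk_candidates_stats.tsv",
                        package = "fragwise")
    read.delim(path, stringsAsFactors = FALSE)
}

# random small multi-group dataset for exact-test property tests
random_small_groups <- function(max_total = 8) {
    k <- sample(2:3, 1)
    repeat {
        sizes <- sample(1:4, k, replace = TRUE)
        if (sum(sizes) >= max(3, k + 1) && sum(sizes) <= max_total) break
    }
    # draw from a small pool so ties occur often
    x <- sample(1:5, sum(sizes), replace = TRUE)
    g <- rep(paste0("grp", seq_len(k)), sizes)
    list(x = x, g = g, sizes = sizes)
}
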