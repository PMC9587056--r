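#' @importFrom stats rnorm runif rbinom rpois rgamma rnbinom setNames
NULL

## Labeled substream seeding: one top-level seed drives independent substreams
## so adding a generator never perturbs another.
.streamSeed <- function(seed, label) {
    h <- 7
    for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483629
    as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629)
}

.setStream <- function(config, label) {
    set.seed(.streamSeed(config@seed, label))
}

#' Create a validated simulation configuration
#'
#' Defaults emulate the study design the generator is modeled on: five
#' treatment groups (a shared control plus two organophosphorus pesticides,
#' azinphos-methyl and chlorpyrifos, each at 6 h and 24 h) run in duplicate;
#' on average about two to three accepted fragments per gene; moderate
#' treatment effects (mostly below 2-fold) with down-regulations outnumbering
#' up-regulations about 3:1; a panel of designated low-variability
#' housekeeping genes; and a small fraction of zero/erratic fragments.
#'
#' @param n_genes number of genes.
#' @param fragments_per_gene integer range (length 2) of fragments per gene.
#' @param treatments ordered treatment labels; must contain \code{control}
#'   exactly once.
#' @param control the control group label.
#' @param n_replicates biological replicates per treatment (>= 2).
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   per-gene baseline abundance (count units on a typical library).
#' @param nb_dispersion negative-binomial dispersion phi; the biological
#'   coefficient of variation is \code{sqrt(phi)}.
#' @param library_size_cv CV of per-sample library-size factors.
#' @param frac_affected fraction of non-housekeeping genes with a planted
#'   effect.
#' @param down_up_ratio odds that a planted effect is a down-regulation.
#' @param effect_log2_range interval for |log2 fold change| of planted
#'   effects.
#' @param n_hk_genes number of designated housekeeping genes.
#' @param hk_cv_target percent CV ceiling housekeeping genes are tuned under.
#' @param hk_min_abundance abundance floor for housekeeping genes.
#' @param frac_bad_fragments fraction of fragments corrupted.
#' @param dirichlet_conc symmetric Dirichlet concentration for fragment
#'   shares.
#' @param seed integer seed.
#'
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(n_genes = 100, seed = 42)
#' @export
simulationConfig <- function(n_genes = 2000L,
                             fragments_per_gene = c(1L, 5L),
                             treatments = c("control", "AZM6", "AZM24",
                                            "CPF6", "CPF24"),
                             control = "control",
                             n_replicates = 2L,
                             baseline_log_mean = 5,
                             baseline_log_sd = 1.5,
                             nb_dispersion = 0.10,
                             library_size_cv = 0.15,
                             frac_affected = 0.30,
                             down_up_ratio = 3,
                             effect_log2_range = c(0.3, 2.0),
                             n_hk_genes = 12L,
                             hk_cv_target = 15,
                             hk_min_abundance = 600,
                             frac_bad_fragments = 0.05,
                             dirichlet_conc = 5,
                             seed = 20221021L) {
    obj <- methods::new("SimulationConfig",
        n_genes = as.integer(n_genes),
        fragments_per_gene = as.integer(fragments_per_gene),
        treatments = as.character(treatments),
        control = as.character(control),
        n_replicates = as.integer(n_replicates),
        baseline_log_mean = as.numeric(baseline_log_mean),
        baseline_log_sd = as.numeric(baseline_log_sd),
        nb_dispersion = as.numeric(nb_dispersion),
        library_size_cv = as.numeric(library_size_cv),
        frac_affected = as.numeric(frac_affected),
        down_up_ratio = as.numeric(down_up_ratio),
        effect_log2_range = as.numeric(effect_log2_range),
        n_hk_genes = as.integer(n_hk_genes),
        hk_cv_target = as.numeric(hk_cv_target),
        hk_min_abundance = as.numeric(hk_min_abundance),
        frac_bad_fragments = as.numeric(frac_bad_fragments),
        dirichlet_conc = as.numeric(dirichlet_conc),
        seed = as.integer(seed))
    methods::validObject(obj)
    obj
}

#' Generate the sample design table
#'
#' One sample per (treatment, replicate) pair, in treatment order. The default
#' configuration yields the 5 groups x 2 replicates = 10 samples of the
#' emulated exposure design.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with columns \code{sample_id}, \code{treatment}
#'   (factor, levels in configuration order) and \code{replicate}.
#' @examples
#' generateDesign(simulationConfig(seed = 1))
#' @export
generateDesign <- function(config) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    tr <- rep(config@treatments, each = config@n_replicates)
    rp <- rep(seq_len(config@n_replicates), times = length(config@treatments))
    data.frame(
        sample_id = sprintf("%s_r%d", tr, rp),
        treatment = factor(tr, levels = config@treatments),
        replicate = rp,
        stringsAsFactors = FALSE)
}

## Symmetric Dirichlet via normalized gammas.
.rdirichlet1 <- function(k, conc) {
    g <- rgamma(k, shape = conc, rate = 1)
    if (all(g == 0)) g <- rep(1, k)
    g / sum(g)
}

#' Generate fragment-level counts with ground truth
#'
#' Draws negative-binomial fragment counts for the given design. Per gene g,
#' sample s and fragment f the expected count is
#' \code{lib_s * A_g * 2^eff(g, t(s)) * share_f}; the NB variation
#' (variance mu + phi mu^2) is realized as a per-(gene, sample) Gamma
#' multiplier with squared CV phi shared by the gene's fragments, followed by
#' Poisson sampling per fragment, so the NB(mu, phi) marginal holds both per
#' fragment and for the gene-level sum while fragments of one gene share
#' their biological replicate noise. Housekeeping genes receive zero effect,
#' an abundance floor and a tightened dispersion so their realized CV percent
#' stays below \code{hk_cv_target}. A fraction \code{frac_bad_fragments} of
#' fragments is corrupted: either one randomly chosen sample is forced to
#' zero, or the fragment is rescaled below the expression floor and one
#' replicate per treatment group is multiplied by Uniform(0.05, 0.3) noise
#' ("low and erratic" values).
#'
#' @param design output of [generateDesign()].
#' @param config the same \linkS4class{SimulationConfig}.
#' @return list with \code{experiment} (a \linkS4class{FragmentExperiment}
#'   with a \code{counts} assay; \code{rowData} carries \code{is_bad} and
#'   \code{bad_mode}) and \code{truth} (data.frame: \code{gene_id},
#'   \code{group_tag}, \code{is_hk}, one \code{log2_effect_<treatment>}
#'   column per non-control treatment, \code{bad_fragment_ids}
#'   comma-separated).
#' @examples
#' cfg <- simulationConfig(n_genes = 50, seed = 7)
#' sim <- generateCounts(generateDesign(cfg), cfg)
#' head(sim$truth)
#' @export
generateCounts <- function(design, config) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    if (!all(c("sample_id", "treatment", "replicate") %in% colnames(design)))
        stop("'design' must come from generateDesign()")
    nG <- config@n_genes
    nS <- nrow(design)
    treatments <- config@treatments
    control <- config@control
    noncontrol <- setdiff(treatments, control)

    ## -- substream: structure (gene architecture, effects, HK designation) --
    .setStream(config, "structure")
    gene_id <- sprintf("g%05d", seq_len(nG))
    frag_range <- seq(config@fragments_per_gene[1L],
                      config@fragments_per_gene[2L])
    nfrag <- frag_range[sample.int(length(frag_range), nG, replace = TRUE)]
    hk_idx <- if (config@n_hk_genes > 0L)
        sort(sample.int(nG, config@n_hk_genes)) else integer()
    is_hk <- seq_len(nG) %in% hk_idx
    group_tag <- sample(c("B", "C", "D", "E"), nG, replace = TRUE)
    group_tag[is_hk] <- "A"
    abundance <- exp(rnorm(nG, config@baseline_log_mean, config@baseline_log_sd))
    abundance[is_hk] <- pmax(abundance[is_hk], config@hk_min_abundance)
    affected <- !is_hk & rbinom(nG, 1L, config@frac_affected) == 1L
    direction <- ifelse(
        runif(nG) < config@down_up_ratio / (1 + config@down_up_ratio), -1, 1)
    magnitude <- runif(nG, config@effect_log2_range[1L],
                       config@effect_log2_range[2L])
    log2_effect <- ifelse(affected, direction * magnitude, 0)
    shares <- lapply(seq_len(nG), function(g)
        .rdirichlet1(nfrag[g], config@dirichlet_conc))

    ## -- substream: library sizes --
    .setStream(config, "library")
    if (config@library_size_cv > 0) {
        sdlog <- sqrt(log(1 + config@library_size_cv^2))
        lib <- exp(rnorm(nS, 0, sdlog))
        lib <- lib / exp(mean(log(lib)))
    } else {
        lib <- rep(1, nS)
    }

    ## -- substream: counts --
    .setStream(config, "counts")
    frag_gene <- rep.int(gene_id, nfrag)
    frag_share <- unlist(shares, use.names = FALSE)
    frag_id <- unlist(lapply(seq_len(nG), function(g)
        sprintf("%s_f%d", gene_id[g], seq_len(nfrag[g]))), use.names = FALSE)
    nF <- length(frag_id)
    phi_hk <- (0.6 * config@hk_cv_target / 100)^2
    phi <- ifelse(is_hk, pmin(phi_hk, config@nb_dispersion), config@nb_dispersion)
    treat_of_sample <- as.character(design$treatment)
    eff_mat <- matrix(0, nG, nS)  # log2 effect per gene x sample
    for (s in seq_len(nS))
        if (treat_of_sample[s] != control)
            eff_mat[, s] <- log2_effect
    counts <- matrix(0L, nF, nS, dimnames = list(frag_id, design$sample_id))
    frag_of_gene <- split(seq_len(nF), factor(frag_gene, levels = gene_id))
    for (g in seq_len(nG)) {
        mu_gene <- abundance[g] * 2^eff_mat[g, ] * lib  # length nS
        bio <- rgamma(nS, shape = 1 / phi[g], rate = 1 / phi[g])
        idx <- frag_of_gene[[g]]
        sh <- frag_share[idx]
        counts[idx, ] <- matrix(
            rpois(length(idx) * nS, outer(sh, mu_gene * bio)),
            nrow = length(idx))
    }

    ## -- substream: corruption --
    .setStream(config, "corruption")
    n_bad <- round(config@frac_bad_fragments * nF)
    bad_idx <- if (n_bad > 0L) sort(sample.int(nF, n_bad)) else integer()
    bad_mode <- rep("", nF)
    if (n_bad > 0L) {
        modes <- sample(c("zero", "erratic"), n_bad, replace = TRUE)
        bad_mode[bad_idx] <- modes
        exp_total <- sum(abundance)  # expected library, count units
        grp_samples <- split(seq_len(nS), treat_of_sample)
        for (j in seq_along(bad_idx)) {
            f <- bad_idx[j]
            if (modes[j] == "zero") {
                counts[f, sample.int(nS, 1L)] <- 0L
            } else {
                ## scale below the expression floor, then corrupt one
                ## replicate per group with multiplicative erratic noise
                target <- runif(1, 1, 4) * exp_total / 1e6
                counts[f, ] <- rpois(nS, target * lib)
                for (ss in grp_samples) {
                    pick <- ss[sample.int(length(ss), 1L)]
                    counts[f, pick] <-
                        as.integer(round(counts[f, pick] * runif(1, 0.05, 0.3)))
                }
            }
        }
    }

    bad_by_gene <- vapply(frag_of_gene, function(idx) {
        b <- frag_id[idx][bad_mode[idx] != ""]
        paste(b, collapse = ",")
    }, character(1))

    truth <- data.frame(gene_id = gene_id, group_tag = group_tag,
                        is_hk = is_hk,
                        baseline_abundance = abundance,
                        stringsAsFactors = FALSE)
    for (tr in noncontrol)
        truth[[paste0("log2_effect_", tr)]] <- log2_effect
    truth$bad_fragment_ids <- unname(bad_by_gene)

    fe <- FragmentExperiment(counts,
                             gene_id = frag_gene,
                             group_tag = rep.int(group_tag, nfrag),
                             design = design, assay_name = "counts")
    rowData(fe)$is_bad <- bad_mode != ""
    rowData(fe)$bad_mode <- bad_mode
    rowData(fe)$true_share <- frag_share
    list(experiment = fe, truth = truth)
}

#' Generate BLAST-tabular alignment hits for annotation confirmation
#'
#' Emits one best-hit row per fragment in an outfmt-6-like dialect
#' (\code{qseqid sseqid pident length evalue bitscore}). Exactly
#' \code{round(confirm_rate * n)} fragments receive a hit with percent
#' identity above 50 to their expected gene; the remainder get either a
#' low-identity hit (< 50) to the expected gene or no hit row at all.
#'
#' @param fragments character vector of fragment ids, or a
#'   \linkS4class{FragmentExperiment} (its rownames are used).
#' @param gene_id parent gene per fragment; taken from the experiment when
#'   \code{fragments} is a \linkS4class{FragmentExperiment}.
#' @param confirm_rate fraction of fragments to confirm, in [0, 1].
#' @param config a \linkS4class{SimulationConfig} (drives the "hits"
#'   substream).
#' @return list with \code{hits} (BLAST-tabular data.frame) and
#'   \code{expected} (data.frame \code{fragment_id}, \code{gene_id}: the
#'   fragment-to-expected-gene map). Subject accessions are the gene id plus
#'   a version suffix (\code{<gene>.1}).
#' @examples
#' cfg <- simulationConfig(n_genes = 30, seed = 3)
#' sim <- generateCounts(generateDesign(cfg), cfg)
#' ah <- generateAlignmentHits(sim$experiment, confirm_rate = 0.9, config = cfg)
#' head(ah$hits)
#' @export
generateAlignmentHits <- function(fragments, gene_id = NULL, confirm_rate,
                                  config) {
    stopifnot(methods::is(config, "SimulationConfig"))
    if (length(confirm_rate) != 1L || is.na(confirm_rate) ||
        confirm_rate < 0 || confirm_rate > 1)
        stop("'confirm_rate' must be a single value in [0, 1]")
    if (methods::is(fragments, "FragmentExperiment")) {
        gene_id <- unname(fragmentGenes(fragments))
        fragments <- rownames(fragments)
    }
    if (is.null(gene_id) || length(gene_id) != length(fragments))
        stop("'gene_id' must have one entry per fragment")
    n <- length(fragments)
    .setStream(config, "hits")
    n_conf <- round(confirm_rate * n)
    conf <- rep(FALSE, n)
    if (n_conf > 0L) conf[sample.int(n, n_conf)] <- TRUE
    ## unconfirmed fragments: half get a low-identity hit, half no hit row
    no_hit <- !conf & runif(n) < 0.5
    pid <- ifelse(conf, runif(n, 55, 99), runif(n, 20, 49.5))
    len <- round(runif(n, 150, 900))
    keep <- !no_hit
    hits <- data.frame(
        qseqid = fragments[keep],
        sseqid = paste0(gene_id[keep], ".1"),
        pident = round(pid[keep], 2),
        length = len[keep],
        evalue = signif(10^(-runif(n, 5, 120)), 3)[keep],
        bitscore = round(len[keep] * 2 * pid[keep] / 100, 1),
        stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    list(hits = hits,
         expected = data.frame(fragment_id = fragments, gene_id = gene_id,
                               stringsAsFactors = FALSE))
}

#' Generate a qPCR Ct table from simulated ground truth
#'
#' Ct values follow \code{Ct = Ct0_g - log_E(Q) + Normal(0, ct_noise_sd)}
#' where Q is the relative quantity implied by the truth table (\code{2^eff}
#' in treated samples, 1 otherwise) and E the amplification efficiency.
#' Housekeeping genes have a treatment-independent expected Ct.
#'
#' @param design output of [generateDesign()].
#' @param truth truth table from [generateCounts()].
#' @param target_genes gene ids assayed as targets; defaults to up to 4
#'   affected genes (largest planted |effect| first).
#' @param hk_genes gene ids used as housekeeping references; defaults to the
#'   first two designated housekeeping genes.
#' @param efficiency amplification efficiency per cycle, in (1, 2].
#' @param ct_noise_sd technical noise SD on the Ct scale (cycles).
#' @param config a \linkS4class{SimulationConfig} (drives the "qpcr"
#'   substream).
#' @return data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{role} (\code{target}/\code{hk}), \code{ct}, \code{efficiency}.
#' @examples
#' cfg <- simulationConfig(n_genes = 60, seed = 11)
#' sim <- generateCounts(generateDesign(cfg), cfg)
#' ct <- generateQpcr(generateDesign(cfg), sim$truth, config = cfg)
#' head(ct)
#' @export
generateQpcr <- function(design, truth, target_genes = NULL, hk_genes = NULL,
                         efficiency = 2, ct_noise_sd = 0, config) {
    stopifnot(methods::is(config, "SimulationConfig"))
    if (efficiency <= 1 || efficiency > 2)
        stop("'efficiency' must be in (1, 2]")
    if (ct_noise_sd < 0) stop("'ct_noise_sd' must be >= 0")
    effcols <- grep("^log2_effect_", colnames(truth), value = TRUE)
    if (is.null(hk_genes)) {
        hk_genes <- utils::head(truth$gene_id[truth$is_hk], 2L)
        if (length(hk_genes) == 0L)
            stop("no housekeeping genes in 'truth'; supply 'hk_genes'")
    }
    if (is.null(target_genes)) {
        eff <- truth[[effcols[1L]]]
        cand <- truth$gene_id[!truth$is_hk & eff != 0]
        ord <- order(-abs(eff[match(cand, truth$gene_id)]))
        target_genes <- utils::head(cand[ord], 4L)
        if (length(target_genes) == 0L)
            stop("no affected genes in 'truth'; supply 'target_genes'")
    }
    genes <- c(target_genes, hk_genes)
    missing <- setdiff(genes, truth$gene_id)
    if (length(missing))
        stop("genes absent from truth table: ", paste(missing, collapse = ", "))
    .setStream(config, "qpcr")
    ct0 <- setNames(runif(length(genes), 20, 30), genes)
    control <- config@control
    rows <- expand.grid(sample_id = design$sample_id, gene_id = genes,
                        stringsAsFactors = FALSE)
    rows$role <- ifelse(rows$gene_id %in% hk_genes, "hk", "target")
    tr <- as.character(design$treatment)[match(rows$sample_id, design$sample_id)]
    log2q <- numeric(nrow(rows))
    for (i in seq_len(nrow(rows))) {
        if (rows$role[i] == "hk" || tr[i] == control) next
        log2q[i] <- truth[[paste0("log2_effect_", tr[i])]][
            match(rows$gene_id[i], truth$gene_id)]
    }
    q <- 2^log2q
    rows$ct <- ct0[rows$gene_id] - log(q) / log(efficiency) +
        rnorm(nrow(rows), 0, ct_noise_sd)
    rows$efficiency <- efficiency
    rownames(rows) <- NULL
    rows
}
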