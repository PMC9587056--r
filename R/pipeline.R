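#' Pipeline configuration
#'
#' A flat list of parameters for [runPipeline()]; every entry has a default.
#' In \code{"simulate+analyze"} mode the synthetic-data generator produces
#' the inputs; in \code{"analyze-only"} mode \code{counts_file},
#' \code{design_file} and \code{hits_file} must point to existing TSVs
#' (validated before any stage runs).
#'
#' @param mode \code{"simulate+analyze"} or \code{"analyze-only"}.
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param sim a \linkS4class{SimulationConfig} (simulate mode).
#' @param confirm_rate synthetic annotation confirmation rate.
#' @param counts_file,design_file,hits_file input paths (analyze-only mode).
#' @param min_match annotation confirmation threshold (percent).
#' @param low_floor,erratic_cv expression-filter parameters.
#' @param cv_max housekeeping CV threshold (percent).
#' @param control control group label.
#' @param alpha,tendency nonparametric calling thresholds.
#' @param n_perm omnibus permutation count.
#' @param fc_threshold,p_max NB DEG thresholds.
#' @param qpcr_noise_sd Ct noise SD for the synthetic qPCR assay.
#' @param seed analysis seed (permutation substreams).
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(mode = c("simulate+analyze", "analyze-only"),
                           out_dir = tempfile("fragwise_run_"),
                           sim = simulationConfig(),
                           confirm_rate = 0.938,
                           counts_file = NULL, design_file = NULL,
                           hits_file = NULL,
                           min_match = 50, low_floor = 5, erratic_cv = 50,
                           cv_max = 20, control = "control",
                           alpha = 0.05, tendency = 0.10, n_perm = 2000,
                           fc_threshold = 2, p_max = 0.05,
                           qpcr_noise_sd = 0.2, seed = 1L) {
    mode <- match.arg(mode)
    cfg <- list(mode = mode, out_dir = out_dir, sim = sim,
                confirm_rate = confirm_rate, counts_file = counts_file,
                design_file = design_file, hits_file = hits_file,
                min_match = min_match, low_floor = low_floor,
                erratic_cv = erratic_cv, cv_max = cv_max, control = control,
                alpha = alpha, tendency = tendency, n_perm = n_perm,
                fc_threshold = fc_threshold, p_max = p_max,
                qpcr_noise_sd = qpcr_noise_sd, seed = as.integer(seed))
    if (mode == "analyze-only") {
        for (f in c("counts_file", "design_file", "hits_file")) {
            if (is.null(cfg[[f]]))
                stop("analyze-only mode requires '", f, "'")
            if (!file.exists(cfg[[f]]))
                stop("input file does not exist: ", cfg[[f]],
                     " ('", f, "')")
        }
    }
    structure(cfg, class = "PipelineConfig")
}

.stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full workflow
#'
#' Executes the stages in dependency order — simulate (or load), curate,
#' TMM-normalize, housekeeping selection and standardization, nonparametric
#' and NB differential expression, concordance, heatmap summary, qPCR — and
#' writes each stage's artifact plus a run manifest (parameters, output
#' checksums, seed) to \code{config$out_dir}. Identical configuration and
#' seed yield identical checksums. Progress is logged to stderr with
#' stage-tagged lines.
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()].
#' @return the manifest, invisibly; also written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "PipelineConfig"))
        config <- do.call(pipelineConfig, config)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    emit <- function(name, writer) {
        p <- file.path(config$out_dir, name)
        writer(p)
        paths[[name]] <<- p
        p
    }

    if (config$mode == "simulate+analyze") {
        .stageLog("simulate", "generating design, counts, hits, Ct")
        design <- generateDesign(config$sim)
        sim <- generateCounts(design, config$sim)
        fe <- sim$experiment
        hits <- generateAlignmentHits(fe, confirm_rate = config$confirm_rate,
                                      config = config$sim)
        ct <- generateQpcr(design, sim$truth,
                           ct_noise_sd = config$qpcr_noise_sd,
                           config = config$sim)
        emit("design.tsv", function(p) writeSampleDesign(design, p))
        emit("counts.tsv", function(p) writeFragmentCounts(fe, p))
        emit("truth.tsv", function(p) .writeTSV(sim$truth, p))
        emit("hits.tsv", function(p) writeAlignmentHits(hits, p))
        emit("ct.tsv", function(p) writeCtTable(ct, p))
    } else {
        .stageLog("load", "reading inputs")
        design <- readSampleDesign(config$design_file)
        fe <- readFragmentCounts(config$counts_file, config$design_file)
        hits <- readAlignmentHits(config$hits_file)
        ct <- NULL
    }

    .stageLog("normalize", "TMM factors")
    fe <- tmmNormalize(fe)
    emit("tmm_factors.tsv", function(p)
        .writeTSV(data.frame(sample_id = colnames(fe),
                             factor = colData(fe)$tmm_factor), p))

    .stageLog("curate", "annotation + expression funnel")
    funnel <- curationFunnel(fe, hits, threshold_percent = config$min_match,
                             low_floor = config$low_floor,
                             erratic_cv_percent = config$erratic_cv)
    emit("curation.tsv", function(p) {
        st <- merge(funnel$annotation$status, funnel$expression$status,
                    by = "fragment_id", all.x = TRUE,
                    suffixes = c("_annotation", "_expression"))
        .writeTSV(st[order(st$fragment_id), ], p)
    })
    .stageLog("curate", sprintf("%d/%d confirmed, %d accepted",
                                funnel$funnel["confirmed"],
                                funnel$funnel["total"],
                                funnel$funnel["accepted"]))

    .stageLog("hk-select", "stability statistics")
    tmm <- assay(fe, "tmm")
    gene_tmm <- collapseFragments(tmm, rowData(fe)$gene_id)
    hk_candidates <- if ("group_tag" %in% colnames(rowData(fe))) {
        g <- unique(rowData(fe)$gene_id[rowData(fe)$group_tag == "A"])
        if (length(g) >= 2L) g else rownames(gene_tmm)
    } else rownames(gene_tmm)
    stats_tab <- hkStats(gene_tmm, intersect(hk_candidates,
                                             rownames(gene_tmm)))
    hk <- selectHK(stats_tab, cv_max = config$cv_max)
    emit("hk_stats.tsv", function(p) .writeTSV(stats_tab, p))
    emit("hk_selected.tsv", function(p) .writeTSV(hk, p))
    if (nrow(hk) == 0L)
        stop("stage hk-select: no housekeeping gene passes CV% < ",
             config$cv_max)

    .stageLog("standardize", length(hk$transcript_id), " HK genes")
    accepted_tmm <- tmm[funnel$accepted, , drop = FALSE]
    std <- standardize(accepted_tmm, hk, design, control = config$control,
                       hk_expr = gene_tmm)
    emit("standardized.tsv", function(p)
        .writeTSV(data.frame(fragment_id = rownames(std$standardized),
                             std$standardized, check.names = FALSE), p))

    .stageLog("detest-np", "exact nonparametric tests")
    gene_of_accepted <- rowData(fe)[funnel$accepted, "gene_id"]
    np <- nonparametricDE(std$standardized, gene_of_accepted, design,
                          control = config$control, alpha = config$alpha,
                          tendency = config$tendency,
                          n_perm = config$n_perm, seed = config$seed)
    emit("np_genes.tsv", function(p) .writeTSV(np$genes, p))
    emit("np_pairs.tsv", function(p) .writeTSV(np$pairs, p))

    .stageLog("detest-nb", "collapsed NB exact tests")
    nb <- nbDE(fe, control = config$control,
               tmm_factors = stats::setNames(colData(fe)$tmm_factor,
                                             colnames(fe)),
               fc_threshold = config$fc_threshold, p_max = config$p_max)
    emit("nb_results.tsv", function(p) .writeTSV(nb$results, p))

    .stageLog("compare", "concordance + heatmap")
    conc <- compareCalls(np$pairs, nb$results, alpha = config$alpha)
    hm <- heatmapTable(np$pairs)
    emit("concordance.tsv", function(p) .writeTSV(conc$cells, p))
    emit("heatmap.tsv", function(p)
        .writeTSV(data.frame(gene_id = rownames(hm$matrix), hm$matrix,
                             check.names = FALSE), p))
    emit("summary.json", function(p)
        jsonlite::write_json(list(
            funnel = as.list(funnel$funnel),
            n_hk = nrow(hk),
            dispersion = nb$dispersion,
            concordance_percent = conc$overall_percent,
            n_up = hm$n_up, n_down = hm$n_down,
            down_up_ratio = hm$down_up_ratio), p,
            auto_unbox = TRUE, digits = NA))

    if (!is.null(ct)) {
        .stageLog("qpcr", "geometric-mean normalization")
        qp <- relativeExpression(ct, design, control = config$control)
        emit("qpcr_fc.tsv", function(p) .writeTSV(qp$fc, p))
    }

    .stageLog("manifest", "checksums")
    manifest <- list(
        package_version = as.character(utils::packageVersion("fragwise")),
        mode = config$mode,
        seed = config$seed,
        parameters = config[setdiff(names(config),
                                    c("sim", "out_dir"))],
        sim_seed = if (config$mode == "simulate+analyze")
            config$sim@seed else NULL,
        outputs = as.list(tools::md5sum(unlist(paths))))
    names(manifest$outputs) <- names(paths)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
}
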