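#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assays<- rowData<- colData<-
NULL

#' FragmentExperiment: fragment-level expression with gene and pathway annotation
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one row per
#' transcript fragment (an assembled isoform/contig mapped to an annotated
#' gene) and one column per biological sample. \code{rowData} must carry
#' \code{gene_id} (parent gene) and \code{group_tag} (pathway group
#' \code{A}-\code{E}, or \code{"none"}); \code{colData} must carry
#' \code{treatment} and \code{replicate}. The first assay is either raw
#' integer counts (assay name \code{"counts"}) or TMM-normalized abundance
#' (assay name \code{"tmm"}).
#'
#' @slot .. no additional slots; the class exists for validity checking and
#'   method dispatch.
#'
#' @seealso [FragmentExperiment()] for the constructor,
#'   [tmmNormalize()], [collapseFragments()].
#' @export
setClass("FragmentExperiment", contains = "SummarizedExperiment")

.validFragmentExperiment <- function(object) {
    msg <- character()
    rd <- rowData(object)
    cd <- colData(object)
    if (!all(c("gene_id", "group_tag") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'gene_id' and 'group_tag'")
    if (!all(c("treatment", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'treatment' and 'replicate'")
    if (length(assays(object)) < 1L) {
        msg <- c(msg, "at least one assay is required")
    } else {
        a <- assay(object, 1L)
        if (any(is.na(a)))
            msg <- c(msg, "assay contains NA values")
        else if (any(a < 0))
            msg <- c(msg, "assay contains negative values")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "fragment ids (rownames) must be unique")
    }
    if (length(msg)) msg else TRUE
}

setValidity("FragmentExperiment", .validFragmentExperiment)

#' Simulation configuration for the synthetic study design
#'
#' Parameters of the synthetic fragment-level expression generator emulating a
#' five-treatment, duplicated exposure design (control plus two
#' organophosphorus pesticides at two exposure times). Construct with
#' [simulationConfig()], which validates all fields.
#'
#' @slot n_genes number of genes.
#' @slot fragments_per_gene integer range (length 2) of fragments per gene.
#' @slot treatments ordered treatment labels; first element is the control.
#' @slot control label of the control group (must occur exactly once).
#' @slot n_replicates biological replicates per treatment (>= 2).
#' @slot baseline_log_mean,baseline_log_sd natural-log-scale parameters of the
#'   per-gene baseline abundance distribution (count units on a typical
#'   library).
#' @slot nb_dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2).
#' @slot library_size_cv coefficient of variation of per-sample library-size
#'   factors.
#' @slot frac_affected fraction of non-housekeeping genes given a nonzero
#'   treatment effect.
#' @slot down_up_ratio odds of a planted effect being a down- rather than an
#'   up-regulation.
#' @slot effect_log2_range interval for the magnitude |log2 fold change| of
#'   planted effects.
#' @slot n_hk_genes number of designated housekeeping genes.
#' @slot hk_cv_target percent CV ceiling the housekeeping genes are tuned to
#'   stay under.
#' @slot hk_min_abundance abundance floor applied to housekeeping genes so
#'   counting noise cannot dominate their CV.
#' @slot frac_bad_fragments fraction of fragments corrupted (forced zero or
#'   low-and-erratic values).
#' @slot dirichlet_conc concentration of the symmetric Dirichlet that splits a
#'   gene's abundance across its fragments.
#' @slot seed integer seed driving labeled substreams.
#' @export
setClass("SimulationConfig",
    representation(
        n_genes = "integer",
        fragments_per_gene = "integer",
        treatments = "character",
        control = "character",
        n_replicates = "integer",
        baseline_log_mean = "numeric",
        baseline_log_sd = "numeric",
        nb_dispersion = "numeric",
        library_size_cv = "numeric",
        frac_affected = "numeric",
        down_up_ratio = "numeric",
        effect_log2_range = "numeric",
        n_hk_genes = "integer",
        hk_cv_target = "numeric",
        hk_min_abundance = "numeric",
        frac_bad_fragments = "numeric",
        dirichlet_conc = "numeric",
        seed = "integer"
    )
)

.validSimulationConfig <- function(object) {
    chkfrac <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            sprintf("'%s' must be a single value in [0, 1]", nm)
        else character()
    }
    msg <- character()
    if (length(object@n_genes) != 1L || is.na(object@n_genes) || object@n_genes < 1L)
        msg <- c(msg, "'n_genes' must be a positive integer")
    if (length(object@fragments_per_gene) != 2L ||
        any(is.na(object@fragments_per_gene)) ||
        object@fragments_per_gene[1L] < 1L ||
        object@fragments_per_gene[2L] < object@fragments_per_gene[1L])
        msg <- c(msg, "'fragments_per_gene' must be an increasing integer range with lower bound >= 1")
    if (length(object@treatments) < 2L || anyDuplicated(object@treatments))
        msg <- c(msg, "'treatments' must be >= 2 distinct labels")
    if (sum(object@treatments == object@control) != 1L)
        msg <- c(msg, "'treatments' must contain the control label exactly once")
    if (length(object@n_replicates) != 1L || is.na(object@n_replicates) ||
        object@n_replicates < 2L)
        msg <- c(msg, "'n_replicates' must be an integer >= 2")
    if (!is.finite(object@baseline_log_mean))
        msg <- c(msg, "'baseline_log_mean' must be finite")
    if (!is.finite(object@baseline_log_sd) || object@baseline_log_sd < 0)
        msg <- c(msg, "'baseline_log_sd' must be >= 0")
    if (!is.finite(object@nb_dispersion) || object@nb_dispersion <= 0)
        msg <- c(msg, "'nb_dispersion' must be > 0")
    if (!is.finite(object@library_size_cv) || object@library_size_cv < 0)
        msg <- c(msg, "'library_size_cv' must be >= 0")
    msg <- c(msg, chkfrac(object@frac_affected, "frac_affected"))
    msg <- c(msg, chkfrac(object@frac_bad_fragments, "frac_bad_fragments"))
    if (!is.finite(object@down_up_ratio) || object@down_up_ratio <= 0)
        msg <- c(msg, "'down_up_ratio' must be > 0")
    if (length(object@effect_log2_range) != 2L ||
        any(!is.finite(object@effect_log2_range)) ||
        object@effect_log2_range[1L] < 0 ||
        object@effect_log2_range[2L] < object@effect_log2_range[1L])
        msg <- c(msg, "'effect_log2_range' must be a nonnegative increasing interval")
    if (length(object@n_hk_genes) != 1L || is.na(object@n_hk_genes) ||
        object@n_hk_genes < 0L || object@n_hk_genes > object@n_genes)
        msg <- c(msg, "'n_hk_genes' must be in [0, n_genes]")
    if (!is.finite(object@hk_cv_target) || object@hk_cv_target <= 0)
        msg <- c(msg, "'hk_cv_target' must be > 0")
    if (!is.finite(object@hk_min_abundance) || object@hk_min_abundance <= 0)
        msg <- c(msg, "'hk_min_abundance' must be > 0")
    if (!is.finite(object@dirichlet_conc) || object@dirichlet_conc <= 0)
        msg <- c(msg, "'dirichlet_conc' must be > 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single integer")
    if (length(msg)) msg else TRUE
}

setValidity("SimulationConfig", .validSimulationConfig)

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat("  genes:", object@n_genes,
        sprintf("(%d housekeeping)", object@n_hk_genes), "\n")
    cat("  fragments/gene:", paste(object@fragments_per_gene, collapse = "-"), "\n")
    cat("  design:", length(object@treatments), "treatments x",
        object@n_replicates, "replicates;",
        "control =", object@control, "\n")
    cat("  NB dispersion:", object@nb_dispersion,
        "| affected fraction:", object@frac_affected,
        "| down:up odds:", object@down_up_ratio, "\n")
    cat("  seed:", object@seed, "\n")
    invisible(NULL)
})
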