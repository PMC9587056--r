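#' Construct a FragmentExperiment
#'
#' @param counts numeric matrix (fragments x samples); raw counts or
#'   TMM-normalized abundance.
#' @param gene_id character vector, parent gene per fragment.
#' @param group_tag pathway group per fragment (\code{"A"}..\code{"E"} or
#'   \code{"none"}). Recycled if length 1.
#' @param design data.frame with columns \code{sample_id}, \code{treatment},
#'   \code{replicate} (see [generateDesign()]); rows must match the columns of
#'   \code{counts}.
#' @param assay_name \code{"counts"} for raw counts, \code{"tmm"} for
#'   normalized abundance.
#'
#' @return A \linkS4class{FragmentExperiment}.
#' @examples
#' cfg <- simulationConfig(n_genes = 20, seed = 1)
#' sim <- generateCounts(generateDesign(cfg), cfg)
#' sim$experiment
#' @export
FragmentExperiment <- function(counts, gene_id, group_tag = "none", design,
                               assay_name = c("counts", "tmm")) {
    assay_name <- match.arg(assay_name)
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("'counts' must have fragment ids as rownames")
    if (length(gene_id) != nrow(counts))
        stop("'gene_id' must have one entry per fragment")
    group_tag <- rep_len(as.character(group_tag), nrow(counts))
    design <- as.data.frame(design)
    if (!all(c("sample_id", "treatment", "replicate") %in% colnames(design)))
        stop("'design' must have columns sample_id, treatment, replicate")
    if (is.null(colnames(counts)))
        colnames(counts) <- design$sample_id
    if (!identical(colnames(counts), as.character(design$sample_id)))
        design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
    if (any(is.na(design$sample_id)))
        stop("columns of 'counts' do not match 'design$sample_id'")
    cd <- S4Vectors::DataFrame(design, row.names = design$sample_id)
    rd <- S4Vectors::DataFrame(gene_id = as.character(gene_id),
                               group_tag = group_tag,
                               row.names = rownames(counts))
    al <- list(counts)
    names(al) <- assay_name
    se <- SummarizedExperiment::SummarizedExperiment(assays = al,
                                                     rowData = rd, colData = cd)
    methods::new("FragmentExperiment", se)
}

#' Accessors for FragmentExperiment annotation
#'
#' \code{fragmentGenes} returns the parent gene of each fragment,
#' \code{pathwayGroups} the pathway group tag, and \code{sampleTreatments}
#' the treatment label of each sample.
#'
#' @param object a \linkS4class{FragmentExperiment}.
#' @return A named character vector.
#' @rdname fragment-accessors
#' @export
setGeneric("fragmentGenes", function(object) standardGeneric("fragmentGenes"))

#' @rdname fragment-accessors
#' @export
setGeneric("pathwayGroups", function(object) standardGeneric("pathwayGroups"))

#' @rdname fragment-accessors
#' @export
setGeneric("sampleTreatments", function(object) standardGeneric("sampleTreatments"))

#' @rdname fragment-accessors
setMethod("fragmentGenes", "FragmentExperiment", function(object) {
    stats::setNames(rowData(object)$gene_id, rownames(object))
})

#' @rdname fragment-accessors
setMethod("pathwayGroups", "FragmentExperiment", function(object) {
    stats::setNames(rowData(object)$group_tag, rownames(object))
})

#' @rdname fragment-accessors
setMethod("sampleTreatments", "FragmentExperiment", function(object) {
    stats::setNames(as.character(colData(object)$treatment), colnames(object))
})

setMethod("show", "FragmentExperiment", function(object) {
    cat("FragmentExperiment:", nrow(object), "fragments,",
        length(unique(rowData(object)$gene_id)), "genes,",
        ncol(object), "samples\n")
    tr <- table(colData(object)$treatment)
    cat("  treatments:", paste(sprintf("%s(%d)", names(tr), tr), collapse = " "), "\n")
    cat("  assays:", paste(names(assays(object)), collapse = ", "), "\n")
    invisible(NULL)
})

#' Sample design table of a FragmentExperiment
#'
#' @param object a \linkS4class{FragmentExperiment}.
#' @return data.frame with columns sample_id, treatment, replicate.
#' @export
sampleDesign <- function(object) {
    cd <- as.data.frame(colData(object))
    cd[, c("sample_id", "treatment", "replicate"), drop = FALSE]
}
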