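## TSV readers/writers for the pipeline's artifacts. All files are UTF-8,
## tab-separated, header row, "." decimal separator.

.writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

.readTSV <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a fragment expression matrix with annotation
#'
#' Layout: \code{fragment_id}, \code{gene_id}, \code{group_tag}, then one
#' column per sample.
#'
#' @param x a \linkS4class{FragmentExperiment}.
#' @param path file path.
#' @param assay_name which assay to write (default first).
#' @return \code{writeFragmentCounts}: the path, invisibly.
#' @rdname fragment-io
#' @export
writeFragmentCounts <- function(x, path, assay_name = NULL) {
    a <- assay(x, assay_name %||% 1L)
    df <- data.frame(fragment_id = rownames(x),
                     gene_id = rowData(x)$gene_id,
                     group_tag = rowData(x)$group_tag,
                     a, check.names = FALSE, stringsAsFactors = FALSE)
    .writeTSV(df, path)
}

#' @param design_path path of the design TSV written with
#'   [writeSampleDesign()].
#' @param assay_name assay name for the matrix being read (\code{"counts"}
#'   or \code{"tmm"}).
#' @return \code{readFragmentCounts}: a \linkS4class{FragmentExperiment}.
#' @rdname fragment-io
#' @export
readFragmentCounts <- function(path, design_path,
                               assay_name = c("counts", "tmm")) {
    assay_name <- match.arg(assay_name)
    df <- .readTSV(path)
    design <- .readTSV(design_path)
    meta <- c("fragment_id", "gene_id", "group_tag")
    m <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
    rownames(m) <- df$fragment_id
    if (assay_name == "counts") storage.mode(m) <- "integer"
    FragmentExperiment(m, gene_id = df$gene_id, group_tag = df$group_tag,
                       design = design, assay_name = assay_name)
}

#' Write a sample design table
#' @param design data.frame from [generateDesign()].
#' @param path file path.
#' @export
writeSampleDesign <- function(design, path) .writeTSV(design, path)

#' Read a sample design table
#' @param path file path.
#' @return data.frame with \code{sample_id}, \code{treatment},
#'   \code{replicate}.
#' @export
readSampleDesign <- function(path) .readTSV(path)

#' Write / read BLAST-tabular alignment hits
#'
#' Columns: \code{qseqid sseqid pident length evalue bitscore} (an
#' outfmt-6-like dialect, with a header row).
#'
#' @param hits hit table (or the list from [generateAlignmentHits()], in
#'   which case the expected map is written alongside with suffix
#'   \code{.expected.tsv}).
#' @param path file path.
#' @rdname hits-io
#' @export
writeAlignmentHits <- function(hits, path) {
    if (is.list(hits) && !is.data.frame(hits)) {
        .writeTSV(hits$expected, paste0(path, ".expected.tsv"))
        hits <- hits$hits
    }
    .writeTSV(hits, path)
}

#' @rdname hits-io
#' @export
readAlignmentHits <- function(path) {
    hits <- .readTSV(path)
    exp_path <- paste0(path, ".expected.tsv")
    if (file.exists(exp_path))
        return(list(hits = hits, expected = .readTSV(exp_path)))
    hits
}

#' Write / read a qPCR Ct table
#' @param ct Ct table (see [generateQpcr()]).
#' @param path file path.
#' @rdname ct-io
#' @export
writeCtTable <- function(ct, path) .writeTSV(ct, path)

#' @rdname ct-io
#' @export
readCtTable <- function(path) .readTSV(path)
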