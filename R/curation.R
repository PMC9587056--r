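#' Confirm fragment annotation from alignment hits
#'
#' A fragment's annotation is confirmed when its best alignment hit (highest
#' bit score; ties broken by lowest e-value, then lexicographic subject id)
#' maps back to the expected parent gene with a percent match strictly above
#' the threshold. Fragments without any hit row are rejected (not an error).
#' Subject accessions are matched to genes after stripping a trailing
#' \code{.<version>} suffix.
#'
#' @param hits BLAST-tabular data.frame with columns \code{qseqid},
#'   \code{sseqid}, \code{pident}, \code{length}, \code{evalue},
#'   \code{bitscore}, or the list returned by [generateAlignmentHits()].
#' @param expected data.frame with columns \code{fragment_id} and
#'   \code{gene_id} (the expected parent gene per fragment); also carries the
#'   pathway \code{group_tag} column if available. Ignored when \code{hits}
#'   already bundles its expected map.
#' @param threshold_percent confirmation threshold on percent match
#'   (strict \code{>}; default 50).
#' @param group_tag optional named vector of pathway groups per fragment, for
#'   per-group rates.
#'
#' @return A curation report: list of class \code{"CurationReport"} with
#'   \code{status} (data.frame \code{fragment_id}, \code{status} in
#'   \code{confirmed}/\code{rejected_annotation}), \code{summary}
#'   (\code{n_total}, \code{n_confirmed}, \code{percent_confirmed}) and
#'   \code{per_group} (confirmation percentages per pathway group).
#' @examples
#' hits <- data.frame(qseqid = "f1", sseqid = "geneA.1", pident = 75,
#'                    length = 300, evalue = 1e-50, bitscore = 450)
#' expected <- data.frame(fragment_id = "f1", gene_id = "geneA")
#' confirmAnnotation(hits, expected)$summary
#' @export
confirmAnnotation <- function(hits, expected = NULL, threshold_percent = 50,
                              group_tag = NULL) {
    if (is.list(hits) && !is.data.frame(hits) &&
        all(c("hits", "expected") %in% names(hits))) {
        expected <- hits$expected
        hits <- hits$hits
    }
    if (is.null(expected))
        stop("an expected fragment-to-gene map is required")
    need <- c("qseqid", "sseqid", "pident", "evalue", "bitscore")
    if (!all(need %in% colnames(hits)))
        stop("malformed hit table: missing column(s) ",
             paste(setdiff(need, colnames(hits)), collapse = ", "))
    bad <- which(!is.finite(hits$pident) | hits$pident < 0 | hits$pident > 100)
    if (length(bad))
        stop("malformed hit row: pident out of [0,100] at line ", bad[1L])
    if (nrow(expected) == 0L) stop("'expected' is empty")

    frag <- expected$fragment_id
    status <- rep("rejected_annotation", length(frag))
    if (nrow(hits) > 0L) {
        ## deterministic best hit per query: bitscore desc, evalue asc,
        ## subject id lexicographic
        o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
        h <- hits[o, , drop = FALSE]
        best <- h[!duplicated(h$qseqid), , drop = FALSE]
        m <- match(frag, best$qseqid)
        subject_gene <- sub("\\.[0-9]+$", "", best$sseqid[m])
        ok <- !is.na(m) &
            subject_gene == expected$gene_id &
            best$pident[m] > threshold_percent
        status[ok] <- "confirmed"
    }
    if (is.null(group_tag) && "group_tag" %in% colnames(expected))
        group_tag <- stats::setNames(expected$group_tag, frag)
    .curationReport(frag, status, "confirmed", group_tag,
                    stage = "annotation")
}

#' Filter fragments on expression level
#'
#' A fragment is rejected when (a) any sample value is exactly zero, or (b)
#' its overall mean is below \code{low_floor} (TMM units) and any
#' within-group percent CV exceeds \code{erratic_cv_percent} ("very low and
#' erratic" levels); otherwise it is accepted.
#'
#' @param expr numeric matrix of normalized abundance (fragments x samples)
#'   or a \linkS4class{FragmentExperiment} carrying a \code{tmm} assay.
#' @param design data.frame with \code{sample_id} and \code{treatment};
#'   taken from the experiment when \code{expr} is a
#'   \linkS4class{FragmentExperiment}.
#' @param low_floor expression floor in TMM units (default 5).
#' @param erratic_cv_percent within-group percent CV above which a low
#'   fragment counts as erratic (default 50).
#' @param group_tag optional named vector of pathway groups, for per-group
#'   rates.
#'
#' @return A \code{"CurationReport"} list with per-fragment
#'   \code{accepted}/\code{rejected_expression} status and acceptance
#'   percentages overall and per pathway group.
#' @examples
#' x <- rbind(f1 = c(100, 110, 90, 105), f2 = c(0, 50, 60, 55))
#' d <- data.frame(sample_id = colnames(x, do.NULL = FALSE),
#'                 treatment = c("c", "c", "t", "t"))
#' colnames(x) <- d$sample_id
#' filterExpression(x, d)$status
#' @export
filterExpression <- function(expr, design = NULL, low_floor = 5,
                             erratic_cv_percent = 50, group_tag = NULL) {
    if (methods::is(expr, "FragmentExperiment")) {
        if (is.null(design)) design <- sampleDesign(expr)
        if (is.null(group_tag)) group_tag <- pathwayGroups(expr)
        nm <- if ("tmm" %in% names(assays(expr))) "tmm" else 1L
        expr <- assay(expr, nm)
    }
    expr <- as.matrix(expr)
    if (any(expr < 0)) stop("expression matrix contains negative values")
    if (is.null(design)) stop("a sample design is required")
    grp <- as.character(design$treatment)[match(colnames(expr), design$sample_id)]
    if (any(is.na(grp)))
        stop("samples missing from design: ",
             paste(colnames(expr)[is.na(grp)], collapse = ", "))
    if (any(table(grp) < 2L))
        stop("each treatment group needs >= 2 samples")

    has_zero <- apply(expr == 0, 1L, any)
    frag_mean <- rowMeans(expr)
    cols_by_grp <- split(seq_len(ncol(expr)), grp)
    max_group_cv <- rep(0, nrow(expr))
    for (cols in cols_by_grp) {
        m <- rowMeans(expr[, cols, drop = FALSE])
        s <- apply(expr[, cols, drop = FALSE], 1L, stats::sd)
        cv <- ifelse(m > 0, 100 * s / m, 0)
        max_group_cv <- pmax(max_group_cv, cv)
    }
    reject <- has_zero | (frag_mean < low_floor &
                          max_group_cv > erratic_cv_percent)
    status <- ifelse(reject, "rejected_expression", "accepted")
    .curationReport(rownames(expr), status, "accepted", group_tag,
                    stage = "expression")
}

.curationReport <- function(fragment_id, status, pass_label, group_tag,
                            stage) {
    ok <- status == pass_label
    per_group <- NULL
    if (!is.null(group_tag)) {
        g <- as.character(group_tag[fragment_id])
        tab <- table(g)
        pg <- vapply(names(tab), function(k)
            100 * sum(ok[g == k]) / sum(g == k), numeric(1))
        per_group <- data.frame(group_tag = names(tab),
                                n = as.integer(tab),
                                percent_pass = unname(pg),
                                stringsAsFactors = FALSE)
    }
    structure(list(
        stage = stage,
        status = data.frame(fragment_id = fragment_id, status = status,
                            stringsAsFactors = FALSE),
        summary = list(n_total = length(fragment_id),
                       n_pass = sum(ok),
                       percent_pass = 100 * mean(ok)),
        per_group = per_group), class = "CurationReport")
}

#' @export
print.CurationReport <- function(x, ...) {
    cat(sprintf("CurationReport (%s stage): %d/%d passing (%.1f%%)\n",
                x$stage, x$summary$n_pass, x$summary$n_total,
                x$summary$percent_pass))
    if (!is.null(x$per_group)) {
        for (i in seq_len(nrow(x$per_group)))
            cat(sprintf("  group %s: %.1f%% of %d\n",
                        x$per_group$group_tag[i],
                        x$per_group$percent_pass[i], x$per_group$n[i]))
    }
    invisible(x)
}

#' Run the full curation funnel
#'
#' Annotation confirmation followed by expression filtering; only confirmed
#' fragments are carried into the expression stage, so the accepted set is a
#' subset of the confirmed set.
#'
#' @param experiment a \linkS4class{FragmentExperiment} with a \code{tmm}
#'   assay (see [tmmNormalize()]).
#' @param hits alignment hits (see [confirmAnnotation()]).
#' @param threshold_percent,low_floor,erratic_cv_percent stage thresholds.
#' @return list with both stage reports, the final \code{accepted} fragment
#'   ids and a funnel count vector.
#' @export
curationFunnel <- function(experiment, hits, threshold_percent = 50,
                           low_floor = 5, erratic_cv_percent = 50) {
    ann <- confirmAnnotation(hits, threshold_percent = threshold_percent,
                             group_tag = pathwayGroups(experiment))
    confirmed <- ann$status$fragment_id[ann$status$status == "confirmed"]
    confirmed <- intersect(rownames(experiment), confirmed)
    sub <- experiment[confirmed, ]
    expr <- filterExpression(sub, low_floor = low_floor,
                             erratic_cv_percent = erratic_cv_percent)
    accepted <- expr$status$fragment_id[expr$status$status == "accepted"]
    list(annotation = ann, expression = expr, accepted = accepted,
         funnel = c(total = nrow(experiment),
                    confirmed = length(confirmed),
                    accepted = length(accepted)))
}
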