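#' Percent coefficient of variation
#'
#' \code{100 * sd / mean}; the reference-gene stability measure.
#'
#' @param sd sample standard deviation (n - 1 denominator).
#' @param mean arithmetic mean.
#' @return percent CV (vectorized).
#' @export
cvPercent <- function(sd, mean) 100 * sd / mean

#' Distribution statistics for housekeeping candidates
#'
#' Per candidate transcript, over all samples of all treatments: mean,
#' minimum, maximum, sample SD (n - 1), median and percent CV
#' (\code{100 * SD / mean}), in TMM units.
#'
#' @param expr numeric matrix of TMM abundance (transcripts x samples) or a
#'   \linkS4class{FragmentExperiment} with a \code{tmm} assay.
#' @param candidates transcript ids to evaluate (default: all rows).
#' @return data.frame: \code{transcript_id}, \code{mean}, \code{minimum},
#'   \code{maximum}, \code{sd}, \code{median}, \code{cv_percent}.
#' @examples
#' x <- rbind(t1 = c(100, 100, 100, 100), t2 = 1:4 * 10)
#' hkStats(x)
#' @export
hkStats <- function(expr, candidates = NULL) {
    if (methods::is(expr, "FragmentExperiment")) {
        nm <- if ("tmm" %in% names(assays(expr))) "tmm" else 1L
        expr <- assay(expr, nm)
    }
    expr <- as.matrix(expr)
    if (ncol(expr) < 2L) stop("at least 2 samples are required")
    if (is.null(candidates)) candidates <- rownames(expr)
    missing <- setdiff(candidates, rownames(expr))
    if (length(missing))
        stop("candidates absent from matrix: ",
             paste(missing, collapse = ", "))
    x <- expr[candidates, , drop = FALSE]
    m <- rowMeans(x)
    s <- apply(x, 1L, stats::sd)
    data.frame(
        transcript_id = candidates,
        mean = unname(m),
        minimum = unname(apply(x, 1L, min)),
        maximum = unname(apply(x, 1L, max)),
        sd = unname(s),
        median = unname(apply(x, 1L, stats::median)),
        cv_percent = unname(cvPercent(s, m)),
        stringsAsFactors = FALSE)
}

#' Complete a housekeeping statistics table from printed summaries
#'
#' Recomputes \code{cv_percent = 100 * sd / mean} for a table that already
#' carries summary columns (e.g. a published reference-gene stability table),
#' validating \code{minimum <= median <= maximum} where those columns exist.
#'
#' @param stats data.frame with at least \code{transcript_id}, \code{mean}
#'   and \code{sd}.
#' @return the table with a recomputed \code{cv_percent} column.
#' @export
hkStatsFromSummary <- function(stats) {
    if (!all(c("transcript_id", "mean", "sd") %in% colnames(stats)))
        stop("'stats' needs columns transcript_id, mean, sd")
    if (all(c("minimum", "median", "maximum") %in% colnames(stats)) &&
        any(stats$minimum > stats$median | stats$median > stats$maximum))
        stop("inconsistent summary: minimum <= median <= maximum violated")
    stats$cv_percent <- cvPercent(stats$sd, stats$mean)
    stats
}

#' Select housekeeping transcripts by CV threshold
#'
#' Transcripts with percent CV strictly below \code{cv_max} are retained,
#' sorted by ascending CV. An empty result raises a warning (downstream
#' standardization then refuses to run), not an error.
#'
#' @param stats output of [hkStats()] or [hkStatsFromSummary()].
#' @param cv_max percent CV threshold (default 20).
#' @return the retained rows, sorted by ascending \code{cv_percent}.
#' @examples
#' x <- rbind(t1 = c(100, 102, 98, 100), t2 = c(10, 30, 5, 50))
#' selectHK(hkStats(x))
#' @export
selectHK <- function(stats, cv_max = 20) {
    if (nrow(stats) == 0L) stop("'stats' is empty")
    # zero-mean (unexpressed) candidates have undefined CV: never retained
    keep <- is.finite(stats$cv_percent) & stats$cv_percent < cv_max
    out <- stats[keep, , drop = FALSE]
    out <- out[order(out$cv_percent, out$transcript_id), , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out) == 0L)
        warning("no transcript passes CV% < ", cv_max)
    out
}

#' Housekeeping-referenced standardization of TMM expression
#'
#' For each housekeeping gene h and sample s, the control-referenced ratio is
#' \code{r[h, s] = TMM[h, s] / mean(TMM[h, control samples])}. The per-sample
#' standardization factor is the arithmetic mean of these ratios over the
#' housekeeping set (\code{mode = "per_sample"}), or that mean further
#' averaged over the replicates of each treatment
#' (\code{mode = "per_treatment"}). Standardized expression is
#' \code{E'[g, s] = TMM[g, s] / F[s]}, and the relative-to-control table is
#' \code{R[g, t] = mean(E'[g, s in t]) / mean(E'[g, s in control])}.
#'
#' @param expr TMM matrix (rows x samples) to standardize.
#' @param hk character vector of housekeeping ids, or the data.frame from
#'   [selectHK()].
#' @param design data.frame with \code{sample_id} and \code{treatment}.
#' @param control control group label (default \code{"control"}).
#' @param hk_expr matrix holding the housekeeping rows (defaults to
#'   \code{expr}; pass a gene-level matrix when \code{expr} is
#'   fragment-level).
#' @param mode \code{"per_sample"} (default) or \code{"per_treatment"}.
#' @return list with \code{factors} (data.frame \code{sample_id},
#'   \code{factor}), \code{hk}, \code{standardized} (matrix like
#'   \code{expr}) and \code{relative} (rows x treatments matrix R).
#' @examples
#' x <- rbind(hk1 = c(100, 100, 120, 110), g1 = c(50, 54, 20, 28))
#' colnames(x) <- c("c1", "c2", "t1", "t2")
#' d <- data.frame(sample_id = colnames(x),
#'                 treatment = c("control", "control", "CPF6", "CPF6"))
#' standardize(x, "hk1", d)$relative
#' @export
standardize <- function(expr, hk, design, control = "control",
                        hk_expr = expr,
                        mode = c("per_sample", "per_treatment")) {
    mode <- match.arg(mode)
    if (is.data.frame(hk)) hk <- hk$transcript_id
    if (length(hk) == 0L) stop("housekeeping set is empty")
    expr <- as.matrix(expr)
    hk_expr <- as.matrix(hk_expr)
    missing <- setdiff(hk, rownames(hk_expr))
    if (length(missing))
        stop("housekeeping ids absent from matrix: ",
             paste(missing, collapse = ", "))
    grp <- as.character(design$treatment)[match(colnames(expr),
                                                design$sample_id)]
    ctrl <- which(grp == control)
    if (length(ctrl) < 2L)
        stop("control group '", control, "' needs >= 2 replicates")
    hx <- hk_expr[hk, colnames(expr), drop = FALSE]
    ctrl_mean <- rowMeans(hx[, ctrl, drop = FALSE])
    if (any(ctrl_mean == 0))
        stop("housekeeping gene(s) with zero control mean: ",
             paste(hk[ctrl_mean == 0], collapse = ", "))
    r <- sweep(hx, 1L, ctrl_mean, "/")
    f <- colMeans(r)
    if (mode == "per_treatment")
        f <- stats::ave(f, grp)
    std <- sweep(expr, 2L, f, "/")
    treatments <- unique(grp)
    rel <- vapply(treatments, function(t)
        rowMeans(std[, grp == t, drop = FALSE]), numeric(nrow(std)))
    rel <- matrix(rel, nrow = nrow(std),
                  dimnames = list(rownames(expr), treatments))
    rel <- rel / rel[, control]
    list(factors = data.frame(sample_id = colnames(expr), factor = unname(f),
                              stringsAsFactors = FALSE),
         hk = hk, control_means = ctrl_mean,
         standardized = std, relative = rel)
}
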