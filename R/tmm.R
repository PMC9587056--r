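#' Trimmed mean of M-values (TMM) scale factors
#'
#' Computes per-sample between-library scale factors from raw counts. The
#' reference sample is the one whose 75th-percentile count fraction is
#' closest to the mean of those fractions. For each sample k versus the
#' reference r, per-row log-ratios \code{M = log2((y_k/N_k)/(y_r/N_r))} and
#' average log-abundances \code{A = 0.5 log2((y_k/N_k)(y_r/N_r))} are formed
#' over rows positive in both libraries, doubly trimmed (\code{trim_m} of the
#' M tails, \code{trim_a} of the A tails), and averaged with
#' inverse-asymptotic-variance weights
#' \code{1 / ((N_k - y_k)/(N_k y_k) + (N_r - y_r)/(N_r y_r))}; the factor is
#' \code{2^(weighted mean M)}. Factors are rescaled so their geometric mean
#' is 1.
#'
#' @param counts integer matrix (rows x samples) or a
#'   \linkS4class{FragmentExperiment}.
#' @param trim_m fraction trimmed from each tail of M (default 0.30).
#' @param trim_a fraction trimmed from each tail of A (default 0.05).
#' @return named numeric vector of factors, one per sample, geometric mean 1.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30, 40, 50, 60),
#'            s2 = c(20, 40, 60, 80, 100, 120))
#' tmmFactors(m)  # proportional libraries: both 1
#' @export
tmmFactors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
    if (methods::is(counts, "SummarizedExperiment"))
        counts <- assay(counts, 1L)
    counts <- as.matrix(counts)
    if (ncol(counts) < 2L) stop("at least 2 samples are required")
    lib <- colSums(counts)
    if (any(lib <= 0)) stop("library sizes must be > 0")
    f75 <- apply(counts, 2L, function(x) stats::quantile(x, 0.75)) / lib
    ref <- which.min(abs(f75 - mean(f75)))
    f <- vapply(seq_len(ncol(counts)), function(k)
        .tmmPair(counts[, k], counts[, ref], lib[k], lib[ref],
                 trim_m, trim_a,
                 sample_name = colnames(counts)[k]), numeric(1))
    f <- f / exp(mean(log(f)))
    stats::setNames(f, colnames(counts))
}

.tmmPair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a,
                     sample_name = NULL) {
    pos <- obs > 0 & ref > 0
    if (!any(pos))
        stop("sample ", sample_name %||% "?",
             " shares no positive rows with the reference")
    obs <- obs[pos]; ref <- ref[pos]
    logR <- log2((obs / n_obs) / (ref / n_ref))
    absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
    v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(logR); rA <- rank(absE)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    w <- 1 / v[keep]
    2^(sum(w * logR[keep]) / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TMM-normalize a FragmentExperiment
#'
#' Adds a \code{tmm} assay: \code{count / (library size x factor) * 1e6}
#' (counts per million on the effective library). Factors are stored in
#' \code{colData(x)$tmm_factor}.
#'
#' @param x a \linkS4class{FragmentExperiment} with a \code{counts} assay.
#' @param trim_m,trim_a trim fractions passed to [tmmFactors()].
#' @return \code{x} with an added \code{tmm} assay.
#' @export
tmmNormalize <- function(x, trim_m = 0.30, trim_a = 0.05) {
    stopifnot(methods::is(x, "FragmentExperiment"))
    counts <- assay(x, "counts")
    f <- tmmFactors(counts, trim_m, trim_a)
    lib <- colSums(counts)
    tmm <- sweep(counts, 2L, lib * f, "/") * 1e6
    SummarizedExperiment::assays(x)$tmm <- tmm
    colData(x)$tmm_factor <- unname(f)
    x
}

#' Collapse fragments to gene-level counts
#'
#' Column-preserving sum of each gene's fragment rows; genes ordered
#' lexicographically.
#'
#' @param x a \linkS4class{FragmentExperiment}, or a matrix together with
#'   \code{gene_id}.
#' @param gene_id parent gene per row (ignored for a
#'   \linkS4class{FragmentExperiment}).
#' @param assay_name which assay to collapse (default first).
#' @return matrix (genes x samples), same column order.
#' @examples
#' m <- rbind(f1 = c(3, 5), f2 = c(7, 5))
#' collapseFragments(m, gene_id = c("g1", "g1"))
#' @export
collapseFragments <- function(x, gene_id = NULL, assay_name = NULL) {
    if (methods::is(x, "SummarizedExperiment")) {
        gene_id <- rowData(x)$gene_id
        x <- assay(x, assay_name %||% 1L)
    }
    x <- as.matrix(x)
    if (is.null(gene_id) || length(gene_id) != nrow(x))
        stop("'gene_id' must have one entry per row")
    g <- factor(as.character(gene_id))
    out <- rowsum(x, g, reorder = TRUE)
    out[order(rownames(out)), , drop = FALSE]
}
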