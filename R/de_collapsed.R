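## Collapsed-gene negative-binomial exact testing (classic exact-test style,
## implemented from first principles with a method-of-moments common
## dispersion).

#' Method-of-moments common dispersion
#'
#' On library-size-normalized counts (scaled to the geometric-mean library),
#' each gene's within-group mean m and sample variance s^2 are combined
#' across replicated groups as
#' \code{phi_g = max(0, sum_grp(s^2 - m) / sum_grp(m^2))}; the common
#' dispersion is the median of \code{phi_g} over genes whose overall mean
#' exceeds \code{min_mean}.
#'
#' @param gc gene-level count matrix (genes x samples), see
#'   [collapseFragments()].
#' @param design data.frame with \code{sample_id}, \code{treatment}.
#' @param min_mean minimum normalized mean for a gene to inform the estimate
#'   (default 5).
#' @return the common dispersion phi (>= 0).
#' @export
estimateCommonDispersion <- function(gc, design, min_mean = 5) {
    gc <- as.matrix(gc)
    grp <- as.character(design$treatment)[match(colnames(gc),
                                                design$sample_id)]
    sizes <- table(grp)
    rep_groups <- names(sizes)[sizes >= 2L]
    if (length(rep_groups) == 0L)
        stop("no treatment group with replication")
    lib <- colSums(gc)
    y <- sweep(gc, 2L, lib, "/") * exp(mean(log(lib)))
    num <- rep(0, nrow(gc))
    den <- rep(0, nrow(gc))
    for (t in rep_groups) {
        cols <- which(grp == t)
        m <- rowMeans(y[, cols, drop = FALSE])
        s2 <- apply(y[, cols, drop = FALSE], 1L, stats::var)
        num <- num + (s2 - m)
        den <- den + m^2
    }
    phi_g <- pmax(0, ifelse(den > 0, num / den, 0))
    use <- rowMeans(y) > min_mean
    if (!any(use)) return(0)
    stats::median(phi_g[use])
}

#' Two-group negative-binomial exact test for one gene
#'
#' Conditions on the pooled total of the two group sums: with group sums
#' modeled as negative binomial with means proportional to the effective
#' library sizes and common dispersion phi, the two-sided p-value sums the
#' conditional probabilities of all splits of the total as or less likely
#' than the observed one. Unequal effective library sizes are handled by
#' deterministic linear rescaling of each group sum to the geometric-mean
#' effective library (rounded) before conditioning. The reported fold change
#' is \code{log2FC = log2((a1 + c)/(a2 + c))} with abundances a on the
#' counts-per-geometric-mean-library scale and prior count c.
#'
#' @param y1,y2 counts per sample in the treated and control group.
#' @param lib1,lib2 effective library sizes (raw library size x TMM factor)
#'   per sample; default 1 per sample (equal libraries).
#' @param phi common NB dispersion (0 gives the Poisson/binomial limit).
#' @param prior_count prior count c for fold-change stabilization
#'   (default 0.5).
#' @param max_enumerate totals up to this are fully enumerated; larger
#'   totals use a support window holding all but ~1e-14 of the conditional
#'   mass.
#' @return list: \code{p}, \code{log2FC}, \code{s1}, \code{s2} (adjusted
#'   group sums).
#' @examples
#' nbExactTest(c(9, 6), c(3, 2), phi = 0.1)
#' @export
nbExactTest <- function(y1, y2, lib1 = rep(1, length(y1)),
                        lib2 = rep(1, length(y2)), phi = 0,
                        prior_count = 0.5, max_enumerate = 5000) {
    if (length(y1) < 1L || length(y2) < 1L)
        stop("both groups need >= 1 sample")
    if (phi < 0) stop("'phi' must be >= 0")
    n1 <- length(y1); n2 <- length(y2)
    S1 <- sum(y1); S2 <- sum(y2)
    L1 <- sum(lib1); L2 <- sum(lib2)
    Lbar <- exp(mean(log(c(lib1, lib2))))
    a1 <- S1 / L1 * Lbar
    a2 <- S2 / L2 * Lbar
    log2FC <- log2((a1 / n1 + prior_count) / (a2 / n2 + prior_count))
    ## adjusted integer group sums on a common library scale
    equal_libs <- all(abs(c(lib1, lib2) / Lbar - 1) < 1e-12)
    s1 <- if (equal_libs) S1 else round(S1 * n1 * Lbar / L1)
    s2 <- if (equal_libs) S2 else round(S2 * n2 * Lbar / L2)
    T <- s1 + s2
    if (T == 0)
        return(list(p = 1, log2FC = 0, s1 = s1, s2 = s2))
    m <- T / (n1 + n2)
    logf <- function(s) {
        if (phi < 1e-12) {
            stats::dbinom(s, T, n1 / (n1 + n2), log = TRUE)
        } else {
            stats::dnbinom(s, size = n1 / phi, mu = n1 * m, log = TRUE) +
                stats::dnbinom(T - s, size = n2 / phi, mu = n2 * m,
                               log = TRUE)
        }
    }
    if (T <= max_enumerate) {
        s <- 0:T
    } else {
        if (phi < 1e-12) {
            lo <- stats::qbinom(1e-14, T, n1 / (n1 + n2))
            hi <- stats::qbinom(1e-14, T, n1 / (n1 + n2), lower.tail = FALSE)
        } else {
            lo <- min(stats::qnbinom(1e-14, size = n1 / phi, mu = n1 * m),
                      T - stats::qnbinom(1e-14, size = n2 / phi, mu = n2 * m,
                                         lower.tail = FALSE))
            hi <- max(stats::qnbinom(1e-14, size = n1 / phi, mu = n1 * m,
                                     lower.tail = FALSE),
                      T - stats::qnbinom(1e-14, size = n2 / phi, mu = n2 * m))
        }
        s <- max(0, lo):min(T, hi)
        if (!(s1 %in% s)) s <- sort(unique(c(s, s1)))
    }
    lf <- logf(s)
    lmax <- max(lf)
    f <- exp(lf - lmax)
    f_obs <- exp(logf(s1) - lmax)
    p <- sum(f[f <= f_obs * (1 + 1e-12)]) / sum(f)
    list(p = min(1, p), log2FC = unname(log2FC), s1 = s1, s2 = s2)
}

#' Call differentially expressed genes
#'
#' \code{up} when fold change >= \code{fc_threshold} and p <= \code{p_max};
#' \code{down} when fold change <= 1/\code{fc_threshold} and p <=
#' \code{p_max}; otherwise \code{none}.
#'
#' @param results data.frame with \code{log2FC} and \code{p} columns.
#' @param fc_threshold fold-change threshold (default 2).
#' @param p_max p-value threshold (default 0.05).
#' @return \code{results} with an added \code{call} column.
#' @export
callDEGs <- function(results, fc_threshold = 2, p_max = 0.05) {
    if (nrow(results) == 0L) stop("'results' is empty")
    lfc <- log2(fc_threshold)
    results$call <- ifelse(
        results$p <= p_max & results$log2FC >= lfc, "up",
        ifelse(results$p <= p_max & results$log2FC <= -lfc, "down", "none"))
    results
}

#' Rank called DEGs by fold-change magnitude
#'
#' Significant DEGs are ranked 1..K by descending |log2FC| (ties: smaller p
#' first, then gene id) and binned: top-10, 10-50, 50-100, 100-500,
#' 500-1500, >1500; uncalled genes get bin NS.
#'
#' @param results output of [callDEGs()] for one comparison pair.
#' @return \code{results} with added \code{rank} (NA for uncalled) and
#'   \code{bin} columns.
#' @export
rankDEGs <- function(results) {
    called <- results$call != "none"
    results$rank <- NA_integer_
    if (any(called)) {
        sub <- results[called, , drop = FALSE]
        o <- order(-abs(sub$log2FC), sub$p, sub$gene_id)
        results$rank[called][o] <- seq_len(sum(called))
    }
    results$bin <- ifelse(
        !called, "NS",
        ifelse(results$rank <= 10, "top-10",
        ifelse(results$rank <= 50, "10-50",
        ifelse(results$rank <= 100, "50-100",
        ifelse(results$rank <= 500, "100-500",
        ifelse(results$rank <= 1500, "500-1500", ">1500"))))))
    results
}

#' Collapsed-gene NB differential expression across all pairs
#'
#' Collapses fragments to gene counts, estimates the common dispersion,
#' runs the NB exact test for every treated-versus-control pair, calls and
#' ranks DEGs.
#'
#' @param experiment a \linkS4class{FragmentExperiment} with raw counts.
#' @param control control group label.
#' @param phi common dispersion; estimated with
#'   [estimateCommonDispersion()] when NULL.
#' @param tmm_factors per-sample TMM factors; computed when NULL. Effective
#'   library size = raw library size x factor.
#' @param fc_threshold,p_max DEG calling thresholds.
#' @param prior_count fold-change prior count.
#' @return list: \code{results} (per gene x pair, with calls, ranks, bins),
#'   \code{dispersion}.
#' @export
nbDE <- function(experiment, control = "control", phi = NULL,
                 tmm_factors = NULL, fc_threshold = 2, p_max = 0.05,
                 prior_count = 0.5) {
    counts <- assay(experiment, "counts")
    design <- sampleDesign(experiment)
    gc <- collapseFragments(counts, rowData(experiment)$gene_id)
    if (is.null(tmm_factors)) tmm_factors <- tmmFactors(counts)
    eff_lib <- colSums(counts) * tmm_factors[colnames(counts)]
    if (is.null(phi)) phi <- estimateCommonDispersion(gc, design)
    grp <- as.character(design$treatment)[match(colnames(gc),
                                                design$sample_id)]
    other <- setdiff(unique(grp), control)
    out <- vector("list", length(other))
    for (j in seq_along(other)) {
        t <- other[j]
        c1 <- which(grp == t); c2 <- which(grp == control)
        res <- lapply(seq_len(nrow(gc)), function(i) {
            r <- nbExactTest(gc[i, c1], gc[i, c2],
                             eff_lib[c1], eff_lib[c2], phi = phi,
                             prior_count = prior_count)
            data.frame(gene_id = rownames(gc)[i], pair = t,
                       log2FC = r$log2FC, p = r$p,
                       stringsAsFactors = FALSE)
        })
        res <- do.call(rbind, res)
        res$dispersion <- phi
        out[[j]] <- rankDEGs(callDEGs(res, fc_threshold, p_max))
    }
    list(results = do.call(rbind, out), dispersion = phi)
}
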