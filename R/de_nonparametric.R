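## Exact nonparametric tests treating a gene's accepted fragments x
## replicates as observations.

## Cache of combination index matrices (two-group enumeration) and of
## permutation index matrices (Monte-Carlo), keyed by problem signature.
.enumCache <- new.env(parent = emptyenv())

.combnIndex <- function(N, n1) {
    key <- paste0("c", N, "_", n1)
    if (is.null(.enumCache[[key]]))
        .enumCache[[key]] <- utils::combn(N, n1)
    .enumCache[[key]]
}

.assignmentsCached <- function(sizes) {
    key <- paste0("a", paste(sizes, collapse = "_"))
    if (is.null(.enumCache[[key]]))
        .enumCache[[key]] <- .multinomialAssignments(sizes)
    .enumCache[[key]]
}

## Null distribution of the enumeration statistic. For a given rank multiset
## and group-size layout the distribution is identical across genes, so it
## is cached: with continuous data (no ties) the ranks are always 1..N and
## every gene with the same layout shares one distribution.
.nullDistCached <- function(kind, sizes, r, compute) {
    key <- paste0(kind, paste(sizes, collapse = "_"), "|",
                  paste(sort(r), collapse = ","))
    if (is.null(.enumCache[[key]]))
        .enumCache[[key]] <- compute()
    .enumCache[[key]]
}

.midranks <- function(x) rank(x, ties.method = "average")

.tieCorrection <- function(x) {
    N <- length(x)
    t <- table(x)
    1 - sum(t^3 - t) / (N^3 - N)
}

.hFromGroupSums <- function(sums, sizes, N, C) {
    rbar <- (N + 1) / 2
    h <- (12 / (N * (N + 1))) * colSums((sums / sizes - rbar)^2 * sizes)
    h / C
}

## All distinct assignments of N items to groups of the given sizes:
## returns a matrix (N x n_assignments) of group labels.
.multinomialAssignments <- function(sizes) {
    k <- length(sizes)
    N <- sum(sizes)
    recurse <- function(avail, gi) {
        if (gi == k)
            return(matrix(avail, ncol = 1L))
        cmb <- utils::combn(length(avail), sizes[gi])
        out <- vector("list", ncol(cmb))
        for (j in seq_len(ncol(cmb))) {
            pick <- avail[cmb[, j]]
            rest <- recurse(avail[-cmb[, j]], gi + 1L)
            out[[j]] <- rbind(matrix(pick, nrow = sizes[gi],
                                     ncol = ncol(rest)), rest)
        }
        do.call(cbind, out)
    }
    recurse(seq_len(N), 1L)
}

#' Exact Kruskal-Wallis test
#'
#' Tie-corrected H statistic on midranks, with the p-value taken from the
#' permutation null: full enumeration of all distinct assignments of the
#' observations to the group sizes when feasible, otherwise seeded
#' Monte-Carlo sampling, otherwise (flagged) the chi-square approximation.
#' Two-group layouts are enumerated whenever \code{choose(N, n1)} is at most
#' \code{enum_cap}; multi-group layouts whenever the total N is at most
#' \code{exact_limit}.
#'
#' @param x numeric observations (or a list of per-group vectors, in which
#'   case \code{g} is ignored).
#' @param g group labels, same length as \code{x}.
#' @param exact_limit largest total N fully enumerated for k > 2 groups
#'   (default 10).
#' @param enum_cap largest \code{choose(N, n1)} enumerated for k = 2 groups.
#' @param n_perm Monte-Carlo permutations beyond the exact regime.
#' @param seed optional seed for the Monte-Carlo path.
#' @param perm_matrix optional pre-built permutation index matrix
#'   (N x n_perm), e.g. shared across genes.
#' @param method \code{"auto"} (default), or force \code{"exact"},
#'   \code{"perm"}, \code{"chisq"}.
#' @return list: \code{statistic} (H), \code{p.value}, \code{method}.
#' @examples
#' kruskalWallisExact(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
kruskalWallisExact <- function(x, g = NULL, exact_limit = 10,
                               enum_cap = 200000, n_perm = 100000,
                               seed = NULL, perm_matrix = NULL,
                               method = c("auto", "exact", "perm", "chisq")) {
    method <- match.arg(method)
    if (is.list(x)) {
        g <- rep(seq_along(x), lengths(x))
        x <- unlist(x, use.names = FALSE)
    }
    g <- factor(g)
    sizes <- as.integer(table(g))
    if (any(sizes == 0L)) stop("empty group")
    k <- nlevels(g)
    if (k < 2L) stop("at least 2 groups are required")
    N <- length(x)
    if (N < 3L) stop("total N must be >= 3")
    if (length(unique(x)) == 1L)
        return(list(statistic = 0, p.value = 1, method = "degenerate"))

    r <- .midranks(x)
    C <- .tieCorrection(x)
    obs_sums <- as.numeric(rowsum(r, g))
    H <- .hFromGroupSums(matrix(obs_sums, ncol = 1L), sizes, N, C)
    eps <- 1e-9 * max(1, H)

    exact_ok <- (k == 2L && choose(N, sizes[1L]) <= enum_cap) ||
        N <= exact_limit
    if (method == "exact" && !exact_ok)
        stop("exact enumeration infeasible for this layout")
    if (method == "auto")
        method <- if (exact_ok) "exact" else "perm"

    if (method == "exact") {
        if (k == 2L) {
            dev <- .nullDistCached("t", sizes, r, function() {
                idx <- .combnIndex(N, sizes[1L])
                s1 <- colSums(matrix(r[idx], nrow = sizes[1L]))
                abs(s1 - sizes[1L] * (N + 1) / 2)
            })
            dev_obs <- abs(obs_sums[1L] - sizes[1L] * (N + 1) / 2)
            p <- mean(dev >= dev_obs - 1e-9)
        } else {
            hs <- .nullDistCached("h", sizes, r, function() {
                asg <- .assignmentsCached(sizes)
                lab <- rep.int(seq_len(k), sizes)
                sums <- rowsum(matrix(r[asg], nrow = N), lab)
                .hFromGroupSums(sums, sizes, N, C)
            })
            p <- mean(hs >= H - eps)
        }
    } else if (method == "perm") {
        if (is.null(perm_matrix)) {
            if (!is.null(seed)) set.seed(seed)
            perm_matrix <- vapply(seq_len(n_perm), function(i) sample.int(N),
                                  integer(N))
        }
        sums <- rowsum(matrix(r[perm_matrix], nrow = N), as.integer(g))
        hs <- .hFromGroupSums(sums, sizes, N, C)
        p <- (1 + sum(hs >= H - eps)) / (ncol(perm_matrix) + 1)
    } else {
        p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    }
    list(statistic = unname(H), p.value = p, method = method)
}

#' Mood's median test
#'
#' Observations are dichotomized at the grand median (strictly above vs at or
#' below), forming a 2 x k table. The p-value is exact by conditional
#' enumeration over all tables with the observed margins (summing the
#' multivariate hypergeometric probabilities of tables as or less likely
#' than the observed one) when total N is at most \code{exact_limit},
#' otherwise a chi-square test on the table (with continuity correction for
#' 2 x 2).
#'
#' @inheritParams kruskalWallisExact
#' @param exact_limit largest N handled by full table enumeration.
#' @return list: \code{statistic} (chi-square of the table), \code{p.value},
#'   \code{method}, \code{table}.
#' @examples
#' medianTest(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
medianTest <- function(x, g = NULL, exact_limit = 10) {
    if (is.list(x)) {
        g <- rep(seq_along(x), lengths(x))
        x <- unlist(x, use.names = FALSE)
    }
    g <- factor(g)
    sizes <- as.integer(table(g))
    if (any(sizes == 0L)) stop("empty group")
    k <- nlevels(g)
    N <- length(x)
    med <- stats::median(x)
    above <- x > med
    m <- sum(above)
    tab <- rbind(below_or_equal = as.integer(table(g[!above])),
                 above = as.integer(table(g[above])))
    colnames(tab) <- levels(g)
    if (m == 0L || m == N)
        return(list(statistic = 0, p.value = 1, method = "degenerate",
                    table = tab))
    stat <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$statistic)
    if (N <= exact_limit) {
        p_obs <- prod(choose(sizes, tab["above", ])) / choose(N, m)
        p <- .medianExactP(sizes, m, p_obs)
        method <- "exact"
    } else {
        correct <- k == 2L
        p <- suppressWarnings(
            stats::chisq.test(tab, correct = correct)$p.value)
        method <- "chisq"
    }
    list(statistic = unname(stat), p.value = p, method = method, table = tab)
}

## Sum the probabilities of all 2 x k tables with fixed margins whose
## probability is <= p_obs (up to numerical tolerance).
.medianExactP <- function(sizes, m, p_obs) {
    k <- length(sizes)
    total <- choose(sum(sizes), m)
    acc <- 0
    recurse <- function(gi, left, prob) {
        if (gi == k) {
            if (left >= 0 && left <= sizes[k]) {
                pr <- prob * choose(sizes[k], left) / total
                if (pr <= p_obs * (1 + 1e-7)) acc <<- acc + pr
            }
            return(invisible(NULL))
        }
        for (xi in 0:min(sizes[gi], left))
            recurse(gi + 1L, left - xi, prob * choose(sizes[gi], xi))
    }
    recurse(1L, m, 1)
    min(1, acc)
}

#' Pairwise treated-versus-control exact rank tests
#'
#' One two-group exact rank test (Kruskal-Wallis with k = 2, the exact
#' two-sided rank-sum) per non-control treatment.
#'
#' @param values numeric observations.
#' @param groups treatment label per observation.
#' @param control control label.
#' @param ... passed to [kruskalWallisExact()].
#' @return data.frame: \code{treatment}, \code{p}, \code{method}.
#' @examples
#' pairwiseVsControl(c(10, 11, 20, 21), c("c", "c", "t", "t"), control = "c")
#' @export
pairwiseVsControl <- function(values, groups, control = "control", ...) {
    groups <- as.character(groups)
    if (!control %in% groups) stop("control group '", control, "' not found")
    other <- setdiff(unique(groups), control)
    res <- lapply(other, function(t) {
        sel <- groups %in% c(t, control)
        kw <- kruskalWallisExact(values[sel], groups[sel], ...)
        data.frame(treatment = t, p = kw$p.value, method = kw$method,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Classify a relative-expression response
#'
#' Two-tier calling mirroring figure annotation practice: significant at
#' \code{p <= alpha}, a tendency at \code{alpha < p <= tendency}, otherwise
#' NS (direction suppressed). The magnitude bin is taken on
#' \code{max(R, 1/R)}: below 2-fold, 2-4-fold, above 4-fold.
#'
#' @param R relative expression versus control (> 0); vectorized.
#' @param p pairwise p-value(s).
#' @param alpha significance threshold (default 0.05).
#' @param tendency tendency threshold (default 0.10).
#' @return data.frame: \code{direction} (\code{up}/\code{down}), \code{tier}
#'   (\code{significant}/\code{tendency}/\code{NS}), \code{magnitude}
#'   (\code{"<2-fold"}, \code{"2-4-fold"}, \code{">4-fold"}),
#'   \code{category} (e.g. \code{"down/significant/<2-fold"}, or
#'   \code{"NS"}).
#' @examples
#' classifyResponse(c(0.6, 3.0, 1.5), c(0.04, 0.01, 0.09))
#' @export
classifyResponse <- function(R, p, alpha = 0.05, tendency = 0.10) {
    if (any(!is.finite(R) | R <= 0)) stop("'R' must be positive and finite")
    direction <- ifelse(R > 1, "up", "down")
    tier <- ifelse(p <= alpha, "significant",
                   ifelse(p <= tendency, "tendency", "NS"))
    fold <- pmax(R, 1 / R)
    magnitude <- ifelse(fold < 2, "<2-fold",
                        ifelse(fold < 4, "2-4-fold", ">4-fold"))
    category <- ifelse(tier == "NS", "NS",
                       paste(direction, tier, magnitude, sep = "/"))
    data.frame(direction = direction, tier = tier, magnitude = magnitude,
               category = category, stringsAsFactors = FALSE)
}

#' Per-gene nonparametric differential expression
#'
#' Uses a gene's accepted fragments x replicates as observations: omnibus
#' Kruskal-Wallis across all treatments, Mood's median test, exact pairwise
#' treated-versus-control rank tests, relative expression and two-tier
#' response classification.
#'
#' @param std standardized expression matrix (fragments x samples), e.g.
#'   \code{standardize(...)$standardized}.
#' @param gene_id parent gene per row of \code{std}.
#' @param design data.frame with \code{sample_id}, \code{treatment}.
#' @param control control group label.
#' @param accepted fragment ids to use (default: all rows).
#' @param alpha,tendency classification thresholds.
#' @param n_perm Monte-Carlo permutations for the omnibus test beyond the
#'   exact regime; one seeded permutation set is shared across genes.
#' @param seed seed for the shared permutation set.
#' @param exact_limit,enum_cap exact-regime limits, see
#'   [kruskalWallisExact()].
#' @return list with \code{genes} (gene_id, n_obs, H, p_kw, p_median) and
#'   \code{pairs} (gene_id, treatment, p, R, direction, tier, magnitude,
#'   category).
#' @export
nonparametricDE <- function(std, gene_id, design, control = "control",
                            accepted = NULL, alpha = 0.05, tendency = 0.10,
                            n_perm = 2000, seed = 1L, exact_limit = 10,
                            enum_cap = 200000) {
    std <- as.matrix(std)
    if (length(gene_id) != nrow(std))
        stop("'gene_id' must have one entry per row")
    if (!is.null(accepted)) {
        keep <- rownames(std) %in% accepted
        std <- std[keep, , drop = FALSE]
        gene_id <- gene_id[keep]
    }
    grp <- as.character(design$treatment)[match(colnames(std),
                                                design$sample_id)]
    treatments <- unique(grp)
    if (!control %in% treatments) stop("control group not present")
    rows_by_gene <- split(seq_len(nrow(std)), gene_id)
    perm_cache <- new.env(parent = emptyenv())
    genes <- vector("list", length(rows_by_gene))
    pairs <- vector("list", length(rows_by_gene))
    for (i in seq_along(rows_by_gene)) {
        gid <- names(rows_by_gene)[i]
        idx <- rows_by_gene[[i]]
        vals <- as.vector(std[idx, , drop = FALSE])
        obs_grp <- rep(grp, each = length(idx))
        N <- length(vals)
        key <- as.character(N)
        exact_ok <- N <= exact_limit
        pm <- NULL
        if (!exact_ok) {
            if (is.null(perm_cache[[key]])) {
                set.seed(.streamSeed(seed, paste0("np_perm_", N)))
                perm_cache[[key]] <- vapply(seq_len(n_perm),
                                            function(j) sample.int(N),
                                            integer(N))
            }
            pm <- perm_cache[[key]]
        }
        kw <- kruskalWallisExact(vals, obs_grp, exact_limit = exact_limit,
                                 enum_cap = enum_cap, perm_matrix = pm)
        md <- medianTest(vals, obs_grp, exact_limit = exact_limit)
        pw <- pairwiseVsControl(vals, obs_grp, control = control,
                                exact_limit = exact_limit,
                                enum_cap = enum_cap, n_perm = n_perm,
                                seed = .streamSeed(seed, paste0("pw_", gid)))
        mean_ctrl <- mean(vals[obs_grp == control])
        Rt <- vapply(pw$treatment, function(t)
            mean(vals[obs_grp == t]) / mean_ctrl, numeric(1))
        Rt[!is.finite(Rt) | Rt <= 0] <- NA_real_
        cls <- classifyResponse(ifelse(is.na(Rt), 1, Rt), pw$p,
                                alpha = alpha, tendency = tendency)
        genes[[i]] <- data.frame(gene_id = gid, n_obs = N,
                                 H = kw$statistic, p_kw = kw$p.value,
                                 p_median = md$p.value,
                                 stringsAsFactors = FALSE)
        pairs[[i]] <- data.frame(gene_id = gid, treatment = pw$treatment,
                                 p = pw$p, R = unname(Rt), cls,
                                 stringsAsFactors = FALSE)
    }
    list(genes = do.call(rbind, genes),
         pairs = do.call(rbind, pairs))
}
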