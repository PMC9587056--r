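# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (label-permutation enumeration, literal
# formula evaluation) through code paths disjoint from the package's.

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- all_perms(n - 1L)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }
    do.call(rbind, out)
}

# all distinct orderings of a label vector (cached per size/multiset)
.perm_cache <- new.env(parent = emptyenv())
distinct_label_perms <- function(labels) {
    key <- paste(c(length(labels), sort(labels)), collapse = "|")
    if (is.null(.perm_cache[[key]])) {
        pk <- paste0("p", length(labels))
        if (is.null(.perm_cache[[pk]]))
            .perm_cache[[pk]] <- all_perms(length(labels))
        p <- .perm_cache[[pk]]
        m <- matrix(sort(labels)[p], nrow(p), ncol(p))
        .perm_cache[[key]] <- unique(m)
    }
    .perm_cache[[key]]
}

oracle_h_stat <- function(x, g) {
    r <- rank(x)
    N <- length(x)
    tb <- table(r)
    C <- 1 - sum(tb^3 - tb) / (N^3 - N)
    ssq <- sum(tapply(r, g, function(v)
        length(v) * (mean(v) - (N + 1) / 2)^2))
    h <- (12 / (N * (N + 1))) * ssq
    if (C == 0) 0 else h / C
}

# exact Kruskal-Wallis p by full enumeration of label assignments
oracle_kw_p <- function(x, g) {
    h_obs <- oracle_h_stat(x, g)
    perms <- distinct_label_perms(as.character(g))
    hs <- apply(perms, 1L, function(lab) oracle_h_stat(x, lab))
    mean(hs >= h_obs - 1e-9)
}

# exact Mood's median test p: fraction of label assignments whose
# above/below table is as or less frequent than the observed one
oracle_median_p <- function(x, g) {
    med <- median(x)
    above <- x > med
    if (all(above) || !any(above)) return(1)
    tab_key <- function(lab) paste(tapply(above, lab, sum)[sort(unique(lab))],
                                   collapse = "_")
    perms <- distinct_label_perms(as.character(g))
    keys <- apply(perms, 1L, tab_key)
    freq <- table(keys) / length(keys)
    p_obs <- freq[[tab_key(as.character(g))]]
    sum(freq[freq <= p_obs * (1 + 1e-7)])
}

# literal TMM factor computation following the published recipe
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
    lib <- colSums(counts)
    f75 <- sapply(seq_len(ncol(counts)), function(j)
        quantile(counts[, j], 0.75) / lib[j])
    ref <- which.min(abs(f75 - mean(f75)))
    fac <- sapply(seq_len(ncol(counts)), function(k) {
        y <- counts[, k]; r <- counts[, ref]
        keep <- y > 0 & r > 0
        y <- y[keep]; r <- r[keep]
        M <- log2((y / lib[k]) / (r / lib[ref]))
        A <- 0.5 * log2((y / lib[k]) * (r / lib[ref]))
        v <- (lib[k] - y) / (lib[k] * y) + (lib[ref] - r) / (lib[ref] * r)
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        keepM <- rank(M) >= floor(n * trim_m) + 1 &
            rank(M) <= n - floor(n * trim_m)
        keepA <- rank(A) >= floor(n * trim_a) + 1 &
            rank(A) <= n - floor(n * trim_a)
        sel <- keepM & keepA
        if (!any(sel)) return(1)
        2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
    })
    fac <- fac / exp(mean(log(fac)))
    names(fac) <- colnames(counts)
    fac
}

# NB exact split-probability p by naive enumeration of every split of T
oracle_nb_p <- function(s1, s2, n1, n2, phi) {
    T <- s1 + s2
    if (T == 0) return(1)
    m <- T / (n1 + n2)
    pr <- sapply(0:T, function(s) {
        if (phi == 0) {
            dbinom(s, T, n1 / (n1 + n2))
        } else {
            dnbinom(s, size = n1 / phi, mu = n1 * m) *
                dnbinom(T - s, size = n2 / phi, mu = n2 * m)
        }
    })
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[s1 + 1] * (1 + 1e-12)])
}

# naive double-loop groupby sum
oracle_collapse <- function(counts, gene_id) {
    genes <- sort(unique(gene_id))
    out <- matrix(0, length(genes), ncol(counts),
                  dimnames = list(genes, colnames(counts)))
    for (i in seq_len(nrow(counts)))
        for (j in seq_len(ncol(counts)))
            out[gene_id[i], j] <- out[gene_id[i], j] + counts[i, j]
    out
}
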