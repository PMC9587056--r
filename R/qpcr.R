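#' Geometric-mean housekeeping normalization of qPCR Ct data
#'
#' Per sample s and gene g, the quantity implied by the quantification cycle
#' is \code{Q[g, s] = E_g^(-Ct[g, s])}. The per-sample normalization factor
#' is the geometric mean of the housekeeping quantities,
#' \code{NF[s] = geomean_h Q[h, s]}; relative quantities are
#' \code{RQ[g, s] = Q[g, s] / NF[s]}, and the fold change per treatment is
#' the ratio of geometric means,
#' \code{FC[g, t] = geomean_{s in t} RQ[g, s] / geomean_{s in control}
#' RQ[g, s]} (arithmetic replicate pooling available via
#' \code{replicate_mean = "arithmetic"}). With a single housekeeping gene
#' and E = 2 this reduces to the classic 2^-ddCt method. Technical-replicate
#' Ct rows (duplicated sample x gene) are averaged arithmetically on the Ct
#' scale first.
#'
#' @param ct data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{role} (\code{target}/\code{hk}), \code{ct} and optionally
#'   \code{efficiency} (per gene; default 2).
#' @param design data.frame with \code{sample_id}, \code{treatment}.
#' @param control control group label.
#' @param hk_genes housekeeping gene ids; default: genes with role
#'   \code{"hk"}.
#' @param efficiency fallback amplification efficiency for genes without an
#'   \code{efficiency} column, in (1, 2].
#' @param replicate_mean \code{"geometric"} (default) or
#'   \code{"arithmetic"} pooling of RQ across biological replicates.
#' @return list: \code{rq} (per sample x gene relative quantities, long
#'   data.frame) and \code{fc} (data.frame \code{gene_id},
#'   \code{treatment}, \code{fold_change}; control column equals 1).
#' @examples
#' cfg <- simulationConfig(n_genes = 60, seed = 5)
#' d <- generateDesign(cfg)
#' sim <- generateCounts(d, cfg)
#' ct <- generateQpcr(d, sim$truth, config = cfg)
#' head(relativeExpression(ct, d)$fc)
#' @export
relativeExpression <- function(ct, design, control = "control",
                               hk_genes = NULL, efficiency = 2,
                               replicate_mean = c("geometric",
                                                  "arithmetic")) {
    replicate_mean <- match.arg(replicate_mean)
    need <- c("sample_id", "gene_id", "ct")
    if (!all(need %in% colnames(ct)))
        stop("'ct' needs columns ", paste(need, collapse = ", "))
    if (any(ct$ct <= 0)) stop("Ct values must be > 0")
    if (is.null(hk_genes)) {
        if (!"role" %in% colnames(ct))
            stop("supply 'hk_genes' or a 'role' column")
        hk_genes <- unique(ct$gene_id[ct$role == "hk"])
    }
    if (length(hk_genes) == 0L)
        stop("at least one housekeeping gene is required")
    if (!"efficiency" %in% colnames(ct)) ct$efficiency <- efficiency
    if (any(ct$efficiency <= 1 | ct$efficiency > 2))
        stop("amplification efficiency must be in (1, 2]")
    ## average technical replicates on the Ct scale
    agg <- stats::aggregate(ct["ct"],
                            by = ct[c("sample_id", "gene_id", "efficiency")],
                            FUN = mean)
    tr <- as.character(design$treatment)[match(agg$sample_id,
                                               design$sample_id)]
    if (any(is.na(tr)))
        stop("samples missing from design: ",
             paste(unique(agg$sample_id[is.na(tr)]), collapse = ", "))
    if (!control %in% tr) stop("no control samples present")
    samples <- unique(agg$sample_id)
    for (s in samples) {
        have <- agg$gene_id[agg$sample_id == s]
        miss <- setdiff(hk_genes, have)
        if (length(miss))
            stop("sample ", s, " lacks housekeeping measurement(s): ",
                 paste(miss, collapse = ", "))
    }
    agg$log_q <- -agg$ct * log(agg$efficiency)  # log quantity
    ## per-sample normalization factor: geometric mean over HK genes
    hk_rows <- agg$gene_id %in% hk_genes
    log_nf <- tapply(agg$log_q[hk_rows], agg$sample_id[hk_rows], mean)
    agg$log_rq <- agg$log_q - as.numeric(log_nf[agg$sample_id])
    agg$rq <- exp(agg$log_rq)
    agg$treatment <- tr
    pool <- function(v) if (replicate_mean == "geometric")
        mean(v) else log(mean(exp(v)))
    fc <- do.call(rbind, lapply(unique(agg$gene_id), function(g) {
        sub <- agg[agg$gene_id == g, ]
        lc <- pool(sub$log_rq[sub$treatment == control])
        data.frame(
            gene_id = g,
            treatment = unique(tr),
            fold_change = vapply(unique(tr), function(t)
                exp(pool(sub$log_rq[sub$treatment == t]) - lc), numeric(1)),
            stringsAsFactors = FALSE)
    }))
    rownames(fc) <- NULL
    list(rq = agg[, c("sample_id", "gene_id", "treatment", "rq")],
         fc = fc)
}
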