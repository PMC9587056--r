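#' Concordance between the nonparametric and NB approaches
#'
#' Per gene x treated-versus-control pair, the two approaches agree when
#' both call a significant effect in the same direction, or both call NS.
#' The nonparametric call uses its native rule (pairwise p <= alpha;
#' tendencies count as NS unless \code{tendency_as_sig}); the NB call uses
#' its own rule (p <= p_max AND fold-change bound, i.e. the \code{call}
#' column).
#'
#' @param np_pairs \code{pairs} table from [nonparametricDE()].
#' @param nb_results \code{results} table from [nbDE()].
#' @param alpha nonparametric significance threshold (default 0.05).
#' @param tendency_as_sig count tendencies (p in (alpha, 0.10]) as
#'   significant calls (default FALSE).
#' @param direction_matters require matching direction for an agreement on
#'   significance (default TRUE).
#' @return list: \code{cells} (gene x pair agreement table),
#'   \code{overall_percent}, \code{pair_percent} (per comparison),
#'   \code{histogram} (genes by number of agreeing pairs out of k),
#'   \code{n_genes}.
#' @export
compareCalls <- function(np_pairs, nb_results, alpha = 0.05,
                         tendency_as_sig = FALSE, direction_matters = TRUE) {
    genes <- intersect(unique(np_pairs$gene_id), unique(nb_results$gene_id))
    if (length(genes) == 0L)
        stop("the two result sets share no genes")
    pairs <- intersect(unique(np_pairs$treatment), unique(nb_results$pair))
    if (length(pairs) == 0L) stop("no shared comparison pairs")
    np <- np_pairs[np_pairs$gene_id %in% genes &
                   np_pairs$treatment %in% pairs, ]
    nb <- nb_results[nb_results$gene_id %in% genes &
                     nb_results$pair %in% pairs, ]
    key_np <- paste(np$gene_id, np$treatment)
    key_nb <- paste(nb$gene_id, nb$pair)
    grid <- expand.grid(gene_id = genes, pair = pairs,
                        stringsAsFactors = FALSE)
    gk <- paste(grid$gene_id, grid$pair)
    i_np <- match(gk, key_np); i_nb <- match(gk, key_nb)

    np_sig <- np$p[i_np] <= (if (tendency_as_sig) 0.10 else alpha)
    np_dir <- ifelse(np$R[i_np] > 1, "up", "down")
    nb_call <- nb$call[i_nb]
    nb_sig <- nb_call != "none"

    agree <- ifelse(
        !np_sig & !nb_sig, "agree_ns",
        ifelse(np_sig & nb_sig &
               (!direction_matters | np_dir == nb_call),
               "agree_sig_same_dir", "disagree"))
    agree[is.na(agree)] <- "disagree"
    grid$np_sig <- np_sig
    grid$np_direction <- np_dir
    grid$nb_call <- nb_call
    grid$agreement <- agree

    ok <- agree != "disagree"
    pair_pct <- vapply(pairs, function(p)
        100 * mean(ok[grid$pair == p]), numeric(1))
    per_gene <- tapply(ok, grid$gene_id, sum)
    hist <- table(factor(per_gene, levels = 0:length(pairs)))
    list(cells = grid,
         overall_percent = 100 * mean(ok),
         pair_percent = pair_pct,
         histogram = as.integer(hist),
         n_genes = length(genes))
}

#' Heatmap-style classification table and down:up summary
#'
#' Emits the gene x treatment category matrix from the nonparametric
#' classification, the counts of up- and down-regulated cells among
#' significant and tendency calls, their ratio, and the count of cells per
#' fold-change magnitude bin.
#'
#' @param np_pairs \code{pairs} table from [nonparametricDE()].
#' @return list: \code{matrix} (gene x treatment category codes),
#'   \code{n_up}, \code{n_down}, \code{down_up_ratio} (NA when no up
#'   cells), \code{magnitude_counts}.
#' @export
heatmapTable <- function(np_pairs) {
    genes <- unique(np_pairs$gene_id)
    treatments <- unique(np_pairs$treatment)
    mat <- matrix("NS", length(genes), length(treatments),
                  dimnames = list(genes, treatments))
    mat[cbind(match(np_pairs$gene_id, genes),
              match(np_pairs$treatment, treatments))] <- np_pairs$category
    called <- np_pairs$tier %in% c("significant", "tendency")
    n_up <- sum(called & np_pairs$direction == "up")
    n_down <- sum(called & np_pairs$direction == "down")
    ratio <- if (n_up == 0) NA_real_ else n_down / n_up
    mag <- table(factor(np_pairs$magnitude[called],
                        levels = c("<2-fold", "2-4-fold", ">4-fold")))
    list(matrix = mat, n_up = n_up, n_down = n_down,
         down_up_ratio = ratio,
         magnitude_counts = stats::setNames(as.integer(mag), names(mag)))
}
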