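#' Top fraction of a ranked gene list
#'
#' @param ranked a `ranked_genes` data.frame.
#' @param fraction fraction of the list in (0, 1]; the first
#'   `ceiling(fraction * N)` genes are returned (boundary ties are already
#'   resolved by the recorded lexicographic tie-break of the ranking).
#' @return `ranked_genes` sub-data.frame of the selected genes (use `$gene`
#'   for the bare set).
#' @export
select_top_fraction <- function(ranked, fraction) {
  stopifnot(inherits(ranked, "ranked_genes"))
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * nrow(ranked))
  out <- ranked[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map drug-target data onto a top gene set
#'
#' For each drug, intersects its targets with the selected top genes and
#' reports the hit count and the best (smallest) rank among the hits. Drugs
#' whose targets are entirely absent from the top set get 0 hits and are
#' flagged unmappable.
#'
#' @param top a `ranked_genes` subset (from [select_top_fraction()]) or a
#'   character vector of genes (ranks then unavailable).
#' @param table data.frame with columns drug, gene (one row per drug-target
#'   pair; duplicates collapse).
#' @return data.frame: `drug`, `n_targets`, `n_hits`, `best_rank`,
#'   `hit_genes` (comma-joined), `mappable`; sorted by hits (desc) then best
#'   rank.
#' @export
map_drug_targets <- function(top, table) {
  if (!is.data.frame(table) || ncol(table) < 2L)
    stop("drug-target table must have >= 2 columns")
  tab <- unique(stats::setNames(table[1:2], c("drug", "gene")))
  tab$drug <- as.character(tab$drug); tab$gene <- as.character(tab$gene)
  if (any(!nzchar(tab$gene))) stop("empty target gene in drug-target table")
  if (inherits(top, "data.frame")) {
    top_genes <- top$gene
    ranks <- stats::setNames(top$rank, top$gene)
  } else {
    top_genes <- as.character(top)
    ranks <- stats::setNames(seq_along(top_genes), top_genes)
  }
  if (!length(top_genes) || !nrow(tab)) stop("empty input")
  rows <- lapply(split(tab$gene, tab$drug), function(tg) {
    hits <- intersect(tg, top_genes)
    data.frame(n_targets = length(tg), n_hits = length(hits),
               best_rank = if (length(hits)) min(ranks[hits]) else NA_real_,
               hit_genes = paste(sort(hits), collapse = ","),
               mappable = length(hits) > 0L)
  })
  out <- cbind(drug = names(rows), do.call(rbind, rows))
  out <- out[order(-out$n_hits, out$best_rank, out$drug), ]
  rownames(out) <- NULL
  out
}

#' Prioritize synergistic targets from expression response
#'
#' Intersects three filters: genes significantly changed in the treated /
#' fusion-positive comparison (fold change above `fc_threshold`, p below
#' `p_threshold`) that also sit in the top fraction of the
#' fusion-association ranking. These are candidates whose inhibition may
#' synergize with targeting the fusion itself.
#'
#' @param ranked `ranked_genes` (association ranking).
#' @param de_table data.frame with columns `gene`, `fold_change` (linear
#'   scale, > 1 means up), `p`.
#' @param fc_threshold fold-change cut, default 1.5 (exclusive).
#' @param p_threshold p-value cut, default 0.05 (exclusive).
#' @param top_fraction rank-percentage cut, default 0.10.
#' @return character vector of prioritized genes (sorted by association
#'   rank); attribute `missing` lists ranked genes absent from `de_table`.
#' @export
prioritize_synergistic_targets <- function(ranked, de_table,
                                           fc_threshold = 1.5,
                                           p_threshold = 0.05,
                                           top_fraction = 0.10) {
  stopifnot(inherits(ranked, "ranked_genes"))
  need <- c("gene", "fold_change", "p")
  if (!all(need %in% names(de_table)))
    stop("de_table must have columns gene, fold_change, p")
  top <- select_top_fraction(ranked, top_fraction)
  missing <- setdiff(top$gene, de_table$gene)
  de <- de_table[de_table$gene %in% top$gene, ]
  keep <- de$gene[de$fold_change > fc_threshold & de$p < p_threshold]
  out <- top$gene[top$gene %in% keep]
  attr(out, "missing") <- missing
  out
}

#' ROC curve and AUC of a gene ranking against a benchmark set
#'
#' Benchmark genes present in the ranking are positives, every other ranked
#' gene is a negative. The score threshold is swept over the ranking; tied
#' scores are handled by rank averaging, so the AUC equals the normalized
#' Mann-Whitney U statistic.
#'
#' @param ranked `ranked_genes` (or a `score_vector`).
#' @param positives character vector of benchmark genes.
#' @param exclude genes removed from the evaluation universe first (e.g. the
#'   fusion's parental genes, which trivially rank high).
#' @return list with `auc`, `points` (data.frame fpr, tpr along the sweep),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(ranked, positives, exclude = character()) {
  if (inherits(ranked, "score_vector")) ranked <- rank_genes(ranked)
  stopifnot(inherits(ranked, "ranked_genes"))
  keep <- !(ranked$gene %in% exclude)
  genes <- ranked$gene[keep]; score <- ranked$score[keep]
  lab <- genes %in% positives
  nP <- sum(lab); nN <- sum(!lab)
  if (nP == 0L) stop("no positive gene in the evaluation universe")
  if (nN == 0L) stop("no negative gene in the evaluation universe")
  r <- rank(score)                         # ties averaged
  auc <- (sum(r[lab]) - nP * (nP + 1) / 2) / (nP * nN)
  # sweep thresholds over distinct score values, descending
  ord <- order(-score)
  lab_o <- lab[ord]; sc_o <- score[ord]
  grp_end <- which(!duplicated(sc_o, fromLast = TRUE))  # last index per tie group
  tp <- cumsum(lab_o); fp <- cumsum(!lab_o)
  pts <- data.frame(fpr = c(0, fp[grp_end] / nN), tpr = c(0, tp[grp_end] / nP))
  list(auc = auc, points = pts, n_pos = nP, n_neg = nN)
}
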