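#' Rank genes by score
#'
#' Orders genes by descending score; ties are broken lexicographically by
#' gene identifier and flagged, so the ordering is a deterministic function
#' of the score set alone (input order never matters).
#'
#' @param scores a `score_vector` from [random_walk_restart()] or a named
#'   numeric vector.
#' @return data.frame of class `ranked_genes` with columns `gene`, `score`,
#'   `rank`, `tied` (TRUE when the score is shared with another gene).
#' @export
rank_genes <- function(scores) {
  if (inherits(scores, "score_vector")) scores <- scores$scores
  if (!is.numeric(scores) || is.null(names(scores)) || !length(scores))
    stop("scores must be a non-empty named numeric vector")
  if (anyDuplicated(names(scores))) stop("duplicate gene identifiers")
  ord <- order(-scores, names(scores), method = "radix")
  s <- scores[ord]
  out <- data.frame(gene = names(s), score = as.numeric(s),
                    rank = seq_along(s),
                    tied = duplicated(as.numeric(s)) |
                           duplicated(as.numeric(s), fromLast = TRUE))
  rownames(out) <- NULL
  class(out) <- c("ranked_genes", "data.frame")
  out
}

# Running-sum enrichment from sorted hit positions; O(k) per call.
# Returns the signed maximum deviation (positive wins exact ties).
.es_from_positions <- function(pos, incr, N) {
  k <- length(pos)
  miss <- 1 / (N - k)
  tot <- sum(incr)
  if (tot <= 0) incr <- rep(1 / k, k) else incr <- incr / tot
  cum <- cumsum(incr)
  j <- seq_len(k)
  after <- cum - (pos - j) * miss                 # value just after each hit
  before <- c(0, cum[-k]) - (pos - j) * miss      # value just before each hit
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' GSEA running-sum enrichment score
#'
#' Walks down the ranked list accumulating a running sum: members of the
#' gene set ("hits") add `|score|^weight` (normalized so all hits sum to 1),
#' non-members subtract `1/(N - N_hits)`. The enrichment score is the signed
#' maximum deviation of this sum from zero: near +1 when the set crowds the
#' top of the list, near -1 when it crowds the bottom.
#'
#' @param ranked a [rank_genes()] result.
#' @param gene_set character vector; must intersect the ranked genes and be
#'   a proper subset of them.
#' @param weight exponent on |score| for hit increments; 0 gives the
#'   unweighted (Kolmogorov-Smirnov-like) statistic, 1 (default) the
#'   standard weighted statistic.
#' @return numeric ES in [-1, 1], with attributes `running` (the full
#'   running-sum profile), `hits` (logical over the ranked list) and
#'   `leading_edge` (set members up to / from the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_genes"))
  N <- nrow(ranked)
  hits <- ranked$gene %in% gene_set
  k <- sum(hits)
  if (k == 0L) stop("gene set does not intersect the ranked list")
  if (k == N) stop("invalid input: gene set covers the entire ranked list")
  incr <- numeric(N)
  w <- abs(ranked$score[hits])^weight
  if (sum(w) <= 0) w <- rep(1, k)
  incr[hits] <- w / sum(w)
  incr[!hits] <- -1 / (N - k)
  running <- cumsum(incr)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  le <- if (es >= 0) ranked$gene[hits & seq_len(N) <= i_ext]
        else ranked$gene[hits & seq_len(N) >= i_ext]
  structure(es, running = running, hits = hits, leading_edge = le)
}

#' Permutation p-value for an enrichment score
#'
#' Null distribution built by drawing random gene sets of the same size from
#' the ranked list (gene-set permutation; there are no phenotype labels to
#' permute in an association ranking). The p-value is conditional on the
#' sign of the observed ES:
#' `(1 + #{null ES same sign, at least as extreme}) / (1 + #{null ES same sign})`,
#' which is calibrated (uniform under the null) within each enrichment
#' direction.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed for reproducibility.
#' @return list with `p`, `es`, `n_perm`.
#' @export
gsea_pvalue <- function(ranked, gene_set, weight = 1, n_perm = 10000L,
                        seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  es <- as.numeric(enrichment_score(ranked, gene_set, weight))
  N <- nrow(ranked)
  k <- sum(ranked$gene %in% gene_set)
  absw <- abs(ranked$score)^weight
  nulls <- vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(N, k))
    .es_from_positions(pos, absw[pos], N)
  }, numeric(1))
  list(p = .perm_pvalue(es, nulls), es = es, n_perm = n_perm)
}

# conditional same-sign permutation p-value
.perm_pvalue <- function(es, nulls) {
  if (es >= 0) (1 + sum(nulls >= es)) / (1 + sum(nulls >= 0))
  else (1 + sum(nulls <= es)) / (1 + sum(nulls < 0))
}

# shared GSEA driver for association and deregulation analyses;
# null ES distributions are cached per set size (the ranked list is fixed).
.gsea_collection <- function(ranked, collection, weight = 1,
                             n_perm = 10000L, min_size = 10L,
                             max_size = 500L, seed = NULL) {
  stopifnot(inherits(ranked, "ranked_genes"),
            inherits(collection, "pathway_collection"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(ranked)
  absw <- abs(ranked$score)^weight
  genes <- ranked$gene
  skipped <- list(); rows <- list()
  restricted <- lapply(collection, function(g) intersect(g, genes))
  sizes <- lengths(restricted)
  null_cache <- new.env(parent = emptyenv())
  null_for_size <- function(k) {
    key <- as.character(k)
    if (!is.null(null_cache[[key]])) return(null_cache[[key]])
    v <- vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, k))
      .es_from_positions(pos, absw[pos], N)
    }, numeric(1))
    null_cache[[key]] <- v
    v
  }
  for (nm in names(collection)) {
    k <- sizes[[nm]]
    if (k == 0L) { skipped[[nm]] <- "no overlap with ranked list"; next }
    if (k < min_size) { skipped[[nm]] <- "below min_size"; next }
    if (k > max_size || k >= N) { skipped[[nm]] <- "above max_size"; next }
    esx <- enrichment_score(ranked, restricted[[nm]], weight)
    es <- as.numeric(esx)
    nulls <- null_for_size(k)
    p <- .perm_pvalue(es, nulls)
    same_sign <- if (es >= 0) nulls[nulls > 0] else -nulls[nulls < 0]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    rows[[nm]] <- data.frame(
      pathway = nm, size = k, es = es, nes = nes, p = p,
      leading_edge = paste(attr(esx, "leading_edge"), collapse = ","))
  }
  if (!length(rows)) stop("all pathways were filtered out")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, -abs(out$es), out$pathway),
             c("pathway", "size", "es", "nes", "p", "q", "leading_edge")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "skipped") <- if (length(skipped))
    data.frame(pathway = names(skipped), reason = unlist(skipped),
               row.names = NULL)
    else data.frame(pathway = character(), reason = character())
  attr(out, "collection_source") <- attr(collection, "source")
  out
}

#' Pathway association analysis over a score ranking
#'
#' Ranks all genes by their fusion-association scores and tests every
#' pathway for concentration at the top (or bottom) of the ranking, with
#' gene-set permutation p-values and Benjamini-Hochberg q-values. Pathways
#' are restricted to genes present in the ranking before size filtering.
#'
#' @param scores a `score_vector` or named numeric vector.
#' @param collection a [pathway_collection()].
#' @param weight hit-increment exponent, default 1.
#' @param n_perm permutations per set size, default 10000.
#' @param min_size,max_size in-ranking set-size bounds (default 10-500).
#' @param seed optional integer seed.
#' @return data.frame of class `enrichment_table` with columns `pathway`,
#'   `size`, `es`, `nes`, `p`, `q`, `leading_edge`, sorted by p then |ES|;
#'   attribute `skipped` lists filtered pathways with reasons.
#' @export
association_analysis <- function(scores, collection, weight = 1,
                                 n_perm = 10000L, min_size = 10L,
                                 max_size = 500L, seed = NULL) {
  .gsea_collection(rank_genes(scores), collection, weight = weight,
                   n_perm = n_perm, min_size = min_size,
                   max_size = max_size, seed = seed)
}
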