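#' Named pathway collection
#'
#' @param sets named list of character vectors (gene sets). Names must be
#'   unique and every set non-empty.
#' @param descriptions optional character vector parallel to `sets`.
#' @param source optional label for the collection origin (e.g. a GMT file
#'   or MSigDB category).
#' @return list of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, descriptions = NULL, source = NA_character_) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway name: ",
         names(sets)[duplicated(names(sets))][1])
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty pathway set not allowed")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            source = source, class = c("pathway_collection", "list"))
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("<pathway_collection> ", length(x), " sets, sizes ",
      min(lengths(x)), "-", max(lengths(x)), "\n", sep = "")
  invisible(x)
}

#' Two-group expression dataset
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns.
#' @param groups character/factor of length `ncol(values)` with exactly two
#'   levels and at least two samples per level. The first level (factor
#'   order, or order of appearance) is the reference; positive effects mean
#'   higher expression in the second ("case") level.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, groups) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("expression matrix needs unique gene rownames")
  if (length(groups) != ncol(values))
    stop("groups length must equal the number of samples")
  groups <- if (is.factor(groups)) droplevels(groups) else
            factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) != 2L)
    stop("exactly two sample groups are required")
  if (any(table(groups) < 2L))
    stop("at least two samples per group are required")
  structure(list(values = values, groups = groups),
            class = "expression_dataset")
}

#' Differential-expression ranking
#'
#' Per-gene Welch two-sample t-test (case vs reference level of the group
#' factor), assuming the values are already on a log-like scale. Genes are
#' ranked by signed `-log10(p)` — the sign of the case-minus-reference mean
#' difference — so up-regulated significant genes head the list and
#' down-regulated significant genes tail it. Genes with zero variance in
#' both groups and no mean difference get p = 1 and effect 0 (flagged).
#'
#' @param data an [expression_dataset()].
#' @return `ranked_genes` data.frame (gene, score, rank, tied) with
#'   attribute `stats`: per-gene data.frame (gene, mean_diff, t, df, p,
#'   flat), where `flat` marks degenerate zero-variance genes.
#' @export
differential_ranking <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  g <- data$groups
  ref <- data$values[, g == levels(g)[1], drop = FALSE]
  case <- data$values[, g == levels(g)[2], drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ref)
  m1 <- rowMeans(case); m2 <- rowMeans(ref)
  v1 <- apply(case, 1, stats::var); v2 <- apply(ref, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  d <- m1 - m2
  tt <- ifelse(se2 > 0, d / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df),
              ifelse(d == 0, 1, 0))
  flat <- se2 == 0 & d == 0
  p <- pmax(p, 1e-320)
  key <- sign(ifelse(flat, 0, d)) * -log10(p)
  names(key) <- rownames(data$values)
  ranked <- rank_genes(key)
  attr(ranked, "stats") <- data.frame(
    gene = rownames(data$values), mean_diff = d, t = tt, df = df, p = p,
    flat = flat, row.names = NULL)
  ranked
}

#' Pathway deregulation analysis from expression data
#'
#' Same rank-based enrichment as [association_analysis()], but over the
#' signed differential-expression ranking, so a significant pathway is one
#' whose members move coherently (up or down; the reported ES sign gives the
#' direction) between fusion-positive/treated and control samples.
#'
#' @param data an [expression_dataset()].
#' @inheritParams association_analysis
#' @return `enrichment_table` (see [association_analysis()]).
#' @export
deregulation_analysis <- function(data, collection, weight = 1,
                                  n_perm = 10000L, min_size = 10L,
                                  max_size = 500L, seed = NULL) {
  .gsea_collection(differential_ranking(data), collection, weight = weight,
                   n_perm = n_perm, min_size = min_size,
                   max_size = max_size, seed = seed)
}

#' Truncated product score of two p-values
#'
#' Product of the p-values not exceeding the truncation point `tau`; the
#' empty product (both p above tau) is 1.
#'
#' @param p1,p2 p-values in (0, 1] (vectorized, recycled elementwise).
#' @param tau truncation threshold in (0, 1); default 0.01.
#' @return numeric W in (0, 1].
#' @export
truncated_product_W <- function(p1, p2, tau = 0.01) {
  if (!(tau > 0 && tau < 1)) stop("tau must be in (0, 1)")
  if (any(p1 <= 0 | p1 > 1, na.rm = TRUE) ||
      any(p2 <= 0 | p2 > 1, na.rm = TRUE) || anyNA(c(p1, p2)))
    stop("invalid input: p-values must be in (0, 1]")
  ifelse(p1 <= tau, p1, 1) * ifelse(p2 <= tau, p2, 1)
}

#' Null tail probability of the truncated product score
#'
#' Closed-form `Pr(W <= w)` for two independent uniform p-values, obtained
#' by conditioning on the number k of p-values below tau:
#' `sum_{k=1}^{2} C(2,k) (1-tau)^{2-k} [ w sum_{s=0}^{k-1} (k ln tau - ln w)^s / s! * I(w <= tau^k) + tau^k * I(w > tau^k) ]`.
#' W = 1 (no p-value below tau) maps to p = 1 by convention. The inner terms
#' are evaluated in log space.
#'
#' @param W truncated product score(s) in (0, 1].
#' @param tau truncation threshold in (0, 1).
#' @return combined p-value(s) in (0, 1].
#' @export
truncated_product_pvalue <- function(W, tau = 0.01) {
  if (!(tau > 0 && tau < 1)) stop("tau must be in (0, 1)")
  if (any(W <= 0 | W > 1, na.rm = TRUE) || anyNA(W))
    stop("invalid input: W must be in (0, 1]")
  lw <- log(W)
  # k = 1: exactly one p <= tau, that p <= w
  t1 <- 2 * (1 - tau) * ifelse(W <= tau, W, tau)
  # k = 2: both p <= tau, product <= w
  a <- 2 * log(tau) - lw                       # >= 0 iff w <= tau^2
  t2 <- ifelse(W <= tau^2, exp(lw + log1p(pmax(a, 0))), tau^2)
  p <- t1 + t2
  ifelse(W >= 1, 1, pmin(p, 1))
}

#' Combine pathway association and deregulation p-values
#'
#' Joins the two enrichment tables on pathway name and, per pathway, forms
#' the truncated product score W of the association and deregulation
#' p-values and its combined p-value. Both tables must come from the same
#' pathway collection; pathways surviving the size filter in only one
#' analysis are excluded from the combination and reported.
#'
#' @param assoc,dereg `enrichment_table`s from [association_analysis()] and
#'   [deregulation_analysis()].
#' @param tau truncation threshold for both p-values; default 0.01.
#' @return data.frame of class `combined_pathways` with columns `pathway`,
#'   `p_association`, `p_deregulation`, `W`, `p_combined`, `q_combined`,
#'   sorted ascending by `p_combined`; attribute `unmatched` lists the
#'   excluded pathways.
#' @export
combine_pathway_results <- function(assoc, dereg, tau = 0.01) {
  stopifnot(inherits(assoc, "enrichment_table"),
            inherits(dereg, "enrichment_table"))
  src_a <- attr(assoc, "collection_source")
  src_d <- attr(dereg, "collection_source")
  if (!is.null(src_a) && !is.null(src_d) &&
      !is.na(src_a) && !is.na(src_d) && !identical(src_a, src_d))
    stop("association and deregulation results come from different ",
         "pathway collections ('", src_a, "' vs '", src_d, "')")
  common <- intersect(assoc$pathway, dereg$pathway)
  if (!length(common)) stop("no pathway shared between the two tables")
  only <- c(setdiff(assoc$pathway, common), setdiff(dereg$pathway, common))
  pa <- assoc$p[match(common, assoc$pathway)]
  pd <- dereg$p[match(common, dereg$pathway)]
  W <- truncated_product_W(pa, pd, tau)
  pc <- truncated_product_pvalue(W, tau)
  out <- data.frame(pathway = common, p_association = pa,
                    p_deregulation = pd, W = W, p_combined = pc)
  out$q_combined <- stats::p.adjust(out$p_combined, method = "BH")
  out <- out[order(out$p_combined, out$W, out$pathway), ]
  rownames(out) <- NULL
  class(out) <- c("combined_pathways", "data.frame")
  attr(out, "tau") <- tau
  attr(out, "unmatched") <- only
  out
}
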