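#' Bundle of interaction evidence
#'
#' Collects the evidence used to decide which parental molecular interactions
#' a fusion inherits: a protein-protein interaction (PPI) edge list, a
#' catalog of domain-domain interactions (DDI), transcription-factor target
#' edges, the gene-domain annotation table, and the set of domain accessions
#' regarded as DNA-binding.
#'
#' @param ppi data.frame with two gene columns (undirected pairs).
#' @param ddi data.frame with two domain-accession columns (unordered pairs;
#'   orientation in the file does not matter).
#' @param tf_targets data.frame with columns (regulator, target); may be
#'   empty.
#' @param annotations a [domain_annotation()] table.
#' @param dna_binding_domains character vector of accessions treated as
#'   DNA-binding; may be empty.
#' @return object of class `interaction_bundle`.
#' @export
interaction_bundle <- function(ppi, ddi, tf_targets = NULL, annotations,
                               dna_binding_domains = character()) {
  chk2 <- function(df, what) {
    if (is.null(df)) return(data.frame(a = character(), b = character()))
    if (!is.data.frame(df) || ncol(df) < 2L)
      stop(what, " must be a data.frame with >= 2 columns")
    out <- stats::setNames(df[1:2], c("a", "b"))
    out$a <- as.character(out$a); out$b <- as.character(out$b)
    if (any(!nzchar(out$a)) || any(!nzchar(out$b)) ||
        anyNA(out$a) || anyNA(out$b))
      stop(what, " contains empty or missing identifiers")
    rownames(out) <- NULL
    out
  }
  structure(
    list(ppi = chk2(ppi, "ppi"), ddi = chk2(ddi, "ddi"),
         tf_targets = chk2(tf_targets, "tf_targets"),
         annotations = domain_annotation(annotations),
         dna_binding_domains = unique(as.character(dna_binding_domains))),
    class = "interaction_bundle")
}

# undirected neighbor lookup in a two-column edge frame
.ppi_neighbors <- function(ppi, gene) {
  unique(c(ppi$b[ppi$a == gene], ppi$a[ppi$b == gene]))
}

# TRUE if any pair (x in d1) x (y in d2) is in the DDI catalog, either way
.ddi_pairs <- function(ddi, dom_f, dom_x) {
  if (!length(dom_f) || !length(dom_x) || !nrow(ddi))
    return(data.frame(fusion_domain = character(),
                      partner_domain = character()))
  fwd <- ddi$a %in% dom_f & ddi$b %in% dom_x
  rev <- ddi$b %in% dom_f & ddi$a %in% dom_x
  out <- rbind(
    data.frame(fusion_domain = ddi$a[fwd], partner_domain = ddi$b[fwd]),
    data.frame(fusion_domain = ddi$b[rev], partner_domain = ddi$a[rev]))
  unique(out)
}

#' Predict the fusion's retained protein-protein interaction partners
#'
#' Candidate partners are the PPI neighbors of either parental gene. A
#' candidate is predicted to keep its interaction with the fusion when some
#' domain retained by the fusion and some domain annotated on the candidate
#' form a pair in the DDI catalog; the supporting pairs are reported as
#' evidence. Candidates without any domain annotation cannot satisfy the rule
#' and are dropped (reported in the diagnostics attribute) unless
#' `keep_unannotated` is set.
#'
#' @param fusion a [fusion_spec()].
#' @param bundle an [interaction_bundle()].
#' @param keep_unannotated keep candidates lacking domain annotation
#'   (default `FALSE`).
#' @return data.frame with columns `partner`, `fusion_domain`,
#'   `partner_domain` (one row per supporting DDI pair; for unannotated
#'   partners kept by the flag both domain columns are `NA`). Attribute
#'   `diagnostics` is a data.frame of excluded candidates with reasons.
#' @export
predict_ppi_partners <- function(fusion, bundle, keep_unannotated = FALSE) {
  stopifnot(inherits(fusion, "fusion_spec"),
            inherits(bundle, "interaction_bundle"))
  dom_f <- retained_domains(fusion)
  cand <- character(); diags <- list()
  for (p in c(fusion$parent5, fusion$parent3)) {
    nb <- .ppi_neighbors(bundle$ppi, p)
    if (!length(nb))
      warning("parent gene '", p, "' has no PPI edges; no candidates from it")
    cand <- union(cand, nb)
  }
  cand <- setdiff(cand, c(fusion$parent5, fusion$parent3))
  rows <- list()
  for (x in cand) {
    dom_x <- unique(gene_domains(bundle$annotations, x))
    if (!length(dom_x)) {
      if (keep_unannotated) {
        rows[[x]] <- data.frame(partner = x, fusion_domain = NA_character_,
                                partner_domain = NA_character_)
      } else {
        diags[[x]] <- data.frame(candidate = x, reason = "no_domain_annotation")
      }
      next
    }
    ev <- .ddi_pairs(bundle$ddi, dom_f, dom_x)
    if (nrow(ev)) {
      rows[[x]] <- cbind(partner = x, ev)
    } else {
      diags[[x]] <- data.frame(candidate = x, reason = "no_ddi_support")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(partner = character(), fusion_domain = character(),
                         partner_domain = character())
  rownames(out) <- NULL
  attr(out, "diagnostics") <- if (length(diags)) do.call(rbind, diags)
    else data.frame(candidate = character(), reason = character())
  rownames(attr(out, "diagnostics")) <- NULL
  out
}

#' Predict transcriptional targets inherited by the fusion
#'
#' A fusion that keeps a DNA-binding domain of a parental transcription
#' factor is assumed to still reach that parent's promoters, so it inherits
#' all of that parent's regulatory edges; losing every DNA-binding domain of
#' a parent severs them all.
#'
#' @inheritParams predict_ppi_partners
#' @return data.frame with columns `target`, `parent` (the parent whose
#'   regulatory edges are inherited). Empty result is valid.
#' @export
predict_tf_targets <- function(fusion, bundle) {
  stopifnot(inherits(fusion, "fusion_spec"),
            inherits(bundle, "interaction_bundle"))
  res <- list()
  for (side in list(list(fusion$parent5, fusion$retained5),
                    list(fusion$parent3, fusion$retained3))) {
    p <- side[[1]]; ret <- side[[2]]
    if (!any(ret %in% bundle$dna_binding_domains)) next
    tg <- unique(bundle$tf_targets$b[bundle$tf_targets$a == p])
    tg <- setdiff(tg, c(fusion$parent5, fusion$parent3))
    if (length(tg))
      res[[p]] <- data.frame(target = tg, parent = p)
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(target = character(), parent = character())
  rownames(out) <- NULL
  out
}

#' Full predicted partner set of a fusion
#'
#' Union of the DDI-supported PPI partners and the inherited transcriptional
#' targets, with merged evidence. These genes seed the network propagation;
#' an empty union is fatal because the walk cannot be started.
#'
#' @inheritParams predict_ppi_partners
#' @param include_parents also place the two parental genes in the seed set
#'   (default `FALSE`).
#' @return object of class `predicted_partners`: list with `genes` (sorted
#'   character vector), `ppi_partners`, `tf_target_genes`, `evidence`
#'   (named list of data.frames per gene) and `diagnostics`.
#' @export
predicted_partner_set <- function(fusion, bundle, keep_unannotated = FALSE,
                                  include_parents = FALSE) {
  ppi <- predict_ppi_partners(fusion, bundle,
                              keep_unannotated = keep_unannotated)
  tft <- predict_tf_targets(fusion, bundle)
  genes <- union(unique(ppi$partner), unique(tft$target))
  if (include_parents)
    genes <- union(genes, c(fusion$parent5, fusion$parent3))
  if (!length(genes))
    stop("no predicted partners: propagation cannot be seeded")
  ev <- lapply(stats::setNames(nm = sort(genes)), function(g) {
    list(ppi = ppi[ppi$partner == g, , drop = FALSE],
         tf = tft[tft$target == g, , drop = FALSE])
  })
  structure(
    list(genes = sort(genes),
         ppi_partners = sort(unique(ppi$partner)),
         tf_target_genes = sort(unique(tft$target)),
         evidence = ev,
         diagnostics = attr(ppi, "diagnostics")),
    class = "predicted_partners")
}

#' @export
print.predicted_partners <- function(x, ...) {
  cat("<predicted_partners> ", length(x$genes), " genes (",
      length(x$ppi_partners), " PPI, ", length(x$tf_target_genes),
      " TF targets)\n", sep = "")
  invisible(x)
}
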