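#' Domain annotation table
#'
#' Validates and normalizes a gene-to-domain annotation table. One row per
#' domain instance, so tandem repeats of the same accession on one gene are
#' representable (repeats are kept; presence/absence is what the interaction
#' inference uses downstream).
#'
#' @param x data.frame with columns `gene` and `domain` (character), or any
#'   two-column data.frame taken as (gene, domain).
#' @return data.frame of class `domain_annotation` with columns `gene`,
#'   `domain`.
#' @export
domain_annotation <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 2L)
    stop("domain annotation must be a data.frame with >= 2 columns")
  cols <- if (all(c("gene", "domain") %in% names(x))) x[c("gene", "domain")]
          else stats::setNames(x[1:2], c("gene", "domain"))
  cols$gene <- as.character(cols$gene)
  cols$domain <- as.character(cols$domain)
  if (any(!nzchar(cols$gene)) || any(is.na(cols$gene)))
    stop("empty or missing gene identifier in domain annotation")
  if (any(!nzchar(cols$domain)) || any(is.na(cols$domain)))
    stop("empty or missing domain accession in domain annotation")
  rownames(cols) <- NULL
  class(cols) <- c("domain_annotation", "data.frame")
  cols
}

#' Annotated domains of one gene
#'
#' @param annotations a [domain_annotation()] table.
#' @param gene gene identifier.
#' @return character vector of domain accessions (may repeat; empty if the
#'   gene is unannotated).
#' @export
gene_domains <- function(annotations, gene) {
  annotations$domain[annotations$gene == gene]
}

#' Describe a fusion by its retained parental domains
#'
#' A fusion joins the 5' part of one parental gene to the 3' part of another.
#' Its protein keeps some of each parent's domains and loses the rest; which
#' domains survive is what determines which parental molecular interactions
#' the fusion inherits. The caller states the retained accessions per parent
#' (breakpoints are not modeled; a domain type counts as retained if at least
#' one copy survives) and the lost sets are computed as complements against
#' the annotation table.
#'
#' @param parent5,parent3 identifiers of the 5' and 3' parental genes; must
#'   be distinct and present in `annotations`.
#' @param retained5,retained3 character vectors of retained domain accessions,
#'   subsets of the respective parent's annotated domains.
#' @param annotations a [domain_annotation()] table covering both parents.
#' @return object of class `fusion_spec`: list with `parent5`, `parent3`,
#'   `retained5`, `retained3`, `lost5`, `lost3` (unique accession sets).
#' @examples
#' ann <- domain_annotation(data.frame(
#'   gene = c("A", "A", "B"), domain = c("D1", "D2", "D3")))
#' fusion_spec("A", "B", retained5 = "D1", retained3 = "D3", annotations = ann)
#' @export
fusion_spec <- function(parent5, parent3, retained5, retained3, annotations) {
  stopifnot(is.character(parent5) || is.factor(parent5),
            length(parent5) == 1L, length(parent3) == 1L)
  parent5 <- as.character(parent5); parent3 <- as.character(parent3)
  if (identical(parent5, parent3))
    stop("parental genes must be distinct")
  annotations <- domain_annotation(annotations)
  dom5 <- unique(gene_domains(annotations, parent5))
  dom3 <- unique(gene_domains(annotations, parent3))
  if (length(dom5) == 0L)
    stop("missing annotation: parent gene '", parent5,
         "' has no domain annotation")
  if (length(dom3) == 0L)
    stop("missing annotation: parent gene '", parent3,
         "' has no domain annotation")
  retained5 <- unique(as.character(retained5))
  retained3 <- unique(as.character(retained3))
  bad5 <- setdiff(retained5, dom5)
  bad3 <- setdiff(retained3, dom3)
  if (length(bad5))
    stop("inconsistent input: retained domain(s) not annotated on '",
         parent5, "': ", paste(bad5, collapse = ", "))
  if (length(bad3))
    stop("inconsistent input: retained domain(s) not annotated on '",
         parent3, "': ", paste(bad3, collapse = ", "))
  structure(
    list(parent5 = parent5, parent3 = parent3,
         retained5 = sort(retained5), retained3 = sort(retained3),
         lost5 = sort(setdiff(dom5, retained5)),
         lost3 = sort(setdiff(dom3, retained3))),
    class = "fusion_spec")
}

#' All domain accessions retained by the fusion
#' @param fusion a [fusion_spec()].
#' @return character vector (union of both parents' retained sets).
#' @export
retained_domains <- function(fusion) {
  stopifnot(inherits(fusion, "fusion_spec"))
  sort(unique(c(fusion$retained5, fusion$retained3)))
}

#' @export
print.fusion_spec <- function(x, ...) {
  cat("<fusion_spec> ", x$parent5, "::", x$parent3, "\n", sep = "")
  cat("  5' retained:", paste(x$retained5, collapse = " "), "\n")
  cat("  5' lost:    ", paste(x$lost5, collapse = " "), "\n")
  cat("  3' retained:", paste(x$retained3, collapse = " "), "\n")
  cat("  3' lost:    ", paste(x$lost3, collapse = " "), "\n")
  invisible(x)
}
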