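# Deterministic synthetic inputs with planted structure. The generator
# stands in for the compiled interaction databases: an Erdos-Renyi
# background with one dense planted module, a two-parent fusion whose
# retained domains have DDI support to designated parental neighbors inside
# the module, a pathway collection whose "planted" set is exactly the module,
# and expression data shifting module genes between groups.

#' Generate a self-consistent synthetic input bundle
#'
#' Produces every input the pipeline consumes, wired so that ground truth is
#' known: the fusion's retained domains license interactions only with
#' designated parental neighbors inside the planted module, the planted
#' pathway equals the module, and the expression data shifts module genes by
#' `effect` standard deviations in the case group. Byte-for-byte
#' reproducible given `seed`.
#'
#' @param n_genes number of background genes (default 500).
#' @param module_size planted module size (default 40).
#' @param p_in edge probability inside the module (default 0.3).
#' @param p_bg background edge probability (default 0.01, mean degree ~5).
#' @param n_decoy_pathways decoy gene sets (default 50).
#' @param decoy_size_range size range for decoys (default 15-60).
#' @param n_per_group expression samples per group (default 6).
#' @param effect case-group shift on module genes in units of `noise_sd`
#'   (default 1.5; 0 plants no signal).
#' @param noise_sd expression noise standard deviation (default 1).
#' @param n_drugs drugs in the toy drug-target table (default 10).
#' @param seed integer RNG seed.
#' @return list of class `synthetic_scenario` with elements `network`,
#'   `ppi`, `ddi`, `tf_targets`, `annotations`, `dna_binding`, `fusion`,
#'   `bundle`, `collection`, `expression`, `drug_targets`, `benchmark`,
#'   `truth` (module genes, supported partners, parents) and `params`.
#' @export
simulate_scenario <- function(n_genes = 500L, module_size = 40L,
                              p_in = 0.3, p_bg = 0.01,
                              n_decoy_pathways = 50L,
                              decoy_size_range = c(15L, 60L),
                              n_per_group = 6L, effect = 1.5,
                              noise_sd = 1, n_drugs = 10L, seed = 1L) {
  if (module_size > n_genes) stop("invalid params: module larger than universe")
  if (module_size < 20L) stop("invalid params: module_size must be >= 20")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  module <- sort(sample(genes, module_size))
  parent5 <- "FUSP5"; parent3 <- "FUSP3"

  # background graph + dense planted block
  pair_idx <- utils::combn(n_genes, 2L)
  in_mod <- genes[pair_idx[1, ]] %in% module & genes[pair_idx[2, ]] %in% module
  p_edge <- ifelse(in_mod, p_in, p_bg)
  keep <- stats::runif(ncol(pair_idx)) < p_edge
  net_edges <- data.frame(a = genes[pair_idx[1, keep]],
                          b = genes[pair_idx[2, keep]])

  # parental PPI edges: some module neighbors (partly DDI-supported below),
  # some background neighbors (never supported)
  nb5_mod <- sort(sample(module, 12L))
  nb5_bg <- sort(sample(setdiff(genes, module), 6L))
  nb3_mod <- sort(sample(setdiff(module, nb5_mod), 6L))
  nb3_bg <- sort(sample(setdiff(genes, c(module, nb5_bg)), 4L))
  ppi <- rbind(net_edges,
               data.frame(a = parent5, b = c(nb5_mod, nb5_bg)),
               data.frame(a = parent3, b = c(nb3_mod, nb3_bg)))

  # domain annotations: generic pool + dedicated supported-partner domains
  pool <- sprintf("PF%05d", seq_len(120L))
  n_dom <- sample(1:3, n_genes, replace = TRUE)
  annotations <- data.frame(
    gene = rep(genes, n_dom),
    domain = sample(pool, sum(n_dom), replace = TRUE))
  supported5 <- sort(sample(nb5_mod, 8L))
  supported3 <- sort(sample(nb3_mod, 4L))
  sup_dom <- stats::setNames(
    sprintf("PFSUP%02d", seq_along(c(supported5, supported3))),
    c(supported5, supported3))
  annotations <- rbind(
    annotations,
    data.frame(gene = names(sup_dom), domain = unname(sup_dom)),
    data.frame(gene = parent5, domain = c("DM5A", "DM5B", "DM5C")),
    data.frame(gene = parent3, domain = c("DM3A", "DM3B")))

  # DDI: retained parental domains bind the supported partners' domains;
  # the lost domain DM5C supports a few module neighbors that the fusion
  # must therefore drop; plus random decoy pairs in the generic pool
  ddi <- rbind(
    data.frame(a = "DM5A", b = unname(sup_dom[supported5])),
    data.frame(a = "DM3B", b = unname(sup_dom[supported3])),
    data.frame(a = "DM5C",
               b = annotations$domain[annotations$gene %in%
                                        setdiff(nb5_mod, supported5)][1:2]),
    data.frame(a = sample(pool, 30L, replace = TRUE),
               b = sample(pool, 30L, replace = TRUE)))

  # parent3 is a transcription factor; DM3A is its DNA-binding domain
  tf_mod <- sort(sample(module, 10L))
  tf_bg <- sort(sample(setdiff(genes, module), 3L))
  tf_targets <- data.frame(a = parent3, b = c(tf_mod, tf_bg))
  dna_binding <- "DM3A"

  annotations <- domain_annotation(annotations)
  fusion <- fusion_spec(parent5, parent3,
                        retained5 = c("DM5A", "DM5B"),
                        retained3 = c("DM3A", "DM3B"),
                        annotations = annotations)
  bundle <- interaction_bundle(ppi = ppi, ddi = ddi, tf_targets = tf_targets,
                               annotations = annotations,
                               dna_binding_domains = dna_binding)
  network <- gene_network(rbind(ppi, tf_targets),
                          nodes = c(genes, parent5, parent3))

  # pathway collection: the planted set is the module, decoys are random
  sizes <- sample(decoy_size_range[1]:decoy_size_range[2],
                  n_decoy_pathways, replace = TRUE)
  decoys <- lapply(sizes, function(k) sort(sample(genes, k)))
  sets <- c(list(planted_module = module),
            stats::setNames(decoys,
                            sprintf("decoy_%02d", seq_len(n_decoy_pathways))))
  collection <- pathway_collection(sets, source = "synthetic")

  # expression: Gaussian log-like values, module genes shifted in cases
  n_smp <- 2L * n_per_group
  vals <- matrix(stats::rnorm(n_genes * n_smp, mean = 7, sd = noise_sd),
                 nrow = n_genes,
                 dimnames = list(genes, c(sprintf("ctrl_%02d",
                                                  seq_len(n_per_group)),
                                          sprintf("case_%02d",
                                                  seq_len(n_per_group)))))
  case_cols <- n_per_group + seq_len(n_per_group)
  vals[module, case_cols] <- vals[module, case_cols] + effect * noise_sd
  groups <- rep(c("control", "case"), each = n_per_group)
  expression <- expression_dataset(vals, groups)

  # toy drug-target table: first drugs hit module genes, the rest are decoys
  drug_targets <- do.call(rbind, lapply(seq_len(n_drugs), function(i) {
    tg <- if (i <= 3L) sample(module, sample(2:4, 1L))
          else sample(setdiff(genes, module), sample(2:4, 1L))
    data.frame(drug = sprintf("drug_%02d", i), gene = sort(tg))
  }))

  structure(
    list(network = network, ppi = ppi, ddi = ddi, tf_targets = tf_targets,
         annotations = annotations, dna_binding = dna_binding,
         fusion = fusion, bundle = bundle, collection = collection,
         expression = expression, drug_targets = drug_targets,
         benchmark = module,
         truth = list(module = module,
                      supported_partners = c(supported5, supported3),
                      tf_targets = tf_mod,
                      parents = c(parent5, parent3)),
         params = list(n_genes = n_genes, module_size = module_size,
                       p_in = p_in, p_bg = p_bg, effect = effect,
                       noise_sd = noise_sd, seed = seed)),
    class = "synthetic_scenario")
}

#' Write a synthetic scenario as a directory of input files
#'
#' Standard file names consumed by the CLI subcommands:
#' `network.tsv`, `ppi.tsv`, `ddi.tsv`, `tf_targets.tsv`, `domains.tsv`,
#' `dna_binding.txt`, `fusion.txt`, `pathways.gmt`, `expression.tsv`,
#' `sample_labels.tsv`, `drug_targets.tsv`, `benchmark.txt`, plus
#' `ground_truth.tsv` describing the planted structure.
#'
#' @param scenario a [simulate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written file paths.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_edge_list(scenario$network$edges, p("network.tsv"))
  write_edge_list(scenario$ppi, p("ppi.tsv"))
  write_edge_list(scenario$ddi, p("ddi.tsv"))
  write_edge_list(scenario$tf_targets, p("tf_targets.tsv"))
  .write_tsv(as.data.frame(scenario$annotations), p("domains.tsv"))
  writeLines(scenario$dna_binding, p("dna_binding.txt"))
  fu <- scenario$fusion
  writeLines(c(paste0("parent5 = ", fu$parent5),
               paste0("parent3 = ", fu$parent3),
               paste0("retained5 = ", paste(fu$retained5, collapse = ",")),
               paste0("retained3 = ", paste(fu$retained3, collapse = ","))),
             p("fusion.txt"))
  write_gmt(scenario$collection, p("pathways.gmt"))
  write_expression(scenario$expression, p("expression.tsv"),
                   p("sample_labels.tsv"))
  .write_tsv(scenario$drug_targets, p("drug_targets.tsv"))
  writeLines(scenario$benchmark, p("benchmark.txt"))
  tr <- scenario$truth
  .write_tsv(data.frame(
    item = c(rep("module_gene", length(tr$module)),
             rep("supported_partner", length(tr$supported_partners)),
             rep("tf_target", length(tr$tf_targets)),
             rep("parent", 2L)),
    gene = c(tr$module, tr$supported_partners, tr$tf_targets, tr$parents)),
    p("ground_truth.tsv"))
  files <- c("network.tsv", "ppi.tsv", "ddi.tsv", "tf_targets.tsv",
             "domains.tsv", "dna_binding.txt", "fusion.txt", "pathways.gmt",
             "expression.tsv", "sample_labels.tsv", "drug_targets.tsv",
             "benchmark.txt", "ground_truth.tsv")
  invisible(file.path(dir, files))
}

#' Miniature worked-example system
#'
#' A hardcoded toy with two parental proteins (three domains each, six in
#' all), eight candidate interactors and a DDI catalog wired so that the
#' default fusion (losing one domain per parent) keeps exactly the
#' "supported" partners: candidates bound through a lost domain, and an
#' unannotated candidate, drop out. Used throughout the unit tests and as a
#' README example.
#'
#' @return list with `annotations`, `bundle`, `fusion` (the default retained
#'   sets), `expected` (list: `blue` = partners of the default fusion,
#'   `white` = candidates it loses), and `all_domains` of the two parents.
#' @export
worked_example_fixture <- function() {
  annotations <- domain_annotation(data.frame(
    gene = c("GENEA", "GENEA", "GENEA", "GENEB", "GENEB", "GENEB",
              "P1", "P2", "P3", "P4", "P5"),
    domain = c("A1", "A2", "A3", "B1", "B2", "B3",
               "X1", "X2", "X3", "X4", "X5")))
  ppi <- data.frame(
    a = c("GENEA", "GENEA", "GENEA", "GENEB", "GENEB", "GENEA"),
    b = c("P1", "P2", "P3", "P4", "P5", "P6"))   # P6 is unannotated
  ddi <- data.frame(
    a = c("A1", "A3", "A2", "B2", "B1"),
    b = c("X1", "X2", "X3", "X4", "X5"))
  tf_targets <- data.frame(a = c("GENEB", "GENEB"), b = c("T1", "T2"))
  bundle <- interaction_bundle(ppi = ppi, ddi = ddi, tf_targets = tf_targets,
                               annotations = annotations,
                               dna_binding_domains = "B3")
  fusion <- fusion_spec("GENEA", "GENEB",
                        retained5 = c("A1", "A2"),
                        retained3 = c("B2", "B3"),
                        annotations = annotations)
  list(annotations = annotations, bundle = bundle, fusion = fusion,
       expected = list(blue = c("P1", "P3", "P4", "T1", "T2"),
                       white = c("P2", "P5", "P6")),
       all_domains = list(GENEA = c("A1", "A2", "A3"),
                          GENEB = c("B1", "B2", "B3")))
}
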