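# DDI-filtered partner prediction on the worked-example toy system

wx <- worked_example_fixture()

test_that("default fusion keeps exactly the supported candidates", {
  pp <- predict_ppi_partners(wx$fusion, wx$bundle)
  expect_setequal(unique(pp$partner), c("P1", "P3", "P4"))
  # evidence records name the supporting domain pair
  p1 <- pp[pp$partner == "P1", ]
  expect_equal(p1$fusion_domain, "A1")
  expect_equal(p1$partner_domain, "X1")
  diag <- attr(pp, "diagnostics")
  expect_setequal(diag$candidate, c("P2", "P5", "P6"))
  expect_equal(diag$reason[diag$candidate == "P6"], "no_domain_annotation")
})

test_that("DDI support is found regardless of catalog orientation", {
  b2 <- wx$bundle
  b2$ddi <- data.frame(a = b2$ddi$b, b = b2$ddi$a)  # swap all pairs
  pp <- predict_ppi_partners(wx$fusion, b2)
  expect_setequal(unique(pp$partner), c("P1", "P3", "P4"))
})

test_that("retaining no domains predicts nothing", {
  fu0 <- fusion_spec("GENEA", "GENEB", character(), character(),
                     wx$annotations)
  expect_equal(nrow(predict_ppi_partners(fu0, wx$bundle)), 0)
  expect_equal(nrow(predict_tf_targets(fu0, wx$bundle)), 0)
})

test_that("toy two-domain example matches the spec walk-through", {
  ann <- domain_annotation(data.frame(gene = c("A", "A", "B", "X"),
                                      domain = c("D1", "D2", "Db", "Dx")))
  ppi <- data.frame(a = "A", b = "X")
  ddi <- data.frame(a = "D2", b = "Dx")
  bnd <- interaction_bundle(ppi, ddi, NULL, ann)
  f1 <- fusion_spec("A", "B", "D1", "Db", ann)
  # parent B has no PPI edges in this toy, which warns by contract
  expect_equal(nrow(suppressWarnings(predict_ppi_partners(f1, bnd))), 0)
  f2 <- fusion_spec("A", "B", c("D1", "D2"), "Db", ann)
  pp <- suppressWarnings(predict_ppi_partners(f2, bnd))
  expect_equal(pp$partner, "X")
  expect_equal(pp$fusion_domain, "D2")
})

test_that("all retained-domain subsets match the set-algebra oracle", {
  doms <- c("A1", "A2", "A3", "B1", "B2", "B3")
  for (mask in 0:63) {
    ret <- doms[bitwAnd(mask, 2^(0:5)) > 0]
    fu <- fusion_spec("GENEA", "GENEB",
                      retained5 = intersect(ret, c("A1", "A2", "A3")),
                      retained3 = intersect(ret, c("B1", "B2", "B3")),
                      annotations = wx$annotations)
    got <- sort(unique(predict_ppi_partners(fu, wx$bundle)$partner))
    want <- oracle_ppi_partners(ret, c("GENEA", "GENEB"),
                                wx$bundle$ppi, wx$bundle$ddi,
                                wx$annotations)
    expect_identical(got, want)
  }
})

test_that("prediction is monotone in the retained-domain sets", {
  doms5 <- c("A1", "A2", "A3"); doms3 <- c("B1", "B2", "B3")
  prev <- character()
  for (k in 0:3) {   # growing chain of retained sets
    fu <- fusion_spec("GENEA", "GENEB",
                      retained5 = doms5[seq_len(k)],
                      retained3 = doms3[seq_len(k)],
                      annotations = wx$annotations)
    cur <- unique(predict_ppi_partners(fu, wx$bundle)$partner)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("TF targets follow the retained-DNA-binding-domain rule", {
  # B3 (DNA-binding) retained -> both of GENEB's targets inherited
  tf <- predict_tf_targets(wx$fusion, wx$bundle)
  expect_setequal(tf$target, c("T1", "T2"))
  expect_true(all(tf$parent == "GENEB"))
  # B3 lost -> nothing from GENEB even though it is a TF
  fu_lost <- fusion_spec("GENEA", "GENEB", c("A1", "A2"), "B2",
                         wx$annotations)
  expect_equal(nrow(predict_tf_targets(fu_lost, wx$bundle)), 0)
  # regulator absent from the TF table -> nothing
  b2 <- wx$bundle
  b2$tf_targets <- data.frame(a = "OTHER", b = "T9")
  expect_equal(nrow(predict_tf_targets(wx$fusion, b2)), 0)
})

test_that("predicted_partner_set merges channels and evidence", {
  pp <- predicted_partner_set(wx$fusion, wx$bundle)
  expect_setequal(pp$genes, wx$expected$blue)
  expect_setequal(pp$ppi_partners, c("P1", "P3", "P4"))
  expect_setequal(pp$tf_target_genes, c("T1", "T2"))
  expect_true(all(vapply(pp$evidence, function(e)
    nrow(e$ppi) + nrow(e$tf) >= 1, logical(1))))
  # a gene in both channels appears once with both evidence records
  b2 <- wx$bundle
  b2$tf_targets <- rbind(b2$tf_targets, data.frame(a = "GENEB", b = "P1"))
  pp2 <- predicted_partner_set(wx$fusion, b2)
  expect_equal(sum(pp2$genes == "P1"), 1)
  expect_equal(nrow(pp2$evidence[["P1"]]$ppi), 1)
  expect_equal(nrow(pp2$evidence[["P1"]]$tf), 1)
})

test_that("full retention predicts the DDI-supported neighbor union", {
  fu_all <- fusion_spec("GENEA", "GENEB", c("A1", "A2", "A3"),
                        c("B1", "B2", "B3"), wx$annotations)
  pp <- predicted_partner_set(fu_all, wx$bundle)
  want_ppi <- oracle_ppi_partners(c("A1", "A2", "A3", "B1", "B2", "B3"),
                                  c("GENEA", "GENEB"), wx$bundle$ppi,
                                  wx$bundle$ddi, wx$annotations)
  expect_setequal(pp$ppi_partners, want_ppi)
  expect_setequal(pp$tf_target_genes, c("T1", "T2"))
})

test_that("empty seed union is fatal; keep_unannotated flag works", {
  fu0 <- fusion_spec("GENEA", "GENEB", character(), character(),
                     wx$annotations)
  expect_error(predicted_partner_set(fu0, wx$bundle), "cannot be seeded")
  pp <- predict_ppi_partners(wx$fusion, wx$bundle, keep_unannotated = TRUE)
  expect_true("P6" %in% pp$partner)
})

test_that("a parent without PPI edges warns and contributes no candidates", {
  b2 <- wx$bundle
  b2$ppi <- b2$ppi[b2$ppi$a != "GENEB", ]
  expect_warning(pp <- predict_ppi_partners(wx$fusion, b2), "no PPI edges")
  expect_setequal(unique(pp$partner), c("P1", "P3"))
})
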