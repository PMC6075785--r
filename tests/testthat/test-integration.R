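# differential ranking, truncated product method, combination

make_expr <- function(seed = 1, n_genes = 60, shift_genes = NULL,
                      shift = 0, n = 5) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  v <- matrix(rnorm(n_genes * 2 * n, 7, 1), nrow = n_genes,
              dimnames = list(genes, paste0("s", seq_len(2 * n))))
  if (!is.null(shift_genes))
    v[shift_genes, n + seq_len(n)] <- v[shift_genes, n + seq_len(n)] + shift
  expression_dataset(v, rep(c("ctrl", "case"), each = n))
}

test_that("strongly shifted gene tops the differential ranking", {
  d <- make_expr(seed = 2, shift_genes = "g01", shift = 6)
  r <- differential_ranking(d)
  expect_equal(r$gene[1], "g01")
  st <- attr(r, "stats")
  expect_gt(st$mean_diff[st$gene == "g01"], 4)
})

test_that("label swap reverses the ranking exactly", {
  d <- make_expr(seed = 3, shift_genes = c("g01", "g02"), shift = 3)
  r1 <- differential_ranking(d)
  d2 <- expression_dataset(d$values,
                           factor(d$groups,
                                  levels = rev(levels(d$groups))))
  r2 <- differential_ranking(d2)
  expect_equal(r1$score, -rev(r2$score), tolerance = 1e-12)
})

test_that("null data gives uniform differential p-values", {
  d <- make_expr(seed = 4, n_genes = 400)
  p <- attr(differential_ranking(d), "stats")$p
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("zero-variance genes are flagged, not dropped", {
  d <- make_expr(seed = 5, n_genes = 20)
  v <- d$values; v["g01", ] <- 3
  d2 <- expression_dataset(v, d$groups)
  r <- differential_ranking(d2)
  st <- attr(r, "stats")
  expect_true(st$flat[st$gene == "g01"])
  expect_equal(st$p[st$gene == "g01"], 1)
  expect_true("g01" %in% r$gene)
})

test_that("truncated product score follows the spec examples", {
  expect_equal(truncated_product_W(0.001, 0.5, 0.01), 0.001)
  expect_equal(truncated_product_W(0.005, 0.005, 0.01), 2.5e-5)
  expect_equal(truncated_product_W(0.5, 0.5, 0.01), 1)
  expect_error(truncated_product_W(0, 0.5), "invalid input")
  expect_error(truncated_product_W(0.5, 1.2), "invalid input")
})

test_that("combined p-value conventions and monotonicity", {
  expect_equal(truncated_product_pvalue(1, 0.01), 1)
  expect_error(truncated_product_pvalue(0), "invalid input")
  # monotone non-decreasing in W
  ws <- c(1e-10, 1e-8, 1e-6, 1e-4, 1e-3, 5e-3, 1e-2)
  pc <- truncated_product_pvalue(ws, 0.01)
  expect_true(all(diff(pc) > 0))
  expect_true(all(pc > 0 & pc <= 1))
  # monotone in each input p through W
  p_lo <- truncated_product_pvalue(truncated_product_W(0.001, 0.002, 0.01))
  p_hi <- truncated_product_pvalue(truncated_product_W(0.005, 0.002, 0.01))
  expect_lt(p_lo, p_hi)
})

test_that("closed form agrees with the Monte-Carlo oracle on the grid", {
  set.seed(1234)
  mc <- oracle_tpm_mc(1e5)
  for (tau in c(0.01, 0.05)) {
    for (w in c(1e-6, 1e-5, 1e-4, 5e-3)) {
      p_cf <- truncated_product_pvalue(w, tau)
      se <- sqrt(p_cf * (1 - p_cf) / 1e5)
      expect_lt(abs(mc(w, tau) - p_cf), 3 * se + 1e-12,
                label = sprintf("MC gap at w=%g tau=%g", w, tau))
    }
  }
})

test_that("combined p-value is calibrated under the independent null", {
  # tau = 0.05: the continuous part of W has mass 1-(1-tau)^2 > 0.05, so
  # level 0.05 is attainable (at tau = 0.01 the statistic is conservative)
  set.seed(99)
  n <- 1e4
  W <- truncated_product_W(runif(n), runif(n), tau = 0.05)
  pc <- truncated_product_pvalue(W, tau = 0.05)
  rate <- mean(pc <= 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / n)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("combine_pathway_results joins, sorts, and reports unmatched", {
  et <- function(p, nm) {
    d <- data.frame(pathway = nm, size = 20, es = 0.5, nes = 1.2, p = p,
                    q = p, leading_edge = "")
    class(d) <- c("enrichment_table", "data.frame")
    attr(d, "collection_source") <- "toy"
    d
  }
  assoc <- et(c(0.001, 0.001, 0.2), c("pw1", "pw2", "pw3"))
  dereg <- et(c(0.002, 0.5, 0.3), c("pw1", "pw2", "pw4"))
  res <- combine_pathway_results(assoc, dereg, tau = 0.01)
  expect_equal(res$pathway[1], "pw1")   # both small beats one small
  expect_lt(res$p_combined[res$pathway == "pw1"],
            res$p_combined[res$pathway == "pw2"])
  expect_setequal(attr(res, "unmatched"), c("pw3", "pw4"))
  # symmetry in the two input tables
  res2 <- combine_pathway_results(dereg, assoc, tau = 0.01)
  expect_equal(res$W, res2$W)
  expect_equal(res$p_combined, res2$p_combined)
  # mismatched collections are an error
  dereg2 <- dereg; attr(dereg2, "collection_source") <- "other"
  expect_error(combine_pathway_results(assoc, dereg2), "different")
  # empty join is fatal
  expect_error(combine_pathway_results(et(0.1, "a"), et(0.1, "b")),
               "no pathway shared")
})
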