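# top-fraction selection, drug mapping, synergy filter, ROC/AUC

mk_ranked <- function(n, seed = 1) {
  set.seed(seed)
  rank_genes(stats::setNames(runif(n), sprintf("g%04d", seq_len(n))))
}

test_that("select_top_fraction uses the ceiling convention and nests", {
  r <- mk_ranked(100)
  expect_equal(nrow(select_top_fraction(r, 0.10)), 10)
  expect_equal(select_top_fraction(r, 0.10)$gene, r$gene[1:10])
  expect_equal(nrow(select_top_fraction(r, 1.0)), 100)
  r7 <- mk_ranked(7)
  expect_equal(nrow(select_top_fraction(r7, 0.10)), 1)  # ceiling(0.7)
  # nesting: f1 < f2 => top(f1) subset of top(f2)
  fs <- c(0.05, 0.2, 0.5, 1)
  tops <- lapply(fs, function(f) select_top_fraction(r, f)$gene)
  for (i in 1:3) expect_true(all(tops[[i]] %in% tops[[i + 1]]))
  expect_error(select_top_fraction(r, 0), "fraction")
})

test_that("map_drug_targets counts hits and best ranks", {
  r <- mk_ranked(50)
  top <- select_top_fraction(r, 0.2)   # 10 genes
  tab <- data.frame(
    drug = c("dA", "dA", "dB", "dC"),
    gene = c(top$gene[1], top$gene[5], r$gene[40], top$gene[2]))
  res <- map_drug_targets(top, tab)
  expect_equal(res$drug[1], "dA")      # two hits first
  expect_equal(res$n_hits[res$drug == "dA"], 2)
  expect_equal(res$best_rank[res$drug == "dA"], 1)
  expect_equal(res$n_hits[res$drug == "dB"], 0)
  expect_false(res$mappable[res$drug == "dB"])
  # exhaustive intersection oracle
  for (d in unique(tab$drug)) {
    want <- length(intersect(tab$gene[tab$drug == d], top$gene))
    expect_equal(res$n_hits[res$drug == d], want)
  }
})

test_that("drug hit counts are monotone in the fraction", {
  r <- mk_ranked(200, seed = 3)
  set.seed(4)
  tab <- data.frame(drug = rep(paste0("d", 1:5), each = 4),
                    gene = sample(r$gene, 20))
  prev <- rep(0, 5)
  for (f in c(0.05, 0.1, 0.3, 1)) {
    res <- map_drug_targets(select_top_fraction(r, f), tab)
    cur <- res$n_hits[order(res$drug)]
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("synergy filter applies all three thresholds", {
  r <- mk_ranked(1000, seed = 5)
  de <- data.frame(gene = r$gene,
                   fold_change = 1, p = 1)
  de$fold_change[de$gene == r$gene[5]] <- 2
  de$p[de$gene == r$gene[5]] <- 0.01
  de$fold_change[de$gene == r$gene[500]] <- 2   # good DE, bad rank
  de$p[de$gene == r$gene[500]] <- 0.01
  de$fold_change[de$gene == r$gene[10]] <- 1.2  # good rank, weak FC
  de$p[de$gene == r$gene[10]] <- 0.01
  got <- prioritize_synergistic_targets(r, de)
  expect_equal(as.character(got), r$gene[5])
  # row-by-row oracle on the full table
  top <- select_top_fraction(r, 0.10)$gene
  want <- de$gene[de$fold_change > 1.5 & de$p < 0.05 & de$gene %in% top]
  expect_setequal(as.character(got), want)
})

test_that("missing DE genes are reported, not silently kept", {
  r <- mk_ranked(20, seed = 6)
  de <- data.frame(gene = r$gene[-1], fold_change = 2, p = 0.001)
  got <- prioritize_synergistic_targets(r, de, top_fraction = 0.5)
  expect_equal(attr(got, "missing"), r$gene[1])
  expect_false(r$gene[1] %in% got)
})

test_that("ROC/AUC extremes and the Mann-Whitney pair oracle", {
  r <- mk_ranked(40, seed = 7)
  expect_equal(roc_auc(r, r$gene[1:10])$auc, 1.0)
  expect_equal(roc_auc(r, r$gene[31:40])$auc, 0.0)
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    sc <- stats::setNames(sample(seq_len(10), n, replace = TRUE) / 10,
                          sprintf("g%04d", seq_len(n)))  # ties likely
    pos <- sample(names(sc), sample(3:8, 1))
    rr <- rank_genes(sc)
    lab <- rr$gene %in% pos
    expect_equal(roc_auc(rr, pos)$auc, oracle_auc(rr$score, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms; null is ~0.5", {
  set.seed(9)
  sc <- stats::setNames(runif(1000), sprintf("g%04d", 1:1000))
  pos <- sample(names(sc), 100)
  a1 <- roc_auc(rank_genes(sc), pos)$auc
  a2 <- roc_auc(rank_genes(exp(4 * sc)), pos)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_lt(abs(a1 - 0.5), 0.05)   # labels independent of scores
})

test_that("ROC curve points run from (0,0) to (1,1) monotonically", {
  r <- mk_ranked(60, seed = 10)
  roc <- roc_auc(r, sample(r$gene, 15), exclude = r$gene[1])
  pts <- roc$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_equal(roc$n_pos + roc$n_neg, 59)   # one gene excluded
  expect_error(roc_auc(r, "absent"), "no positive")
})
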