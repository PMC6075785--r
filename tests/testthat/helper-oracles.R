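# Independent oracles and small utilities shared across the test files.
# These deliberately re-derive results by direct enumeration / direct
# solves, not by calling the code paths they check.

# quiet RWR: the 1e-30 tolerance is unreachable in double precision, so the
# non-convergence warning is expected and suppressed in tests
rwr_quiet <- function(...) suppressWarnings(random_walk_restart(...))

# brute-force GSEA running-sum scan: explicit loop over the ranked list
oracle_es <- function(genes, scores, gene_set, weight) {
  N <- length(genes)
  hit <- genes %in% gene_set
  k <- sum(hit)
  stopifnot(k > 0, k < N)
  wsum <- sum(abs(scores[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (wsum > 0) abs(scores[i])^weight / wsum else 1 / k
    } else {
      run <- run - 1 / (N - k)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# set-algebra partner oracle: direct filter over all candidate x domain-pair
# combinations, independent of predict_ppi_partners' loop structure
oracle_ppi_partners <- function(retained, parents, ppi, ddi, annotations) {
  nbr <- function(g) unique(c(ppi$b[ppi$a == g], ppi$a[ppi$b == g]))
  cand <- setdiff(unique(unlist(lapply(parents, nbr))), parents)
  ddi_keys <- unique(c(paste(ddi$a, ddi$b), paste(ddi$b, ddi$a)))
  keep <- vapply(cand, function(x) {
    dx <- annotations$domain[annotations$gene == x]
    if (!length(dx) || !length(retained)) return(FALSE)
    grid <- expand.grid(f = retained, x = dx, stringsAsFactors = FALSE)
    any(paste(grid$f, grid$x) %in% ddi_keys)
  }, logical(1))
  sort(cand[keep])
}

# random connected graph: spanning tree over a random permutation plus
# extra random edges
random_connected_graph <- function(n, extra = n) {
  perm <- sample(n)
  tree <- data.frame(a = paste0("n", perm[-1]),
                     b = paste0("n", perm[pmax(1, floor(seq(2, n) / 2))]))
  i <- sample(n, extra, replace = TRUE)
  j <- sample(n, extra, replace = TRUE)
  ok <- i != j
  edges <- rbind(tree, data.frame(a = paste0("n", i[ok]),
                                  b = paste0("n", j[ok])))
  gene_network(edges)
}

# Monte-Carlo oracle for the truncated-product null: empirical
# Pr(W <= w) from independent uniform pairs, with the truncation applied
# directly (not via the package function)
oracle_tpm_mc <- function(n = 1e5) {
  p1 <- runif(n); p2 <- runif(n)
  function(w, tau) {
    W <- ifelse(p1 <= tau, p1, 1) * ifelse(p2 <= tau, p2, 1)
    mean(W <= w)
  }
}

# brute-force pair-counting AUC (Mann-Whitney with half-credit for ties)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
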