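---
title: "Inferring fusion-associated pathways from retained protein domains"
author: "fusenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fusion-associated pathways from retained protein domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusenet)
```

## The model

A gene fusion's protein keeps a subset of each parental protein's domains.
`fusenet` rests on two mechanistic assumptions and one statistical one:

1. **Interaction inheritance.** A parental protein–protein interaction
   survives in the fusion iff it can still be explained by a domain–domain
   contact: some retained fusion domain pairs with some domain annotated on
   the partner in the DDI catalog. Likewise, a parent's transcriptional
   targets are inherited iff the fusion retains at least one of that
   parent's DNA-binding domains. The method therefore only ever *filters*
   parental interactions — it cannot propose interactions created de novo by
   new domain juxtapositions, which is a stated limitation, not an
   oversight.
2. **Guilt by association.** Genes functionally related to the fusion are
   those close, in a compiled gene network, to its predicted interaction
   partners. Closeness is measured by the stationary distribution of a
   random walk with restart (RWR) seeded uniformly on the partners:
   $p_{t+1} = (1-\gamma)\,T\,p_t + \gamma\,p_0$, with $T$ the
   column-normalized adjacency matrix.
3. **Two-channel evidence.** Network association is condition-agnostic (the
   network pools interactions from many cellular states), so an expression
   contrast (fusion-positive or treated vs control) supplies a second,
   condition-specific p-value per pathway, and the two are combined with the
   truncated product method (TPM).

## Parameters that matter

| parameter | default | units / range | why this default |
|---|---|---|---|
| `gamma` (restart) | 0.7 | probability, (0, 1] | the customary value in RWR gene prioritization; higher = more local to the seeds. The source method does not state its value. |
| `tol` | 1e-30 | L1 change per iteration | stated convergence threshold of the method; unreachable in double precision (see below) |
| `max_iter` | 10000 | iterations | cap when `tol` is unreachable |
| `weight` (GSEA) | 1 | exponent on score | standard weighted statistic; 0 (rank-only) available and used by the invariance tests |
| `n_perm` | 10000 | permutations | resolution 1/(n+1) comfortably below `tau`; analyses at reduced scale pass smaller values explicitly |
| `min_size`, `max_size` | 10, 500 | genes in-ranking | conventional GSEA set-size filter |
| `tau` (TPM) | 0.01 | p-value threshold | the stated truncation point for both channels |
| `fraction` | 0.10 | of ranked genes | the stated "top 10%" convention for drug mapping, with `ceiling` sizing |
| fold change, p | 1.5, 0.05 | linear FC, p | the stated synergistic-target filter |

## Numerical choices

**Convergence.** The stated threshold "1e-30" lies far below the ~1e-16
resolution of double-precision iterates, so the iteration also stops once
the successive change fails to shrink for 10 consecutive iterations — at
that point the iterate *is* the double-precision fixed point. The walk still
warns (the `tol` contract was not met literally) and the acceptance tests
confirm agreement with the direct linear solve
$p = \gamma (I - (1-\gamma) T)^{-1} p_0$ to 1e-10 on hundreds of random
graphs. The change norm is L1 by default (the method does not state a norm;
L1 pairs naturally with probability vectors), selectable via `norm`.

**Dangling nodes.** Degree-0 nodes have all-zero columns in $T$. The walker
standing on one restarts from the seed distribution, which preserves
$\sum_i p_i = 1$ exactly; conservation and the elementwise bound
$p(g) \ge \gamma p_0(g)$ are tested invariants.

**GSEA statistic and null.** The running sum increments hits by
$|s|^w/\sum_{hits}|s|^w$ and decrements misses by $1/(N-N_{hits})$; the ES
is the signed maximum deviation (exact ties resolve to the positive side —
a measure-zero case with continuous scores). Since an association ranking
has no phenotype labels, the null permutes gene sets: random same-size sets
drawn from the ranked list, cached per set size within an analysis. The
p-value is conditional on the enrichment direction,
$(1 + \#\{\text{same-sign nulls at least as extreme}\}) /
(1 + \#\{\text{same-sign nulls}\})$: counting same-sign extremes against the
*full* permutation count is anti-conservative and visibly non-uniform under
the null, and the package's null-calibration acceptance test would fail
with it. If every hit score is zero (possible at `weight = 1` in a
degenerate tail), increments fall back to equal weights rather than 0/0.

**Truncated product.** For two independent uniform p-values,
$\Pr(W \le w)$ is evaluated by conditioning on how many p-values fall below
$\tau$; the $w(1 + 2\ln\tau - \ln w)$ branch is computed as
$\exp(\ln w + \log(1{+}a))$ to stay finite for very small $W$. $W = 1$
(neither p-value below $\tau$) maps to a combined p of exactly 1 — the
$k=0$ case the closed form leaves implicit. Note a structural property,
not a bug: with $\tau = 0.01$ only $1-(1-\tau)^2 \approx 0.0199$ of the
null mass lies below 1, so the combined p-value is *conservative* at the
0.05 level by construction; the calibration test therefore runs at
$\tau = 0.05$, where exact level-0.05 calibration is attainable and holds.
The two channel p-values are treated as independent even though pathway
membership makes them mildly dependent in practice; this mirrors the
method's own usage and is documented rather than corrected.

**Welch ranking.** The differential ranking key is
$\mathrm{sign}(\Delta\bar{x})\,(-\log_{10} p)$ from a per-gene Welch t-test
on log-scale values. Zero-variance, zero-difference genes get $p = 1$ and
stay in the ranking (flagged `flat`); p-values are floored at 1e-320 before
the log. A precomputed ranking can be substituted by calling the enrichment
layer directly with any `ranked_genes` object.

**Ties and ordering.** Gene ranking breaks score ties lexicographically and
records them, so every downstream selection (top-fraction cutoffs, ROC
sweeps) is deterministic. ROC handles tied scores by rank averaging, making
the AUC identical to the normalized Mann–Whitney statistic.

## The synthetic world

`simulate_scenario()` emulates the full input bundle at toy scale: an
Erdős–Rényi background (p = 0.01, ~degree 5 at 500 genes) with one dense
planted block (p = 0.3, 40 genes), two parental genes wired so that the
fusion's retained domains have DDI support only to designated neighbors
inside the module (a lost domain supports others, which the fusion must
drop), a TF parent whose DNA-binding domain is retained, a pathway
collection whose planted set equals the module among 50 random decoys, and
Gaussian log-scale expression shifting module genes by 1.5 SD in cases
(6 vs 6 samples). Defaults are fixed once as the standard benchmark; the
acceptance suite runs them unchanged over 5 seeds.

What a green benchmark does **not** establish: performance on real
databases (scale-free degree structure, annotation bias, correlated
pathways), robustness to incomplete domain annotation, or count-based
RNA-seq noise (the generator is Gaussian by design, matching the Welch
default). The planted module is a best-case guilt-by-association signal;
real effect structure is weaker and less modular.

## Design choices where the design was open

- **Candidate universe**: partners are restricted to parental PPI
  neighbors; unannotated candidates are dropped (reported in diagnostics),
  with `keep_unannotated` to retain them. The DDI-supporting domain must be
  annotated on the candidate itself.
- **Parental genes** are excluded from the seed set (`include_parents`
  flag to override) and from ROC universes by default — they trivially rank
  at the top and would inflate every evaluation.
- **Propagation network**: the undirected union of PPI and symmetrized
  TF-target edges; the network file is an input, so any compiled network
  can be substituted.
- **Seed masses** are uniform over the full predicted partner set (PPI
  partners and TF targets alike).
- **Multiple testing**: BH q-values are reported alongside raw p in every
  table, though the combination step consumes raw p-values.
- **Top-fraction size** uses the ceiling convention
  ($\lceil f N \rceil$), so a 10% cut of 7 genes selects 1.

## Known limitations

- No de-novo interactions from novel domain combinations; fusions whose
  parents are poorly annotated yield little or nothing (an empty seed set
  is a hard error, by contract).
- Breakpoints are not modeled: the caller must classify each domain as
  retained or lost; partially truncated domains need an upstream call.
- The TPM independence assumption is optimistic when the same expression
  data inform correlated pathways.
- Permutation p-values are bounded below by the permutation count; at the
  default `tau`, `n_perm` must exceed ~100 for a pathway to be combinable
  at all.
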