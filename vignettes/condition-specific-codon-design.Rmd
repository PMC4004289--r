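---
title: "Condition-specific codon context matrices and probabilistic gene design"
author: "codonContext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific codon context matrices and probabilistic gene design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonContext)
```

## The model

Codon usage bias — the non-uniform use of synonymous codons — differs not
only between organisms but between growth conditions of the same
organism: the genes highly expressed during rapid growth in rich media
favour different synonymous codons than the genes up-regulated in, say,
stationary phase. A heterologous gene optimized against a whole-genome
codon table therefore need not be optimal for the condition under which
it will actually be expressed. This package builds the codon model from
a *condition-specific* gene set instead, and extends it from single
codons to adjacent codon pairs (codon context), which track translation
elongation more closely than single-codon frequencies.

The central object is the **codon context matrix**: for the 61 sense
codons (the three stop codons are excluded throughout), entry $(c_1,
c_2)$ stores

$$P(c_2 \mid c_1, \mathrm{aa}(c_2)) =
  \frac{N(c_1, c_2)}{\sum_{c' \sim c_2} N(c_1, c')},$$

where $N(c_1, c_2)$ counts adjacent occurrences of the pair across the
training genes (pairs never span two genes) and $c' \sim c_2$ runs over
the synonymous codons of $c_2$'s amino acid. Conditioning on the second
amino acid — not on the first codon alone — is what makes the ATG (Met)
and TGG (Trp) columns identically 1 wherever their context was observed:
these amino acids have no synonyms, so there is no choice to model. Each
observed (first codon, second amino acid) context is thus a probability
distribution over a synonymous group; unobserved contexts are stored as
all-zero groups, with no pseudocounts, so that design-time fallback is an
explicit policy rather than a hidden smoothing constant.

**Gene design** inverts the model. Given a target protein, the first
codon is drawn from the training marginal of the first amino acid (for
the universal Met start this is necessarily ATG); each subsequent codon
is drawn from the previous codon's row restricted to the current amino
acid's group. A Met–Cys pair whose context stores probabilities 0.6/0.4
is thus rendered ATGTGT in 60% and ATGTGC in 40% of designs. Because the
procedure is stochastic, it yields *families* of variants rather than a
single sequence, and keeps synonymous usage balanced instead of
collapsing every residue onto one codon the way argmax table
optimization (`designTable()`) does. The deterministic table method is
retained as the classical baseline.

**Drift** between two conditions is the Frobenius norm of the entrywise
difference of their probability matrices,
$\lVert A - B \rVert_F = \sqrt{\sum_{ij} (A_{ij} - B_{ij})^2}$,
computed over all $61 \times 61$ cells. Identical matrices have drift 0.
Drift is computed on probabilities, not raw counts — counts would make
the measure grow with corpus size — and cells of unobserved contexts
enter as their stored zeros, matching a plain difference of the stored
matrices. In the subsampling experiment (`subsampleDrift()`), random
gene sets of increasing size are drawn without replacement, a matrix is
built per draw, and the mean drift to a reference matrix is fitted with
a power regression $y = A x^b$ by ordinary least squares on
$\log_{10} y$ versus $\log_{10} x$. As subsets grow they average towards
the reference, so $b < 0$; a gene set with genuinely distinct codon
usage (e.g. the most highly expressed genes) sits *above* the random
curve at its size.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `adjPMax` | `selectDifferential()` | 0.05 | conventional adjusted-p cut; strict inequality |
| `absLogfcMin` | `selectDifferential()` | 1 | two-fold change on the log2 scale; strict inequality |
| `sizes` | `subsampleDrift()` | 30…300 | spans the gene-set sizes typical of condition models |
| `replicates` | `subsampleDrift()` | 5 | enough for a mean/sd per size while staying cheap |
| `concentration` | `randomContextMatrix()` | 0.3 | Dirichlet skew of synthetic codon preferences (below) |
| `logMeanShift` | `sampleExpressionTable()` | 2 | expression advantage of biased genes, natural-log units |
| `sdlog` | `sampleExpressionTable()` | 0.5 | log-scale spread of expression noise |

## What the synthetic generator emulates — and what it does not

`sampleGenome()` produces genes as Markov chains of codons: a uniform
amino-acid path, the first codon from the generator's marginal, each
subsequent codon from the generator's conditional row. This makes the
generator's conditional structure *exactly* the quantity that
`buildContextMatrix()` estimates, which is what parameter-recovery tests
need. The default Dirichlet concentration of 0.3 gives strongly skewed
synonymous preferences (a preferred codon typically carrying 60–95% of
its group's mass), in line with the pronounced bias of highly expressed
yeast genes; it was fixed as a modelling choice before any validation
runs. With `biasGenerator`/`biasFraction`, a flagged subset of genes is
drawn from a second matrix, creating a known "highly expressed subset"
with distinct codon usage. `sampleExpressionTable()` then gives those
genes a log-normal expression advantage (log-mean shift 2, `sdlog` 0.5 —
strong but deliberately not perfect separation: roughly nine of ten
top-100 genes are truly biased), plus up-regulated `logfc`/`adj_p`
columns.

What the simulator does **not** model: realistic gene-length
distributions, amino-acid composition (real proteomes are far from
uniform), GC gradients, or any correlation structure beyond first-order
codon pairs. Passing tests on synthetic data therefore demonstrate that
the estimators and the design procedure are correct and internally
consistent — not that any particular biological dataset will show a
particular drift value.

## Numerical and design choices

- **Canonical order.** All matrices index the 61 sense codons
  alphabetically; display groupings by amino acid are a plotting
  concern.
- **Trailing stops.** A single terminal stop codon is accepted and
  silently stripped before any counting, so stops never enter pair
  statistics; whether public gene sets include them is ambiguous, and
  stripping makes the two conventions equivalent.
- **RNG contract.** One seeded generator per design; one uniform draw
  per codon position, consumed left to right; the codon is chosen by
  cumulative-probability inversion over the synonymous group in
  canonical order. Positions with a single codon still consume a draw.
  This makes designs byte-reproducible and the contract portable.
- **Unseen contexts.** Design backs off to the amino acid's training
  marginal, or to uniform if the amino acid was never observed;
  `fallbackEvents` counts the positions affected, keeping the policy
  auditable. Variant batches derive seeds `seed, seed + 1, …`;
  duplicate variants are permitted (independent draws).
- **Ties.** Argmax table design breaks ties by the alphabetically
  smallest codon; expression selectors break value ties by ascending
  gene id. Both keep results independent of input row order.
- **Thresholds.** The differential filter uses strict inequalities
  (`adj_p < 0.05`, `|logfc| > 1`), and ranks survivors by descending
  `|logfc|`; the tie rule at a top-`n` cutoff is this package's own
  deterministic choice.
- **Degenerate inputs.** Empty sequence sets, all-single-codon gene
  sets, non-positive power-law inputs and subsamples larger than the
  genome are errors; an empty differential selection is a warning plus
  an empty result, since it is a legitimate biological outcome.
- **Power fit.** Log–log OLS; on noiseless $y = Ax^b$ data the
  coefficients are recovered exactly and the (meaningless) residual
  variance warning is suppressed.

## Statistical behaviour of matrix recovery

A context estimated from $n$ observations has per-entry standard error
$\sqrt{p(1-p)/n}$, so entries converge at rate $O(1/\sqrt{n})$. The test
suite checks recovery in that form: mean absolute error over
well-observed contexts (at least 200 observations) stays small at 500
genes × 300 codons, and errors shrink as the corpus grows. Note the
implied scale: with a uniform 20-letter amino-acid path, a single
context at that corpus size collects at most a few hundred observations,
so individual entries still carry sampling noise of a few percent —
worst-case (maximum) entry error bounds tighter than that noise floor
require corpora orders of magnitude larger, not a better estimator.

## Problem sizes used in the checks

The validation suite runs synthetic corpora of 20–1,000 genes of 30–300
codons, 10,000-replicate design frequency checks, 50 random matrix pairs
for the norm oracle, and the full subsampling experiment (sizes 30–300,
five replicates) on a 1,000-gene heterogeneous genome with a 10% biased
subset — sizes chosen to exercise every code path at desk scale while
mirroring the gene-set sizes a condition model would use in practice.

## Known limitations

- Standard nuclear genetic code only; no alternative translation
  tables.
- First-order codon-pair model: no higher-order context, no mRNA
  secondary structure, GC targeting or restriction-site avoidance in
  design.
- Drift values are descriptive; the package attaches no significance
  test to them.
- The expression module consumes summary tables; normalization and
  linear-model fitting belong to upstream tools.
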