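# codonContext

Condition-specific codon context matrices, probabilistic gene design,
and codon-usage drift analysis.

## The problem

Synonymous codon usage is biased, and the bias is not one number per
organism: the genes highly expressed in rich-media growth prefer
different codons than the genes up-regulated in stationary phase or
under a given transcription factor. Optimizing a heterologous gene
against a whole-genome codon table can therefore miss the condition the
gene will actually be expressed in. `codonContext` is for metabolic
engineers and molecular biologists who want to (1) derive a codon model
from the gene set of *their* condition — the top expressed genes, or the
significantly up-regulated ones — (2) design DNA variants of a target
protein that follow that condition's codon-pair preferences, and (3)
quantify how far any two conditions' codon usage diverge.

## The model

For the 61 sense codons (stops excluded), the **codon context matrix**
stores conditional codon-pair probabilities

```
P(c2 | c1, aa(c2)) = N(c1, c2) / sum over c' synonymous with c2 of N(c1, c')
```

where `N(c1, c2)` counts adjacent codon pairs in the training genes.
Columns of the single-codon amino acids Met (ATG) and Trp (TGG) are 1
wherever observed. Gene design back-translates a protein by sampling
each codon from the previous codon's row, restricted to the current
amino acid's synonymous group — so a Met–Cys context stored as 0.6/0.4
yields ATGTGT in 60% of designs. Divergence between two conditions is
the Frobenius norm of the difference of their matrices,
`||A - B||_F = sqrt(sum((A - B)^2))`, and the drift of random gene
subsets against a reference follows a power law `y = A * x^b` in the
subset size.

## Worked example

Train a matrix on five toy genes in which Met–Cys occurs three times as
ATG·TGT and twice as ATG·TGC, then design variants:

```r
library(codonContext)

m <- buildContextMatrix(c(g1 = "ATGTGT", g2 = "ATGTGT", g3 = "ATGTGT",
                          g4 = "ATGTGC", g5 = "ATGTGC"),
                        sourceLabel = "met-cys")
probMatrix(m)["ATG", c("TGT", "TGC")]
#> TGT TGC
#> 0.6 0.4

vapply(designVariants("MC", m, n = 3, seed = 17), designedDNA, character(1))
#> [1] "ATGTGT" "ATGTGT" "ATGTGT"
```

Over many seeds the TGT variant appears 60% of the time — the design
samples the stored context probabilities rather than always taking the
argmax. On a synthetic genome with a flagged 10% subset drawn from a
different generator (emulating highly expressed genes with distinct
codon usage):

```r
gen    <- randomContextMatrix(seed = 1)
bias   <- randomContextMatrix(seed = 2)
genome <- sampleGenome(1000, 300, gen, seed = 3,
                       biasGenerator = bias, biasFraction = 0.1)
control <- buildContextMatrix(genome, sourceLabel = "control")
high    <- buildContextMatrix(genome[S4Vectors::mcols(genome)$biased],
                              sourceLabel = "biased-subset")
frobeniusDrift(high, control)
#> [1] 24.26084

subsampleDrift(genome, control, replicates = 5, seed = 4)
#> DriftCurve over 7 subsample sizes (seed 4)
#>  size replicates mean_norm    sd_norm
#>    30          5  9.840670 0.76569695
#>    50          5  6.891826 0.25647248
#>   100          5  4.737695 0.19257020
#>   150          5  3.618023 0.08863043
#>   200          5  3.004850 0.08991929
#>   250          5  2.611589 0.04270595
#>   300          5  2.374006 0.07997275
#>   power fit: drift = 78.67 * size^-0.615
```

Random subsets converge on the control matrix as they grow (negative
exponent), while the biased 100-gene subset drifts about five times
further (24.3) than random 100-gene subsets do on average (4.7) — the
signature of a gene set with genuinely condition-specific codon usage.

A command-line wrapper over the same functions is installed at
`inst/cli/codon-context.R` (subcommands `simulate`, `select`,
`build-table`, `build-matrix`, `design`, `drift`, `subsample`,
`audit`).

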