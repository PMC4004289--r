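# Synthetic genomes, expression tables and proteins with known
# codon-pair structure, so every pipeline stage is testable without any
# external data. Genes are Markov chains of codons driven by a generator
# CodonContextMatrix; the amino-acid path is uniform over the 20 letters,
# which keeps the generator's conditional structure exactly equal to what
# buildContextMatrix() estimates.

#' Random codon context matrix (synthetic generator)
#'
#' Draws, for every (first codon, second amino acid) context, a random
#' probability vector over the amino acid's synonymous group from a
#' symmetric Dirichlet. The default concentration 0.3 yields strongly
#' skewed synonymous preferences (a preferred codon typically carrying
#' 60-95% of the mass), emulating the pronounced codon usage bias of
#' highly expressed yeast genes. Synthetic training codon counts are
#' attached so design-time marginals are defined.
#'
#' @param seed Integer RNG seed.
#' @param concentration Dirichlet concentration parameter (> 0); smaller
#'   values give more extreme codon preferences.
#' @param sourceLabel Label stored with the matrix.
#' @return A fully observed [CodonContextMatrix-class] (every context's
#'   group sums to 1).
#' @examples
#' g <- randomContextMatrix(seed = 7)
#' all(abs(rowSums(probMatrix(g)[, synonymGroups("L")]) - 1) < 1e-9)
#' @export
randomContextMatrix <- function(seed, concentration = 0.3,
                                sourceLabel = "synthetic-generator") {
    if (concentration <= 0) stop("concentration must be positive")
    set.seed(seed)
    P <- matrix(0, 61L, 61L,
        dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
    for (a in .AA_LETTERS) {
        grp <- .SYNONYM_GROUPS[[a]]
        k <- length(grp)
        w <- matrix(stats::rgamma(61L * k, shape = concentration), 61L, k)
        rs <- rowSums(w)
        w[rs == 0, ] <- 1          # guard against gamma underflow
        P[, grp] <- w / rowSums(w)
    }
    counts <- setNames(numeric(61L), .SENSE_CODONS)
    for (a in .AA_LETTERS) {
        grp <- .SYNONYM_GROUPS[[a]]
        w <- stats::rgamma(length(grp), shape = concentration)
        if (sum(w) == 0) w <- rep(1, length(grp))
        counts[grp] <- round(1000 * w / sum(w)) + 1
    }
    new("CodonContextMatrix",
        P = P,
        pairCounts = matrix(0, 61L, 61L,
            dimnames = list(.SENSE_CODONS, .SENSE_CODONS)),
        codonCounts = counts, nGenes = 0, sourceLabel = sourceLabel)
}

# generator matrix -> fast sampling tables (per amino acid: codon
# indices, cumulative conditional rows, cumulative marginal, observed)
.samplerPrep <- function(m) {
    lapply(.SYNONYM_GROUPS, function(grp) {
        block <- m@P[, grp, drop = FALSE]
        denom <- rowSums(block)
        cnt <- m@codonCounts[grp]
        marg <- if (sum(cnt) > 0) cnt / sum(cnt) else
            rep(1 / length(grp), length(grp))
        cumP <- if (length(grp) == 1L) block else t(apply(block, 1L, cumsum))
        list(
            codons = grp,
            cumP = cumP,
            observed = denom > 1e-12,
            cumMarg = cumsum(marg))
    })
}

# one gene: uniform aa path, codons from the generator's conditionals
.sampleGene <- function(L, prep) {
    aaIdx <- sample.int(length(.AA_LETTERS), L, replace = TRUE)
    u <- runif(L)
    codons <- character(L)
    prev <- NULL
    for (i in seq_len(L)) {
        g <- prep[[aaIdx[i]]]
        cs <- if (i == 1L || !g$observed[[prev]]) g$cumMarg else
            g$cumP[prev, ]
        j <- findInterval(u[i], cs, left.open = TRUE) + 1L
        if (j > length(g$codons)) j <- length(g$codons)
        codons[i] <- g$codons[j]
        prev <- codons[i]
    }
    paste(codons, collapse = "")
}

#' Sample a synthetic genome from a generator context matrix
#'
#' Each gene is a Markov chain of codons: the first codon is drawn from
#' the generator's marginal codon distribution for a uniformly chosen
#' amino acid, and each subsequent codon from the generator's conditional
#' row given the previous codon, restricted to the next (uniformly
#' chosen) amino acid's synonymous group. A context matrix rebuilt from
#' such a genome converges entrywise to the generator. Optionally a
#' stated fraction of genes is drawn from a second generator, creating a
#' flagged subset with distinct codon usage that emulates a condition's
#' highly expressed genes.
#'
#' @param nGenes Number of genes (>= 1).
#' @param codonsPerGene Codons per gene: a single integer (>= 2) or a
#'   `c(min, max)` range sampled uniformly per gene.
#' @param generator A [CodonContextMatrix-class] ground truth (e.g.
#'   [randomContextMatrix()]).
#' @param seed Integer RNG seed; the genome is bit-reproducible under it.
#' @param biasGenerator Optional second [CodonContextMatrix-class] for
#'   the biased gene subset.
#' @param biasFraction Fraction of genes drawn from `biasGenerator`
#'   (in `[0, 1]`).
#' @return A named `DNAStringSet` (ids `g000001`, ...) whose
#'   `mcols()$biased` flags the genes drawn from the second generator.
#' @examples
#' g <- sampleGenome(3, 5, randomContextMatrix(1), seed = 2)
#' width(g)
#' @export
sampleGenome <- function(nGenes, codonsPerGene, generator, seed,
                         biasGenerator = NULL, biasFraction = 0) {
    stopifnot(methods::is(generator, "CodonContextMatrix"))
    if (nGenes < 1 || nGenes != round(nGenes))
        stop("nGenes must be a positive integer")
    if (length(codonsPerGene) == 1L) codonsPerGene <- rep(codonsPerGene, 2L)
    if (length(codonsPerGene) != 2L || any(codonsPerGene < 2))
        stop("codonsPerGene must be an integer >= 2 or a (min, max) range with min >= 2")
    if (biasFraction < 0 || biasFraction > 1)
        stop("biasFraction must lie in [0, 1]")
    if (biasFraction > 0 && is.null(biasGenerator))
        stop("biasFraction > 0 requires a biasGenerator")
    set.seed(seed)
    biased <- rep(FALSE, nGenes)
    if (biasFraction > 0)
        biased[sample.int(nGenes, round(biasFraction * nGenes))] <- TRUE
    lens <- if (codonsPerGene[1] == codonsPerGene[2])
        rep(codonsPerGene[1], nGenes)
    else sample(seq.int(codonsPerGene[1], codonsPerGene[2]), nGenes,
        replace = TRUE)
    prepMain <- .samplerPrep(generator)
    prepBias <- if (!is.null(biasGenerator)) .samplerPrep(biasGenerator)
    genes <- vapply(seq_len(nGenes), function(i)
        .sampleGene(lens[i], if (biased[i]) prepBias else prepMain),
        character(1))
    out <- Biostrings::DNAStringSet(genes)
    names(out) <- sprintf("g%06d", seq_len(nGenes))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(biased = biased)
    out
}

#' Sample a synthetic expression summary table
#'
#' Emulates a condition's expression data: the flagged (biased) genes
#' receive stochastically higher expression values (log-normal with the
#' log-mean shifted up by `logMeanShift`) so that [selectTopExpressed()]
#' preferentially recovers them, and the table also carries `logfc` /
#' `adj_p` columns in which the biased genes are up-regulated, so
#' [selectDifferential()] recovers them too.
#'
#' @param genomeIds Character vector of gene ids.
#' @param biasedIds Subset of `genomeIds` to up-shift.
#' @param seed Integer RNG seed.
#' @param logMeanShift Up-shift of the log-mean expression of biased
#'   genes, in natural-log units (default 2).
#' @param sdlog Log-scale standard deviation of expression (default
#'   0.5).
#' @return A data.frame with columns `gene_id`, `value`, `logfc`,
#'   `adj_p`.
#' @export
sampleExpressionTable <- function(genomeIds, biasedIds, seed,
                                  logMeanShift = 2, sdlog = 0.5) {
    if (!all(biasedIds %in% genomeIds))
        stop("biasedIds must be a subset of genomeIds")
    set.seed(seed)
    n <- length(genomeIds)
    biased <- genomeIds %in% biasedIds
    value <- stats::rlnorm(n, meanlog = ifelse(biased, logMeanShift, 0),
        sdlog = sdlog)
    logfc <- stats::rnorm(n, mean = ifelse(biased, 2.5, 0), sd = 0.5)
    pu <- runif(n)
    adj_p <- ifelse(biased, pu * 0.04, pu)
    data.frame(gene_id = genomeIds, value = value, logfc = logfc,
        adj_p = adj_p, stringsAsFactors = FALSE)
}

#' Random protein sequence
#'
#' Uniform i.i.d. amino acids with the first residue forced to Met,
#' mirroring a universal start codon.
#'
#' @param length Protein length (>= 1).
#' @param seed Integer RNG seed.
#' @return An `AAStringSet` of length one.
#' @examples
#' randomProtein(5, seed = 3)
#' @export
randomProtein <- function(length, seed) {
    if (length < 1 || length != round(length))
        stop("length must be a positive integer")
    set.seed(seed)
    aa <- sample(.AA_LETTERS, length, replace = TRUE)
    aa[1] <- "M"
    out <- Biostrings::AAStringSet(paste(aa, collapse = ""))
    names(out) <- sprintf("random_protein_L%d_s%d", as.integer(length),
        as.integer(seed))
    out
}
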