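# Probabilistic and table-based back-translation of proteins into
# codon-optimized DNA.
#
# RNG contract (reproducible across platforms): a single generator seeded
# once per design, one uniform draw per codon position consumed left to
# right, codon chosen by cumulative-probability inversion over the
# synonymous group in canonical (alphabetical) codon order.

# precompute per-matrix design structures shared across many designs
.designPrep <- function(m) {
    P <- m@P
    groups <- .SYNONYM_GROUPS
    observed <- lapply(groups, function(grp)
        rowSums(P[, grp, drop = FALSE]) > 1e-12)
    marginal <- lapply(groups, function(grp) {
        cnt <- m@codonCounts[grp]
        s <- sum(cnt)
        if (s > 0) cnt / s else NULL
    })
    list(P = P, groups = groups, observed = observed, marginal = marginal)
}

# one design under the RNG contract; returns list(dna, fallbackEvents)
.designOne <- function(aaVec, prep, seed) {
    set.seed(seed)
    L <- length(aaVec)
    u <- runif(L)
    codons <- character(L)
    fallback <- 0L
    prev <- NULL
    for (i in seq_len(L)) {
        a <- aaVec[i]
        grp <- prep$groups[[a]]
        if (is.null(grp)) stop("unknown amino-acid letter: ", a)
        if (i == 1L) {
            p <- prep$marginal[[a]]
            if (is.null(p)) {
                p <- rep(1 / length(grp), length(grp))
                fallback <- fallback + 1L
            }
        } else if (prep$observed[[a]][[prev]]) {
            p <- prep$P[prev, grp]
        } else {
            p <- prep$marginal[[a]]
            if (is.null(p)) p <- rep(1 / length(grp), length(grp))
            fallback <- fallback + 1L
        }
        cs <- cumsum(p)
        j <- findInterval(u[i], cs, left.open = TRUE) + 1L
        if (j > length(grp)) j <- length(grp)
        codons[i] <- grp[j]
        prev <- codons[i]
    }
    list(dna = paste(codons, collapse = ""), fallbackEvents = fallback)
}

.aaVector <- function(protein) {
    ch <- .asProteinCharacter(protein)
    if (length(ch) != 1L)
        stop("expected a single protein sequence, got ", length(ch))
    if (nchar(ch) == 0L) stop("protein is empty")
    aa <- strsplit(ch[[1]], "")[[1]]
    bad <- setdiff(unique(aa), .AA_LETTERS)
    if (length(bad))
        stop("protein contains non-standard letters: ",
            paste(bad, collapse = ", "))
    list(id = names(ch), aa = aa)
}

#' Probabilistically design a coding sequence for a protein
#'
#' Back-translates a protein using the conditional codon-pair
#' probabilities of a [CodonContextMatrix-class]. The first codon is
#' drawn from the matrix's training marginal for the first amino acid
#' (for a Met start this is necessarily ATG); each subsequent codon is
#' drawn from the row of the previous codon, restricted to the current
#' amino acid's synonymous group. If, for example, the matrix stores
#' P(ATG, TGT) = 0.6 and P(ATG, TGC) = 0.4, a Met-Cys pair is rendered
#' ATGTGT 60% of the time and ATGTGC 40% of the time over many designs.
#'
#' Contexts never observed in training fall back to the amino acid's
#' training marginal (uniform over the synonymous group if the amino acid
#' was never seen at all); each such position increments
#' `fallbackEvents`. With the same protein, matrix and seed the output is
#' identical byte for byte.
#'
#' @param protein A single protein (`AAString`, `AAStringSet` of length
#'   one, or character string); standard 20-letter alphabet, no stops.
#' @param m A [CodonContextMatrix-class].
#' @param seed Integer RNG seed (recorded in the result).
#' @return A [DesignResult-class]; `translateCds(designedDNA(x))`
#'   reproduces the input protein exactly.
#' @examples
#' m <- buildContextMatrix(c(rep("ATGTGT", 3), rep("ATGTGC", 2)))
#' designedDNA(designProbabilistic("MC", m, seed = 1))
#' @export
designProbabilistic <- function(protein, m, seed) {
    stopifnot(methods::is(m, "CodonContextMatrix"))
    pv <- .aaVector(protein)
    prep <- .designPrep(m)
    d <- .designOne(pv$aa, prep, seed)
    new("DesignResult",
        proteinId = pv$id, protein = paste(pv$aa, collapse = ""),
        dna = d$dna, method = "matrix_probabilistic",
        sourceLabel = m@sourceLabel, seed = as.numeric(seed),
        fallbackEvents = as.numeric(d$fallbackEvents))
}

#' Design several independent variants of a coding sequence
#'
#' Runs [designProbabilistic()] n times with derived seeds `seed`,
#' `seed + 1`, ..., `seed + n - 1`, mirroring the practice of testing a
#' handful of independently drawn variants per condition (e.g. three per
#' matrix). Duplicate sequences are permitted; results are ordered by
#' derived seed.
#'
#' @inheritParams designProbabilistic
#' @param n Number of variants (>= 1).
#' @return A list of n [DesignResult-class] objects.
#' @export
designVariants <- function(protein, m, n, seed) {
    stopifnot(methods::is(m, "CodonContextMatrix"))
    if (n < 1 || n != round(n)) stop("n must be a positive integer")
    pv <- .aaVector(protein)
    prep <- .designPrep(m)
    proteinStr <- paste(pv$aa, collapse = "")
    lapply(seq_len(n) - 1L, function(k) {
        d <- .designOne(pv$aa, prep, seed + k)
        new("DesignResult",
            proteinId = pv$id, protein = proteinStr,
            dna = d$dna, method = "matrix_probabilistic",
            sourceLabel = m@sourceLabel, seed = as.numeric(seed + k),
            fallbackEvents = as.numeric(d$fallbackEvents))
    })
}

#' Deterministically design a coding sequence from a usage table
#'
#' Classic most-abundant-codon optimization: each amino acid is rendered
#' as the codon with the highest relative frequency in its synonymous
#' group; ties are broken by the alphabetically smallest codon, so the
#' design is fully deterministic.
#'
#' @param protein A single protein sequence (as in
#'   [designProbabilistic()]).
#' @param t A [CodonUsageTable-class]; every amino acid of the protein
#'   must have at least one observed codon.
#' @return A [DesignResult-class] with method `"table_argmax"`.
#' @export
designTable <- function(protein, t) {
    stopifnot(methods::is(t, "CodonUsageTable"))
    pv <- .aaVector(protein)
    best <- vapply(.AA_LETTERS, function(a) {
        grp <- .SYNONYM_GROUPS[[a]]
        f <- t@relFreq[grp]
        if (sum(f) == 0) NA_character_ else grp[which.max(f)]
    }, character(1))
    missing <- unique(pv$aa[is.na(best[pv$aa])])
    if (length(missing))
        stop("amino acid(s) with no observed codon in the usage table: ",
            paste(missing, collapse = ", "))
    new("DesignResult",
        proteinId = pv$id, protein = paste(pv$aa, collapse = ""),
        dna = paste(best[pv$aa], collapse = ""),
        method = "table_argmax", sourceLabel = t@sourceLabel,
        seed = NA_real_, fallbackEvents = 0)
}

#' Audit designed sequences against their context-matrix model
#'
#' Compares, for every (first codon, second amino acid) context observed
#' in a set of designs, the empirical codon-selection fractions with the
#' model probabilities of the matrix. For designs sampled from the matrix
#' the maximum absolute deviation shrinks as the number of observations
#' grows (law of large numbers); this is the testable form of the claim
#' that probabilistic design keeps codon usage balanced rather than
#' collapsing onto single codons.
#'
#' @param designs A list of [DesignResult-class] objects, a single one,
#'   or a `DNAStringSet` / named character vector of designed CDS (e.g.
#'   re-read from FASTA).
#' @param m The [CodonContextMatrix-class] to audit against.
#' @return A data.frame with columns `first_codon`, `second_aa`, `codon`,
#'   `n_context`, `empirical_p`, `model_p`, `abs_dev`, one row per codon
#'   of each observed context; zero rows when the designs contain no
#'   codon pairs.
#' @export
pairFrequencyAudit <- function(designs, m) {
    stopifnot(methods::is(m, "CodonContextMatrix"))
    if (methods::is(designs, "DesignResult")) designs <- list(designs)
    if (length(designs) == 0L) stop("no designs to audit")
    dna <- if (is.list(designs)) {
        stopifnot(all(vapply(designs, methods::is, logical(1), "DesignResult")))
        setNames(vapply(designs, function(d) d@dna, character(1)),
            vapply(designs, function(d) d@proteinId, character(1)))
    } else .asDnaCharacter(designs)
    cc <- countCodonPairs(setNames(dna, make.unique(names(dna))))
    pc <- cc$pairCounts
    rows <- list()
    for (a in .AA_LETTERS) {
        grp <- .SYNONYM_GROUPS[[a]]
        block <- pc[, grp, drop = FALSE]
        n <- rowSums(block)
        for (c1 in .SENSE_CODONS[n > 0]) {
            emp <- block[c1, ] / n[c1]
            rows[[length(rows) + 1L]] <- data.frame(
                first_codon = c1, second_aa = a, codon = grp,
                n_context = n[c1], empirical_p = as.numeric(emp),
                model_p = as.numeric(m@P[c1, grp]),
                abs_dev = abs(as.numeric(emp) - as.numeric(m@P[c1, grp])),
                stringsAsFactors = FALSE, row.names = NULL)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(first_codon = character(0),
            second_aa = character(0), codon = character(0),
            n_context = numeric(0), empirical_p = numeric(0),
            model_p = numeric(0), abs_dev = numeric(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write design results to a FASTA file
#'
#' Headers record the design provenance:
#' `>id method=<m> source=<label> seed=<s> fallback_events=<k>`.
#'
#' @param designs A list of [DesignResult-class] objects (or one).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeDesigns <- function(designs, path) {
    if (methods::is(designs, "DesignResult")) designs <- list(designs)
    ids <- make.unique(vapply(designs, function(d) d@proteinId, character(1)))
    headers <- vapply(seq_along(designs), function(i) {
        d <- designs[[i]]
        sprintf("%s method=%s source=%s seed=%s fallback_events=%d",
            ids[i], d@method, d@sourceLabel,
            if (is.na(d@seed)) "NA" else format(d@seed),
            as.integer(d@fallbackEvents))
    }, character(1))
    dna <- Biostrings::DNAStringSet(
        vapply(designs, function(d) d@dna, character(1)))
    names(dna) <- headers
    Biostrings::writeXStringSet(dna, path, width = 70L)
    invisible(path)
}
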