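#' CodonUsageTable: per-codon counts and synonymous relative frequencies
#'
#' Summarises codon usage over a set of coding sequences, in the style of
#' the classic whole-genome codon usage tables: raw counts over all 64
#' codons (trailing stop codons are counted in their stop rows), relative
#' frequency of each sense codon within its synonymous group, and
#' occurrences per 1000 sense codons.
#'
#' @slot counts Named numeric vector over all 64 codons; non-negative
#'   integers.
#' @slot relFreq Named numeric vector over the 61 sense codons; each
#'   observed synonymous group sums to 1, unobserved codons are 0.
#' @slot perThousand Named numeric vector over the 61 sense codons; sums
#'   to 1000 when any sense codon was observed.
#' @slot nCodonsTotal Total number of sense codons counted.
#' @slot sourceLabel Free-text provenance label (e.g. the gene-set name).
#'
#' @seealso [buildUsageTable()]
#' @export
setClass("CodonUsageTable",
    representation(
        counts = "numeric",
        relFreq = "numeric",
        perThousand = "numeric",
        nCodonsTotal = "numeric",
        sourceLabel = "character"
    )
)

setValidity("CodonUsageTable", function(object) {
    msg <- character(0)
    allCodons <- c(.SENSE_CODONS, .STOP_CODONS)
    if (!identical(sort(names(object@counts)), sort(allCodons)))
        msg <- c(msg, "counts must be named by all 64 codons")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
        msg <- c(msg, "counts must be non-negative integers")
    if (!identical(names(object@relFreq), .SENSE_CODONS))
        msg <- c(msg, "relFreq must be named by the 61 sense codons in canonical order")
    for (a in .AA_LETTERS) {
        s <- sum(object@relFreq[.SYNONYM_GROUPS[[a]]])
        if (s > 0 && abs(s - 1) > 1e-9) {
            msg <- c(msg, sprintf("relFreq of amino acid %s sums to %g, not 1", a, s))
            break
        }
    }
    if (object@nCodonsTotal > 0 &&
        abs(sum(object@perThousand) - 1000) > 1e-6)
        msg <- c(msg, "perThousand must sum to 1000 over sense codons")
    if (length(msg)) msg else TRUE
})

#' CodonContextMatrix: conditional codon-pair probabilities
#'
#' The central object of the package: a 61 x 61 matrix over the sense
#' codons (stop codons excluded) whose entry (c1, c2) is the probability
#' of observing c2 as the second codon of an adjacent pair, given that the
#' first codon is c1 and the second amino acid is the one encoded by c2.
#' Columns belonging to the single-codon amino acids Met (ATG) and Trp
#' (TGG) are therefore 1 wherever the corresponding context was observed.
#' Contexts (c1, second amino acid) never observed in the training set
#' have probability 0 across the whole synonymous group; design-time code
#' detects this and applies a documented fallback.
#'
#' @slot P 61 x 61 numeric matrix of conditional probabilities, rows =
#'   first codon, columns = second codon, canonical codon order.
#' @slot pairCounts 61 x 61 matrix of raw adjacent-pair counts.
#' @slot codonCounts Named numeric vector over the 61 sense codons: total
#'   codon counts of the training sequences (used for marginal codon
#'   distributions at design time).
#' @slot nGenes Number of training sequences.
#' @slot sourceLabel Free-text provenance label.
#'
#' @seealso [buildContextMatrix()], [frobeniusDrift()],
#'   [designProbabilistic()]
#' @export
setClass("CodonContextMatrix",
    representation(
        P = "matrix",
        pairCounts = "matrix",
        codonCounts = "numeric",
        nGenes = "numeric",
        sourceLabel = "character"
    )
)

setValidity("CodonContextMatrix", function(object) {
    msg <- character(0)
    d <- dim(object@P)
    if (!identical(d, c(61L, 61L)))
        msg <- c(msg, "P must be 61 x 61")
    if (!identical(rownames(object@P), .SENSE_CODONS) ||
        !identical(colnames(object@P), .SENSE_CODONS))
        msg <- c(msg, "P must have the 61 sense codons as row and column names")
    if (any(object@P < 0) || any(object@P > 1))
        msg <- c(msg, "P entries must lie in [0, 1]")
    if (!identical(dim(object@pairCounts), dim(object@P)))
        msg <- c(msg, "pairCounts must have the same shape as P")
    if (any(object@pairCounts < 0))
        msg <- c(msg, "pairCounts must be non-negative")
    if (!identical(names(object@codonCounts), .SENSE_CODONS))
        msg <- c(msg, "codonCounts must be named by the 61 sense codons")
    if (length(msg) == 0L) {
        # each observed (first codon, second amino acid) group must be a
        # probability distribution; unobserved groups must be all-zero
        for (a in .AA_LETTERS) {
            grp <- .SYNONYM_GROUPS[[a]]
            s <- rowSums(object@P[, grp, drop = FALSE])
            bad <- abs(s - 1) > 1e-9 & s > 1e-9
            if (any(bad)) {
                msg <- c(msg, sprintf(
                    "P rows %s do not sum to 0 or 1 over amino acid %s",
                    paste(head(.SENSE_CODONS[bad], 3), collapse = ","), a))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' DesignResult: one designed coding sequence for a target protein
#'
#' @slot proteinId Identifier of the target protein.
#' @slot protein The target amino-acid sequence (single string).
#' @slot dna The designed coding DNA (single string, 3 x protein length).
#' @slot method `"matrix_probabilistic"` or `"table_argmax"`.
#' @slot sourceLabel Label of the matrix or table that drove the design.
#' @slot seed RNG seed used (`NA` for deterministic table designs).
#' @slot fallbackEvents Number of positions at which the unseen-context
#'   fallback distribution was used instead of the primary rule.
#'
#' @seealso [designProbabilistic()], [designTable()]
#' @export
setClass("DesignResult",
    representation(
        proteinId = "character",
        protein = "character",
        dna = "character",
        method = "character",
        sourceLabel = "character",
        seed = "numeric",
        fallbackEvents = "numeric"
    )
)

setValidity("DesignResult", function(object) {
    msg <- character(0)
    if (!object@method %in% c("matrix_probabilistic", "table_argmax"))
        msg <- c(msg, "unknown design method")
    if (nchar(object@dna) != 3L * nchar(object@protein))
        msg <- c(msg, "dna length must be 3 x protein length")
    if (length(msg)) msg else TRUE
})

#' DriftCurve: subsample size versus codon-matrix drift, with power fit
#'
#' Result of the random-subsampling drift experiment: for each subsample
#' size, the mean and standard deviation over replicates of the Frobenius
#' drift between the subsample's context matrix and a reference matrix,
#' together with the coefficients of the power regression y = A * x^b
#' fitted to the mean drift.
#'
#' @slot curve data.frame with columns `size`, `replicates`, `mean_norm`,
#'   `sd_norm`.
#' @slot fitA Power-law prefactor A (NA when the fit is undefined).
#' @slot fitB Power-law exponent b (NA when the fit is undefined).
#' @slot seed RNG seed of the subsampling experiment.
#'
#' @seealso [subsampleDrift()], [fitPowerLaw()]
#' @export
setClass("DriftCurve",
    representation(
        curve = "data.frame",
        fitA = "numeric",
        fitB = "numeric",
        seed = "numeric"
    )
)

setValidity("DriftCurve", function(object) {
    msg <- character(0)
    need <- c("size", "replicates", "mean_norm", "sd_norm")
    if (!all(need %in% names(object@curve)))
        msg <- c(msg, "curve must have columns size, replicates, mean_norm, sd_norm")
    else {
        if (any(object@curve$mean_norm < 0))
            msg <- c(msg, "mean_norm must be non-negative")
        if (any(object@curve$sd_norm < 0, na.rm = TRUE))
            msg <- c(msg, "sd_norm must be non-negative")
    }
    if (length(msg)) msg else TRUE
})
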