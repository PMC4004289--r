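#' @rdname accessors
#' @export
setMethod("probMatrix", "CodonContextMatrix", function(x) x@P)

#' @rdname accessors
#' @export
setMethod("pairCounts", "CodonContextMatrix", function(x) x@pairCounts)

#' @rdname accessors
#' @export
setMethod("codonCounts", "CodonContextMatrix", function(x) x@codonCounts)

#' @rdname accessors
#' @export
setMethod("codonCounts", "CodonUsageTable", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("relFreq", "CodonUsageTable", function(x) x@relFreq)

#' @rdname accessors
#' @export
setMethod("perThousand", "CodonUsageTable", function(x) x@perThousand)

#' @rdname accessors
#' @export
setMethod("nGenes", "CodonContextMatrix", function(x) x@nGenes)

#' @rdname accessors
#' @export
setMethod("nCodons", "CodonUsageTable", function(x) x@nCodonsTotal)

#' @rdname accessors
#' @export
setMethod("sourceLabel", "CodonContextMatrix", function(x) x@sourceLabel)

#' @rdname accessors
#' @export
setMethod("sourceLabel", "CodonUsageTable", function(x) x@sourceLabel)

#' @rdname accessors
#' @export
setMethod("sourceLabel", "DesignResult", function(x) x@sourceLabel)

#' @rdname accessors
#' @export
setMethod("designedDNA", "DesignResult", function(x) x@dna)

#' @rdname accessors
#' @export
setMethod("designedProtein", "DesignResult", function(x) x@protein)

#' @rdname accessors
#' @export
setMethod("designMethod", "DesignResult", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("fallbackEvents", "DesignResult", function(x) x@fallbackEvents)

#' @rdname accessors
#' @export
setMethod("rngSeed", "DesignResult", function(x) x@seed)

#' @rdname accessors
#' @export
setMethod("rngSeed", "DriftCurve", function(x) x@seed)

#' @rdname accessors
#' @export
setMethod("driftTable", "DriftCurve", function(x) x@curve)

#' @rdname accessors
#' @export
setMethod("powerFit", "DriftCurve", function(x) c(A = x@fitA, b = x@fitB))

setMethod("show", "CodonUsageTable", function(object) {
    cat("CodonUsageTable:", object@sourceLabel, "\n")
    cat("  sense codons counted:", object@nCodonsTotal, "\n")
    obs <- sum(object@relFreq > 0)
    cat("  observed sense codons:", obs, "of 61\n")
})

setMethod("show", "CodonContextMatrix", function(object) {
    cat("CodonContextMatrix:", object@sourceLabel, "\n")
    cat("  61 x 61 conditional codon-pair probabilities",
        "(stop codons excluded)\n")
    cat("  training genes:", object@nGenes,
        "| codon pairs:", sum(object@pairCounts), "\n")
    nObs <- sum(vapply(.AA_LETTERS, function(a) {
        grp <- .SYNONYM_GROUPS[[a]]
        sum(rowSums(object@P[, grp, drop = FALSE]) > 0.5)
    }, numeric(1)))
    cat("  observed (first codon, second amino acid) contexts:",
        nObs, "of", 61 * 20, "\n")
})

setMethod("show", "DesignResult", function(object) {
    cat("DesignResult:", object@proteinId,
        sprintf("(%d aa)", nchar(object@protein)), "\n")
    cat("  method:", object@method, "| source:", object@sourceLabel, "\n")
    cat("  seed:", object@seed,
        "| fallback events:", object@fallbackEvents, "\n")
    dna <- object@dna
    if (nchar(dna) > 60) dna <- paste0(substr(dna, 1, 57), "...")
    cat("  dna:", dna, "\n")
})

setMethod("show", "DriftCurve", function(object) {
    cat("DriftCurve over", nrow(object@curve), "subsample sizes",
        sprintf("(seed %s)\n", format(object@seed)))
    print(object@curve, row.names = FALSE)
    cat(sprintf("  power fit: drift = %.4g * size^%.4g\n",
        object@fitA, object@fitB))
})
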