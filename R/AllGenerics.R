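#' @name accessors
#' @title Accessors for codonContext S4 objects
#'
#' @description Slot accessors for [CodonUsageTable-class],
#' [CodonContextMatrix-class], [DesignResult-class] and
#' [DriftCurve-class] objects. Use these rather than `@` access.
#'
#' @param x An object of the relevant class.
#' @return `probMatrix` and `pairCounts` return 61 x 61 matrices;
#'   `codonCounts`, `relFreq` and `perThousand` named numeric vectors;
#'   `nGenes`, `nCodons`, `rngSeed` and `fallbackEvents` single numbers;
#'   `sourceLabel`, `designedDNA`, `designedProtein` and `designMethod`
#'   single strings; `driftTable` a data.frame; `powerFit` a named vector
#'   `c(A=, b=)`.
NULL

#' @rdname accessors
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' @rdname accessors
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname accessors
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))

#' @rdname accessors
#' @export
setGeneric("relFreq", function(x) standardGeneric("relFreq"))

#' @rdname accessors
#' @export
setGeneric("perThousand", function(x) standardGeneric("perThousand"))

#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname accessors
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))

#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname accessors
#' @export
setGeneric("designedDNA", function(x) standardGeneric("designedDNA"))

#' @rdname accessors
#' @export
setGeneric("designedProtein", function(x) standardGeneric("designedProtein"))

#' @rdname accessors
#' @export
setGeneric("designMethod", function(x) standardGeneric("designMethod"))

#' @rdname accessors
#' @export
setGeneric("fallbackEvents", function(x) standardGeneric("fallbackEvents"))

#' @rdname accessors
#' @export
setGeneric("rngSeed", function(x) standardGeneric("rngSeed"))

#' @rdname accessors
#' @export
setGeneric("driftTable", function(x) standardGeneric("driftTable"))

#' @rdname accessors
#' @export
setGeneric("powerFit", function(x) standardGeneric("powerFit"))
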