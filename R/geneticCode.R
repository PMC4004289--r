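# Standard nuclear genetic code services. Codons are written as DNA
# (ATG, not AUG); U on input is mapped to T at the I/O layer.

.codonToAa <- local({
    gc <- Biostrings::GENETIC_CODE
    setNames(as.character(gc), names(gc))
})

.STOP_CODONS <- sort(names(.codonToAa)[.codonToAa == "*"])
.SENSE_CODONS <- sort(names(.codonToAa)[.codonToAa != "*"])

# amino acid of each sense codon, in canonical (alphabetical) codon order
.AA_OF_CODON <- .codonToAa[.SENSE_CODONS]

.AA_LETTERS <- sort(unique(unname(.AA_OF_CODON)))

# amino-acid letter -> alphabetically ordered codons for that amino acid
.SYNONYM_GROUPS <- lapply(
    setNames(.AA_LETTERS, .AA_LETTERS),
    function(a) .SENSE_CODONS[.AA_OF_CODON == a]
)

#' The 61 sense codons in canonical order
#'
#' Canonical order is alphabetical over the 61 non-stop DNA triplets
#' (AAA ... TTT minus TAA, TAG, TGA). All matrices and tables produced by
#' this package index codons in this order.
#'
#' @return Character vector of length 61.
#' @examples
#' head(senseCodons())
#' length(senseCodons())
#' @export
senseCodons <- function() .SENSE_CODONS

#' The three stop codons of the standard nuclear code
#'
#' @return Character vector `c("TAA", "TAG", "TGA")`.
#' @export
stopCodons <- function() .STOP_CODONS

#' Synonymous codon groups of the standard genetic code
#'
#' @param aa Optional single amino-acid letter. When given, only that
#'   amino acid's codons are returned (as a character vector); otherwise
#'   the full named list is returned.
#' @return Named list mapping each of the 20 amino-acid letters to its
#'   alphabetically ordered codons, or a character vector for one letter.
#'   The groups partition the 61 sense codons; Met (ATG) and Trp (TGG)
#'   are the two single-codon groups.
#' @examples
#' synonymGroups("C")
#' lengths(synonymGroups())
#' @export
synonymGroups <- function(aa = NULL) {
    if (is.null(aa)) return(.SYNONYM_GROUPS)
    if (!aa %in% .AA_LETTERS)
        stop("unknown amino-acid letter: ", aa)
    .SYNONYM_GROUPS[[aa]]
}

#' The standard genetic code as used by this package
#'
#' @return A list with elements `codonToAa` (named character vector over
#'   all 64 codons, stops as `"*"`), `senseCodons`, `stopCodons` and
#'   `synonymGroups`.
#' @export
geneticCode <- function() {
    list(
        codonToAa = .codonToAa,
        senseCodons = .SENSE_CODONS,
        stopCodons = .STOP_CODONS,
        synonymGroups = .SYNONYM_GROUPS
    )
}

# split an upper-case DNA string (length a multiple of 3) into codons
.splitCodons <- function(dna) {
    n <- nchar(dna)
    if (n == 0L) return(character(0))
    substring(dna, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
}
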