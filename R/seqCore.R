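# FASTA I/O, CDS validation and translation. Sequences are carried as
# Biostrings XStringSet objects; codons are DNA triplets (U -> T on input).

#' Read coding DNA sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a
#' [Biostrings::DNAStringSet]. Sequence ids are taken from the header up
#' to the first whitespace; sequences are upper-cased and RNA `U` is
#' mapped to DNA `T`. Record order is preserved. An empty file yields an
#' empty set.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 some description", "atgtgt"), fa)
#' readCodingSequences(fa)
#' @export
readCodingSequences <- function(path) {
    raw <- .readFastaRaw(path)
    dna <- chartr("uU", "tT", toupper(raw))
    out <- Biostrings::DNAStringSet(dna)
    names(out) <- names(raw)
    out
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return An [Biostrings::AAStringSet]; ids are the headers up to the
#'   first whitespace, sequences upper-cased.
#' @export
readProteinSequences <- function(path) {
    raw <- .readFastaRaw(path)
    out <- Biostrings::AAStringSet(toupper(raw))
    names(out) <- names(raw)
    out
}

# shared FASTA reading: Biostrings parser plus an explicit pre-scan so a
# malformed file (sequence before any header) is reported with its line
.readFastaRaw <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    nonEmpty <- which(nzchar(trimws(lines)))
    if (length(nonEmpty) &&
        !startsWith(trimws(lines[nonEmpty[1]]), ">"))
        stop(sprintf(
            "malformed FASTA: line %d contains sequence before any '>' header",
            nonEmpty[1]))
    if (!length(nonEmpty)) return(setNames(character(0), character(0)))
    s <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(s))
    setNames(as.character(s), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `DNAStringSet`, `AAStringSet`, or named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
    if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(seqs, path, width = width)
    invisible(path)
}

#' Validate coding sequences
#'
#' Checks each sequence for the properties a protein-coding DNA sequence
#' must have before it can enter codon statistics: length a positive
#' multiple of 3, characters restricted to A/C/G/T (N tolerated only in
#' lenient mode), and no internal stop codon. A single trailing stop
#' codon is accepted in both modes and flagged so downstream counting can
#' strip it.
#'
#' In `strict` mode any violation rejects the sequence; in `lenient` mode
#' sequences are accepted but the violations are still reported as reason
#' codes, and codons containing N are counted so statistics code can skip
#' them.
#'
#' @param seqs A `DNAStringSet` (or named character vector of DNA).
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A data.frame with one row per sequence: `id`, `accepted`,
#'   `reasons` (comma-separated codes from `length_not_multiple_of_3`,
#'   `invalid_characters`, `internal_stop`, or empty), `trailing_stop`
#'   (logical) and `n_ambiguous_codons`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(ok = "ATGTGTTAA", bad = "ATGTA"))
#' validateCds(seqs)
#' @export
validateCds <- function(seqs, mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    seqs <- .asDnaCharacter(seqs)
    ids <- names(seqs)
    res <- lapply(seq_along(seqs), function(i) {
        dna <- seqs[[i]]
        reasons <- character(0)
        trailingStop <- FALSE
        nAmb <- 0L
        if (nchar(dna) == 0L || nchar(dna) %% 3L != 0L) {
            reasons <- c(reasons, "length_not_multiple_of_3")
        } else {
            alphabet <- if (mode == "lenient") "ACGTN" else "ACGT"
            if (grepl(sprintf("[^%s]", alphabet), dna)) {
                reasons <- c(reasons, "invalid_characters")
            } else {
                cod <- .splitCodons(dna)
                nAmb <- sum(grepl("N", cod, fixed = TRUE))
                if (mode == "strict" && nAmb > 0)
                    reasons <- c(reasons, "invalid_characters")
                isStop <- cod %in% .STOP_CODONS
                n <- length(cod)
                trailingStop <- isStop[n]
                if (any(isStop[-n]))
                    reasons <- c(reasons, "internal_stop")
            }
        }
        accepted <- if (mode == "strict") length(reasons) == 0L else TRUE
        data.frame(
            id = ids[i], accepted = accepted,
            reasons = paste(reasons, collapse = ","),
            trailing_stop = trailingStop,
            n_ambiguous_codons = nAmb,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Strip trailing stop codons
#'
#' Removes a single terminal stop codon (TAA/TAG/TGA) from each sequence
#' that has one, so stop codons never enter codon or codon-pair counts.
#'
#' @param seqs A `DNAStringSet` or named character vector of DNA.
#' @return Object of the same kind with trailing stops removed.
#' @export
stripTrailingStops <- function(seqs) {
    ch <- .asDnaCharacter(seqs)
    n <- nchar(ch)
    last <- substring(ch, pmax(n - 2L, 1L), n)
    hasStop <- n >= 3L & n %% 3L == 0L & last %in% .STOP_CODONS
    ch[hasStop] <- substring(ch[hasStop], 1L, n[hasStop] - 3L)
    if (methods::is(seqs, "DNAStringSet")) {
        out <- Biostrings::DNAStringSet(ch)
        names(out) <- names(seqs)
        out
    } else ch
}

#' Translate coding sequences to protein
#'
#' Standard nuclear genetic code translation. A trailing stop codon is
#' stripped first. In `strict` mode a codon containing N (or any internal
#' stop) is an error; in `lenient` mode N-containing codons are skipped
#' and the number skipped is attached as the `"skipped_codons"` attribute.
#'
#' @param seqs A `DNAStringSet`, single DNA string, or named character
#'   vector.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return An [Biostrings::AAStringSet] of translated proteins (names
#'   preserved), with attribute `skipped_codons` in lenient mode.
#' @examples
#' translateCds(Biostrings::DNAStringSet(c(x = "ATGTGTTAA")))
#' @export
translateCds <- function(seqs, mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    ch <- stripTrailingStops(.asDnaCharacter(seqs))
    skipped <- 0L
    aa <- vapply(seq_along(ch), function(i) {
        if (nchar(ch[i]) %% 3L != 0L)
            stop("sequence length not a multiple of 3: ", names(ch)[i])
        cod <- .splitCodons(ch[i])
        amb <- grepl("N", cod, fixed = TRUE)
        if (any(amb)) {
            if (mode == "strict")
                stop("ambiguous codon (contains N) in ", names(ch)[i])
            skipped <<- skipped + sum(amb)
            cod <- cod[!amb]
        }
        res <- .codonToAa[cod]
        if (anyNA(res))
            stop("invalid codon in ", names(ch)[i])
        if (any(res == "*"))
            stop("internal stop codon in ", names(ch)[i])
        paste(res, collapse = "")
    }, character(1))
    out <- Biostrings::AAStringSet(aa)
    names(out) <- names(ch)
    if (mode == "lenient") attr(out, "skipped_codons") <- skipped
    out
}

# coerce sequence containers to a named character vector of DNA
.asDnaCharacter <- function(seqs) {
    if (methods::is(seqs, "XStringSet")) {
        ch <- as.character(seqs)
        if (length(ch) && is.null(names(ch)))
            names(ch) <- paste0("seq", seq_along(ch))
        return(ch)
    }
    if (methods::is(seqs, "XString")) {
        return(setNames(as.character(seqs), "seq1"))
    }
    if (is.character(seqs)) {
        ch <- chartr("uU", "tT", toupper(seqs))
        if (length(ch) && is.null(names(ch)))
            names(ch) <- paste0("seq", seq_along(ch))
        return(ch)
    }
    stop("unsupported sequence container: ", class(seqs)[1])
}

# protein container -> named character
.asProteinCharacter <- function(p) {
    if (methods::is(p, "XStringSet")) {
        ch <- as.character(p)
        if (is.null(names(ch))) names(ch) <- paste0("protein", seq_along(ch))
        return(ch)
    }
    if (methods::is(p, "XString")) return(setNames(as.character(p), "protein1"))
    if (is.character(p)) {
        ch <- toupper(p)
        if (length(ch) && is.null(names(ch)))
            names(ch) <- paste0("protein", seq_along(ch))
        return(ch)
    }
    stop("unsupported protein container: ", class(p)[1])
}
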