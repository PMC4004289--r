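# Codon usage tables and codon-pair context matrices.
#
# The context matrix is conditional on (first codon, second amino acid):
# P(c1, c2) = pairCounts(c1, c2) / sum over c2' synonymous with c2 of
# pairCounts(c1, c2'). This is what makes the ATG and TGG columns
# (single-codon amino acids) identically 1 wherever observed.

#' Count adjacent codon pairs over a set of coding sequences
#'
#' For each sequence of L codons the L - 1 overlapping adjacent pairs are
#' counted; counts are pooled over sequences with equal weight per
#' occurrence, and no pair spans two sequences. Trailing stop codons are
#' stripped first, so stop codons never appear in the counts. In lenient
#' mode codons containing N are skipped along with the two pairs they
#' participate in.
#'
#' @param seqs A `DNAStringSet` or named character vector of valid CDS.
#' @param mode `"strict"` (default) or `"lenient"` (skip N codons).
#' @return A list with `pairCounts` (61 x 61 integer matrix, rows = first
#'   codon), `codonCounts` (named integer vector over the 61 sense
#'   codons), `firstCodonCounts` (codon counts at gene starts, needed for
#'   marginal distributions), `nGenes`, and `skippedCodons`.
#' @examples
#' countCodonPairs(c(g1 = "ATGTGTTGC"))$pairCounts["ATG", "TGT"]
#' @export
countCodonPairs <- function(seqs, mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    ch <- stripTrailingStops(.asDnaCharacter(seqs))
    if (length(ch) == 0L) stop("no sequences")
    codonLists <- lapply(ch, .splitCodons)
    skipped <- 0L
    if (mode == "lenient") {
        codonLists <- lapply(codonLists, function(cod) {
            amb <- grepl("N", cod, fixed = TRUE)
            skipped <<- skipped + sum(amb)
            # mark ambiguous codons NA so pairs touching them are dropped
            cod[amb] <- NA_character_
            cod
        })
    }
    lev <- .SENSE_CODONS
    all1 <- unlist(lapply(codonLists, function(x) x[-length(x)]),
        use.names = FALSE)
    all2 <- unlist(lapply(codonLists, function(x) x[-1L]),
        use.names = FALSE)
    f1 <- factor(all1, levels = lev)
    f2 <- factor(all2, levels = lev)
    pc <- table(f1, f2, useNA = "no")
    pairCounts <- matrix(as.integer(pc), 61L, 61L,
        dimnames = list(lev, lev))
    allCod <- unlist(codonLists, use.names = FALSE)
    codonCounts <- table(factor(allCod, levels = lev))
    firsts <- vapply(codonLists, function(x)
        if (length(x)) x[1L] else NA_character_, character(1))
    firstCodonCounts <- table(factor(firsts, levels = lev))
    list(
        pairCounts = pairCounts,
        codonCounts = setNames(as.integer(codonCounts), lev),
        firstCodonCounts = setNames(as.integer(firstCodonCounts), lev),
        nGenes = length(ch),
        skippedCodons = skipped
    )
}

#' Build a codon usage table from coding sequences
#'
#' Counts codons pooled over all sequences and derives, for each sense
#' codon, its relative frequency within its synonymous group and its
#' occurrences per 1000 sense codons. Trailing stop codons are counted in
#' the stop rows of `counts` but excluded from relative frequencies and
#' per-thousand values, which cover the 61 sense codons only. Unobserved
#' codons have count 0 and relative frequency 0.
#'
#' @inheritParams countCodonPairs
#' @param sourceLabel Provenance label stored with the table.
#' @return A [CodonUsageTable-class] object.
#' @examples
#' t <- buildUsageTable(c(a = "ATGTGT", b = "ATGTGT", c = "ATGTGC"))
#' relFreq(t)[c("TGT", "TGC", "ATG")]
#' @export
buildUsageTable <- function(seqs, sourceLabel = "",
                            mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    ch <- .asDnaCharacter(seqs)
    if (length(ch) == 0L) stop("no sequences")
    # count trailing stops before they are stripped
    n <- nchar(ch)
    last <- substring(ch, pmax(n - 2L, 1L), n)
    trailing <- last[n >= 3L & n %% 3L == 0L & last %in% .STOP_CODONS]
    stopCounts <- table(factor(trailing, levels = .STOP_CODONS))
    cc <- countCodonPairs(ch, mode = mode)
    counts <- c(setNames(as.numeric(cc$codonCounts), .SENSE_CODONS),
        setNames(as.numeric(stopCounts), .STOP_CODONS))
    total <- sum(cc$codonCounts)
    relFreq <- setNames(numeric(61L), .SENSE_CODONS)
    for (a in .AA_LETTERS) {
        grp <- .SYNONYM_GROUPS[[a]]
        s <- sum(cc$codonCounts[grp])
        if (s > 0) relFreq[grp] <- cc$codonCounts[grp] / s
    }
    perThousand <- if (total > 0) 1000 * cc$codonCounts / total else
        setNames(numeric(61L), .SENSE_CODONS)
    new("CodonUsageTable",
        counts = counts, relFreq = relFreq,
        perThousand = setNames(as.numeric(perThousand), .SENSE_CODONS),
        nCodonsTotal = total, sourceLabel = sourceLabel)
}

#' Build a codon context matrix from coding sequences
#'
#' The condition-specific codon-pair model: a 61 x 61 matrix whose entry
#' (c1, c2) is the probability that the second codon of an adjacent pair
#' is c2, given that the first codon is c1 and the second amino acid is
#' the one c2 encodes. Stop codons are excluded (trailing stops stripped
#' beforehand). Contexts (c1, second amino acid) with no observations are
#' all-zero in the probability matrix; no pseudocounts are added, so
#' design-time fallback is an explicit, separate policy.
#'
#' @inheritParams buildUsageTable
#' @return A [CodonContextMatrix-class] object.
#' @examples
#' m <- buildContextMatrix(c(rep("ATGTGT", 3), rep("ATGTGC", 2)))
#' probMatrix(m)["ATG", c("TGT", "TGC")]
#' @export
buildContextMatrix <- function(seqs, sourceLabel = "",
                               mode = c("strict", "lenient")) {
    mode <- match.arg(mode)
    cc <- countCodonPairs(seqs, mode = mode)
    if (sum(cc$pairCounts) == 0L)
        stop("no codon pairs: every sequence has fewer than two codons")
    P <- .normalizePairCounts(cc$pairCounts)
    new("CodonContextMatrix",
        P = P, pairCounts = cc$pairCounts,
        codonCounts = setNames(as.numeric(cc$codonCounts), .SENSE_CODONS),
        nGenes = cc$nGenes, sourceLabel = sourceLabel)
}

# pair counts -> conditional probabilities within (row, synonym group)
.normalizePairCounts <- function(pairCounts) {
    P <- matrix(0, 61L, 61L, dimnames = dimnames(pairCounts))
    for (a in .AA_LETTERS) {
        grp <- .SYNONYM_GROUPS[[a]]
        block <- pairCounts[, grp, drop = FALSE]
        denom <- rowSums(block)
        obs <- denom > 0
        if (any(obs))
            P[obs, grp] <- block[obs, , drop = FALSE] / denom[obs]
    }
    P
}

#' Write a codon context matrix to TSV files
#'
#' Writes the probability matrix as a TSV with codon labels as the first
#' row and column and probabilities at full double precision, preceded by
#' a `#`-metadata line. A companion `<stem>.counts.tsv` file holds the
#' integer pair counts plus the gene-start codon counts (as a metadata
#' line), making [readContextMatrix()] a lossless round trip.
#'
#' @param m A [CodonContextMatrix-class].
#' @param path Output path for the probability matrix (e.g. `m.tsv`).
#' @return `path`, invisibly.
#' @seealso [readContextMatrix()]
#' @export
writeContextMatrix <- function(m, path) {
    stopifnot(methods::is(m, "CodonContextMatrix"))
    .writeLabelledMatrix(
        m@P, path,
        sprintf("# n_genes=%d\tsource_label=%s", as.integer(m@nGenes),
            m@sourceLabel),
        digits = 17)
    first <- .firstCodonCountsOf(m)
    countsPath <- .countsPathFor(path)
    .writeLabelledMatrix(
        m@pairCounts, countsPath,
        c(sprintf("# n_genes=%d\tsource_label=%s", as.integer(m@nGenes),
            m@sourceLabel),
          paste0("# first_codon_counts=",
            paste(sprintf("%s:%d", names(first), as.integer(first)),
                collapse = ","))),
        digits = 17)
    invisible(path)
}

# codonCounts = colSums(pairCounts) + first-codon counts, so store the
# residual to keep the marginal reconstructible from the counts file
.firstCodonCountsOf <- function(m) {
    res <- m@codonCounts - colSums(m@pairCounts)
    res[res < 0] <- 0
    setNames(res, .SENSE_CODONS)
}

.countsPathFor <- function(path) {
    ext <- tools::file_ext(path)
    if (nzchar(ext))
        sub(sprintf("\\.%s$", ext), ".counts.tsv", path)
    else paste0(path, ".counts.tsv")
}

.writeLabelledMatrix <- function(mat, path, metaLines, digits = 17) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(metaLines, con)
    writeLines(paste(c("codon", colnames(mat)), collapse = "\t"), con)
    body <- apply(format(mat, digits = digits, scientific = FALSE,
        trim = TRUE), 1, paste, collapse = "\t")
    writeLines(paste(rownames(mat), body, sep = "\t"), con)
}

#' Read a codon context matrix written by [writeContextMatrix()]
#'
#' @param path Path to the probability-matrix TSV.
#' @return A [CodonContextMatrix-class]. The companion counts file is
#'   read when present; if it is missing the counts are zero and a
#'   warning is raised (design-time marginals then fall back to uniform).
#' @export
readContextMatrix <- function(path) {
    parsed <- .readLabelledMatrix(path)
    P <- parsed$mat
    if (!identical(rownames(P), .SENSE_CODONS) ||
        !identical(colnames(P), .SENSE_CODONS))
        stop("matrix file labels are not the 61 sense codons in canonical order: ",
            path)
    if (any(P < 0) || any(P > 1))
        stop("matrix file contains probabilities outside [0, 1]: ", path)
    meta <- parsed$meta
    nGenes <- if (!is.na(meta["n_genes"])) as.numeric(meta["n_genes"]) else 0
    label <- if (!is.na(meta["source_label"])) meta["source_label"] else ""
    countsPath <- .countsPathFor(path)
    if (file.exists(countsPath)) {
        cparsed <- .readLabelledMatrix(countsPath)
        pairCounts <- cparsed$mat
        fc <- cparsed$meta["first_codon_counts"]
        firstCounts <- setNames(numeric(61L), .SENSE_CODONS)
        if (!is.na(fc)) {
            kv <- strsplit(strsplit(fc, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
            for (p in kv) firstCounts[p[1]] <- as.numeric(p[2])
        }
        codonCounts <- colSums(pairCounts) + firstCounts
    } else {
        warning("counts companion file not found: ", countsPath,
            "; training counts set to zero")
        pairCounts <- matrix(0, 61L, 61L,
            dimnames = list(.SENSE_CODONS, .SENSE_CODONS))
        codonCounts <- setNames(numeric(61L), .SENSE_CODONS)
    }
    new("CodonContextMatrix",
        P = P, pairCounts = pairCounts,
        codonCounts = setNames(as.numeric(codonCounts), .SENSE_CODONS),
        nGenes = nGenes, sourceLabel = unname(label))
}

.readLabelledMatrix <- function(path) {
    lines <- readLines(path)
    metaLines <- grep("^#", lines, value = TRUE)
    meta <- character(0)
    for (ml in metaLines) {
        kv <- strsplit(strsplit(sub("^#\\s*", "", ml), "\t", fixed = TRUE)[[1]],
            "=", fixed = TRUE)
        for (p in kv) if (length(p) == 2) meta[p[1]] <- p[2]
    }
    body <- lines[!grepl("^#", lines)]
    if (length(body) < 2L) stop("matrix file has no body: ", path)
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]][-1]
    rows <- strsplit(body[-1], "\t", fixed = TRUE)
    labels <- vapply(rows, `[`, character(1), 1L)
    vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
        numeric(length(header))))
    if (anyNA(vals)) stop("non-numeric cell in matrix file: ", path)
    dimnames(vals) <- list(labels, header)
    list(mat = vals, meta = meta)
}

#' Write / read a codon usage table as TSV
#'
#' The table has columns `codon`, `aa`, `count`, `rel_freq`,
#' `per_thousand` over all 64 codons (stop rows carry `*` and NA
#' frequencies), preceded by a `#`-metadata line.
#'
#' @param t A [CodonUsageTable-class].
#' @param path File path.
#' @return `writeUsageTable` returns `path` invisibly; `readUsageTable`
#'   returns a [CodonUsageTable-class].
#' @export
writeUsageTable <- function(t, path) {
    stopifnot(methods::is(t, "CodonUsageTable"))
    allCodons <- c(.SENSE_CODONS, .STOP_CODONS)
    df <- data.frame(
        codon = allCodons,
        aa = .codonToAa[allCodons],
        count = as.integer(t@counts[allCodons]),
        rel_freq = c(t@relFreq, setNames(rep(NA_real_, 3), .STOP_CODONS))[allCodons],
        per_thousand = c(t@perThousand,
            setNames(rep(NA_real_, 3), .STOP_CODONS))[allCodons],
        stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# n_codons_total=%d\tsource_label=%s",
        as.integer(t@nCodonsTotal), t@sourceLabel), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    writeLines(do.call(paste, c(lapply(df, function(x)
        format(x, digits = 17, scientific = FALSE, trim = TRUE)),
        sep = "\t")), con)
    invisible(path)
}

#' @rdname writeUsageTable
#' @export
readUsageTable <- function(path) {
    lines <- readLines(path)
    meta <- character(0)
    for (ml in grep("^#", lines, value = TRUE)) {
        kv <- strsplit(strsplit(sub("^#\\s*", "", ml), "\t", fixed = TRUE)[[1]],
            "=", fixed = TRUE)
        for (p in kv) if (length(p) == 2) meta[p[1]] <- p[2]
    }
    df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
        sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
    if (!all(c("codon", "count", "rel_freq", "per_thousand") %in% names(df)))
        stop("usage-table file missing required columns: ", path)
    counts <- setNames(as.numeric(df$count), df$codon)
    allCodons <- c(.SENSE_CODONS, .STOP_CODONS)
    if (!all(allCodons %in% names(counts)))
        stop("usage-table file does not cover all 64 codons: ", path)
    relFreq <- setNames(df$rel_freq, df$codon)[.SENSE_CODONS]
    relFreq[is.na(relFreq)] <- 0
    perThousand <- setNames(df$per_thousand, df$codon)[.SENSE_CODONS]
    perThousand[is.na(perThousand)] <- 0
    new("CodonUsageTable",
        counts = counts[allCodons],
        relFreq = setNames(as.numeric(relFreq), .SENSE_CODONS),
        perThousand = setNames(as.numeric(perThousand), .SENSE_CODONS),
        nCodonsTotal = if (!is.na(meta["n_codons_total"]))
            as.numeric(meta["n_codons_total"]) else sum(counts[.SENSE_CODONS]),
        sourceLabel = if (!is.na(meta["source_label"]))
            unname(meta["source_label"]) else "")
}
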