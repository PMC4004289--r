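# Selection of condition-specific gene sets from expression summaries.
# Upstream microarray/RNA-seq preprocessing (normalization, linear-model
# fitting) is out of scope: this module consumes its summary table.

#' Read an expression summary table
#'
#' Reads a TSV with a header line. Two layouts are supported:
#' `gene_id`, `value` (absolute expression) or `gene_id`, `logfc`,
#' `adj_p` (differential-expression summary); a table may carry all four
#' columns. Gene ids must be unique.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the recognised columns.
#' @export
readExpressionTable <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
        stringsAsFactors = FALSE, quote = "")
    if (!"gene_id" %in% names(df))
        stop("expression table must have a gene_id column: ", path)
    if (anyDuplicated(df$gene_id))
        stop("duplicate gene ids in expression table: ", path)
    if (!("value" %in% names(df)) &&
        !all(c("logfc", "adj_p") %in% names(df)))
        stop("expression table needs either a value column or logfc + adj_p: ",
            path)
    if ("adj_p" %in% names(df) &&
        any(df$adj_p < 0 | df$adj_p > 1, na.rm = TRUE))
        stop("adj_p outside [0, 1] in ", path)
    df
}

#' Select the n most highly expressed genes
#'
#' Ranks by expression `value`, descending; ties are broken by ascending
#' gene id so the selection is deterministic and independent of row
#' order. This is the selector behind condition models built from e.g.
#' the 100 most highly expressed genes of a growth condition.
#'
#' @param table data.frame with columns `gene_id` and `value`.
#' @param n Number of genes to select (positive).
#' @return Character vector of n gene ids, most expressed first.
#' @examples
#' tbl <- data.frame(gene_id = c("a", "b", "c"), value = c(5, 9, 1))
#' selectTopExpressed(tbl, 2)
#' @export
selectTopExpressed <- function(table, n) {
    if (!all(c("gene_id", "value") %in% names(table)))
        stop("table must have gene_id and value columns")
    if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
        stop("n must be a positive integer")
    ok <- !is.na(table$value)
    if (n > sum(ok))
        stop(sprintf("requested n = %d genes but the table has only %d with a value",
            as.integer(n), sum(ok)))
    tbl <- table[ok, ]
    ord <- order(-tbl$value, tbl$gene_id)
    tbl$gene_id[ord][seq_len(n)]
}

#' Select differentially expressed genes
#'
#' Applies the conventional differential-expression thresholds: adjusted
#' p-value strictly below `adjPMax` and log-fold change strictly above
#' `absLogfcMin` (up), strictly below `-absLogfcMin` (down), or either
#' (both). Survivors are ranked by decreasing absolute log-fold change
#' (ties by ascending gene id) and optionally truncated to the top `n` —
#' e.g. the 50 genes most differentially upregulated in stationary phase.
#'
#' @param table data.frame with columns `gene_id`, `logfc`, `adj_p`.
#' @param adjPMax Adjusted p-value threshold (default 0.05, strict).
#' @param absLogfcMin Log-fold-change magnitude threshold (default 1,
#'   strict).
#' @param direction `"up"` (default), `"down"`, or `"both"`.
#' @param n Optional cap on the number of genes returned.
#' @return Character vector of gene ids (possibly empty, with a warning
#'   when no gene survives the filter).
#' @examples
#' tbl <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   logfc = c(2, 0.5, 3), adj_p = c(0.01, 0.001, 0.2))
#' selectDifferential(tbl)
#' @export
selectDifferential <- function(table, adjPMax = 0.05, absLogfcMin = 1,
                               direction = c("up", "down", "both"),
                               n = NULL) {
    direction <- match.arg(direction)
    if (!all(c("gene_id", "logfc", "adj_p") %in% names(table)))
        stop("table must have gene_id, logfc and adj_p columns")
    keep <- !is.na(table$adj_p) & !is.na(table$logfc) &
        table$adj_p < adjPMax &
        switch(direction,
            up = table$logfc > absLogfcMin,
            down = table$logfc < -absLogfcMin,
            both = abs(table$logfc) > absLogfcMin)
    tbl <- table[keep, ]
    if (nrow(tbl) == 0L) {
        warning("no genes pass the differential-expression filter")
        return(character(0))
    }
    ord <- order(-abs(tbl$logfc), tbl$gene_id)
    ids <- tbl$gene_id[ord]
    if (!is.null(n)) {
        if (n < 1 || n != round(n)) stop("n must be a positive integer")
        ids <- head(ids, n)
    }
    ids
}

#' Fetch coding sequences for a gene-id list
#'
#' Joins a selected gene-id list with a genome's coding sequences,
#' preserving the list order. Unmatched ids are reported via a warning
#' and stored in `metadata(result)$unmatched`.
#'
#' @param geneIds Character vector of gene ids (non-empty).
#' @param genome A named `DNAStringSet` (or named character vector).
#' @return A `DNAStringSet` of the matched sequences, in `geneIds` order.
#' @export
fetchSequences <- function(geneIds, genome) {
    if (length(geneIds) == 0L) stop("empty gene-id list")
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(.asDnaCharacter(genome))
    if (is.null(names(genome)))
        stop("genome sequences must be named")
    found <- geneIds %in% names(genome)
    if (!any(found))
        stop("none of the ", length(geneIds),
            " requested gene ids match the genome")
    res <- genome[geneIds[found]]
    unmatched <- geneIds[!found]
    if (length(unmatched))
        warning(length(unmatched), " gene id(s) not found in genome: ",
            paste(head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ..." else "")
    S4Vectors::metadata(res)$unmatched <- unmatched
    res
}
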