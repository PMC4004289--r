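# Codon-usage drift between context matrices: Frobenius norms of matrix
# differences, pairwise drift tables, and the random-subsampling drift
# experiment with power-law regression.

#' Frobenius drift between two codon context matrices
#'
#' The drift between two conditions is the Frobenius norm of the
#' entrywise difference of their 61 x 61 probability matrices,
#' ||A - B||_F = sqrt(sum((A - B)^2)), with stop codons already excluded
#' from both matrices. Identical matrices have drift zero; a smaller
#' value means more similar codon-pair usage.
#'
#' @param A,B [CodonContextMatrix-class] objects sharing the canonical
#'   61-codon labels.
#' @return A single non-negative number.
#' @examples
#' m <- buildContextMatrix(c(rep("ATGTGT", 3), rep("ATGTGC", 2)))
#' frobeniusDrift(m, m)
#' @export
frobeniusDrift <- function(A, B) {
    stopifnot(methods::is(A, "CodonContextMatrix"),
        methods::is(B, "CodonContextMatrix"))
    if (!identical(dimnames(A@P), dimnames(B@P)))
        stop("matrices do not share the canonical codon labels")
    sqrt(sum((A@P - B@P)^2))
}

#' Pairwise drift table for a set of context matrices
#'
#' Computes [frobeniusDrift()] for every pair in a named collection of
#' matrices (e.g. a control matrix plus one matrix per transcription
#' factor or condition) and returns the symmetric drift table with zero
#' diagonal.
#'
#' @param matrices Named list of at least two
#'   [CodonContextMatrix-class] objects.
#' @return A symmetric numeric matrix of drift values with the list
#'   names as dimnames.
#' @export
pairwiseDrift <- function(matrices) {
    if (!is.list(matrices) || length(matrices) < 2L)
        stop("need at least 2 matrices")
    nm <- names(matrices)
    if (is.null(nm) || any(!nzchar(nm)))
        nm <- paste0("matrix", seq_along(matrices))
    k <- length(matrices)
    out <- matrix(0, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
            d <- frobeniusDrift(matrices[[i]], matrices[[j]])
            out[i, j] <- d
            out[j, i] <- d
        }
    }
    out
}

#' Random-subsampling drift experiment
#'
#' For each subsample size, draws `replicates` independent
#' without-replacement gene samples from the genome, builds a context
#' matrix per sample, and records the mean and sample standard deviation
#' of the Frobenius drift to a reference matrix. The mean drift is then
#' fitted with a power regression y = A * x^b ([fitPowerLaw()]). As more
#' genes enter a subsample its matrix averages towards the reference
#' built from the whole set, so drift decreases with size and the fitted
#' exponent is negative.
#'
#' @param genome A named `DNAStringSet` (or character vector) of valid
#'   CDS.
#' @param reference A [CodonContextMatrix-class] to measure drift
#'   against (typically built from the whole genome).
#' @param sizes Integer vector of genes per subsample; all must be at
#'   most the genome size. Default `c(30, 50, 100, 150, 200, 250, 300)`.
#' @param replicates Independent subsamples per size (default 5).
#' @param seed Integer RNG seed.
#' @return A [DriftCurve-class] object.
#' @export
subsampleDrift <- function(genome, reference,
                           sizes = c(30L, 50L, 100L, 150L, 200L, 250L, 300L),
                           replicates = 5L, seed = 1L) {
    stopifnot(methods::is(reference, "CodonContextMatrix"))
    ch <- .asDnaCharacter(genome)
    nGenome <- length(ch)
    if (any(sizes < 1) || any(sizes != round(sizes)))
        stop("sizes must be positive integers")
    if (max(sizes) > nGenome)
        stop(sprintf("largest subsample size (%d) exceeds genome size (%d)",
            max(sizes), nGenome))
    if (replicates < 1) stop("replicates must be >= 1")
    set.seed(seed)
    rows <- lapply(sizes, function(sz) {
        norms <- vapply(seq_len(replicates), function(r) {
            idx <- sample.int(nGenome, sz)
            sub <- buildContextMatrix(ch[idx],
                sourceLabel = sprintf("subsample_%d_%d", sz, r))
            frobeniusDrift(sub, reference)
        }, numeric(1))
        data.frame(size = sz, replicates = replicates,
            mean_norm = mean(norms),
            sd_norm = if (replicates > 1) stats::sd(norms) else 0)
    })
    curve <- do.call(rbind, rows)
    fitA <- NA_real_
    fitB <- NA_real_
    ok <- curve$mean_norm > 0
    if (length(unique(curve$size[ok])) >= 2L) {
        fit <- fitPowerLaw(curve$size[ok], curve$mean_norm[ok])
        fitA <- fit$A
        fitB <- fit$b
    }
    new("DriftCurve", curve = curve, fitA = fitA, fitB = fitB,
        seed = as.numeric(seed))
}

#' Fit a power law y = A * x^b
#'
#' Ordinary least squares on log10(y) versus log10(x): the exponent b is
#' the slope and A = 10^intercept. Exact data of the form y = A * x^b are
#' recovered exactly; two points are interpolated exactly.
#'
#' @param x,y Positive numeric vectors of equal length (>= 2 points).
#' @return A list with `A`, `b`, `seA` and `seB` (standard errors on the
#'   log10 scale for the intercept and slope; NA with only two points),
#'   and the underlying `fit` (an `lm` object).
#' @examples
#' fitPowerLaw(c(1, 10, 100), 2 * c(1, 10, 100)^-0.5)[c("A", "b")]
#' @export
fitPowerLaw <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 2L) stop("need at least 2 points")
    if (any(x <= 0) || any(y <= 0))
        stop("power-law fit requires strictly positive x and y")
    fit <- stats::lm(ly ~ lx, data = data.frame(lx = log10(x), ly = log10(y)))
    cf <- coef(fit)
    # on noiseless data the residual variance is ~0 and R warns that the
    # fit is "essentially perfect"; the coefficients are still exact
    se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
        error = function(e) c(NA_real_, NA_real_))
    list(A = unname(10^cf[1]), b = unname(cf[2]),
        seA = unname(se[1]), seB = unname(se[2]), fit = fit)
}

#' Write a drift curve to TSV (+ JSON fit sidecar)
#'
#' Writes the size/mean/sd table as TSV and, alongside it, a small JSON
#' file `<stem>.fit.json` with the power-law coefficients and the seed.
#'
#' @param dc A [DriftCurve-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeDriftCurve <- function(dc, path) {
    stopifnot(methods::is(dc, "DriftCurve"))
    write.table(dc@curve, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    side <- sub("\\.[^.]*$", "", path)
    jsonlite::write_json(
        list(fit_A = dc@fitA, fit_b = dc@fitB, seed = dc@seed),
        paste0(side, ".fit.json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}
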