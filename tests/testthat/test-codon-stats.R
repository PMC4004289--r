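test_that("adjacent codon pairs are counted within genes only", {
    one <- countCodonPairs(c(g = "ATGTGT"))
    expect_identical(sum(one$pairCounts), 1L)
    expect_identical(one$pairCounts["ATG", "TGT"], 1L)

    two <- countCodonPairs(c(g = "ATGTGTTGC"))
    expect_identical(two$pairCounts["ATG", "TGT"], 1L)
    expect_identical(two$pairCounts["TGT", "TGC"], 1L)
    expect_identical(sum(two$pairCounts), 2L)
    expect_identical(two$codonCounts[c("ATG", "TGT", "TGC")],
        c(ATG = 1L, TGT = 1L, TGC = 1L))

    # a single-codon gene contributes no pair; no pair spans two genes
    single <- countCodonPairs(c(g = "ATG"))
    expect_identical(sum(single$pairCounts), 0L)
    expect_identical(sum(single$codonCounts), 1L)
    pairTwoGenes <- countCodonPairs(c(a = "ATG", b = "TGT"))
    expect_identical(sum(pairTwoGenes$pairCounts), 0L)

    expect_error(countCodonPairs(character(0)), "no sequences")
})

test_that("trailing stops are stripped before counting, N codons skipped in lenient mode", {
    cc <- countCodonPairs(c(g = "ATGTGTTAA"))
    expect_identical(sum(cc$pairCounts), 1L)
    expect_identical(sum(cc$codonCounts), 2L)

    # N codon drops itself and both pairs it takes part in
    len <- countCodonPairs(c(g = "ATGNNNTGT"), mode = "lenient")
    expect_identical(sum(len$pairCounts), 0L)
    expect_identical(sum(len$codonCounts), 2L)
    expect_identical(len$skippedCodons, 1L)
})

test_that("usage tables normalise within synonymous groups", {
    t <- buildUsageTable(c(a = "ATGTGT", b = "ATGTGT", c = "ATGTGC"),
        sourceLabel = "toy")
    expect_equal(unname(relFreq(t)["TGT"]), 2 / 3)
    expect_equal(unname(relFreq(t)["TGC"]), 1 / 3)
    expect_equal(unname(relFreq(t)["ATG"]), 1)
    expect_equal(sum(perThousand(t)), 1000)
    expect_identical(nCodons(t), 6L)

    # single-gene "ATG": the only codon is 1000 per thousand
    t1 <- buildUsageTable(c(g = "ATG"))
    expect_equal(unname(perThousand(t1)["ATG"]), 1000)

    # trailing stops land in the 64-codon counts but not the frequencies
    t2 <- buildUsageTable(c(g = "ATGTGTTAA"))
    expect_equal(unname(codonCounts(t2)["TAA"]), 1)
    expect_equal(sum(perThousand(t2)), 1000)
})

test_that("the context matrix conditions on (first codon, second amino acid)", {
    m <- metCysMatrix()
    P <- probMatrix(m)
    expect_identical(dim(P), c(61L, 61L))
    expect_identical(rownames(P), senseCodons())
    expect_false(any(stopCodons() %in% colnames(P)))
    expect_equal(unname(P["ATG", "TGT"]), 0.6)
    expect_equal(unname(P["ATG", "TGC"]), 0.4)
    expect_identical(nGenes(m), 5L)
    # Met column carries probability 1 wherever its context was observed
    mm <- buildContextMatrix(c(g = "TGTATGTGG"))
    expect_equal(unname(probMatrix(mm)["TGT", "ATG"]), 1)
    expect_equal(unname(probMatrix(mm)["ATG", "TGG"]), 1)

    expect_error(buildContextMatrix(c(a = "ATG", b = "TGT")), "pair")
})

test_that("every observed (first codon, second aa) group sums to one", {
    gen <- randomContextMatrix(5)
    genome <- sampleGenome(40, c(10, 60), gen, seed = 6)
    m <- buildContextMatrix(genome)
    P <- probMatrix(m)
    for (a in names(synonymGroups())) {
        s <- rowSums(P[, synonymGroups(a), drop = FALSE])
        expect_true(all(abs(s - 1) < 1e-9 | s == 0))
    }
})

test_that("pair counts are consistent with non-initial codon counts", {
    gen <- randomContextMatrix(7)
    genome <- sampleGenome(30, c(5, 40), gen, seed = 8)
    cc <- countCodonPairs(genome)
    expect_identical(colSums(cc$pairCounts) + cc$firstCodonCounts,
        setNames(as.numeric(cc$codonCounts), senseCodons()))
})

test_that("tables and matrices are invariant to gene order", {
    gen <- randomContextMatrix(9)
    genome <- as.character(sampleGenome(25, 20, gen, seed = 10))
    set.seed(1)
    shuffled <- genome[sample(length(genome))]
    expect_equal(probMatrix(buildContextMatrix(genome)),
        probMatrix(buildContextMatrix(shuffled)))
    expect_equal(relFreq(buildUsageTable(genome)),
        relFreq(buildUsageTable(shuffled)))
})

test_that("matrix files round trip losslessly and reject malformed input", {
    gen <- randomContextMatrix(13)
    genome <- sampleGenome(20, 30, gen, seed = 14)
    m <- buildContextMatrix(genome, sourceLabel = "round-trip")
    path <- file.path(tempdir(), "rt.tsv")
    writeContextMatrix(m, path)
    back <- readContextMatrix(path)
    expect_equal(probMatrix(back), probMatrix(m), tolerance = 1e-12)
    expect_equal(pairCounts(back), pairCounts(m))
    expect_equal(codonCounts(back), codonCounts(m))
    expect_identical(sourceLabel(back), "round-trip")
    expect_equal(nGenes(back), 20)

    # a label that is not a sense codon -> format error
    lines <- readLines(path)
    bad <- tempfile(fileext = ".tsv")
    writeLines(sub("^TTT\t", "XXX\t", sub("\tTTT\t", "\tXXX\t", lines)), bad)
    expect_error(readContextMatrix(bad), "61 sense codons")

    # a negative probability -> format error
    bad2 <- tempfile(fileext = ".tsv")
    lines2 <- sub("^AAA\t[0-9.eE+-]+", "AAA\t-0.5", lines)
    writeLines(lines2, bad2)
    expect_error(readContextMatrix(bad2), "outside")
})

test_that("usage-table files round trip", {
    t <- buildUsageTable(metCysSeqs(), sourceLabel = "toy")
    path <- tempfile(fileext = ".tsv")
    writeUsageTable(t, path)
    back <- readUsageTable(path)
    expect_equal(relFreq(back), relFreq(t), tolerance = 1e-12)
    expect_equal(codonCounts(back), codonCounts(t))
    expect_identical(sourceLabel(back), "toy")
})

test_that("rebuilt matrices converge to the generator as the corpus grows", {
    gen <- randomContextMatrix(21, concentration = 0.3)
    errStats <- function(nGenes, seed) {
        genome <- sampleGenome(nGenes, 300, gen, seed = seed)
        m <- buildContextMatrix(genome)
        pc <- pairCounts(m)
        errs <- numeric(0)
        for (a in names(synonymGroups())) {
            grp <- synonymGroups(a)
            n <- rowSums(pc[, grp, drop = FALSE])
            sel <- n >= 200
            if (any(sel))
                errs <- c(errs, abs(probMatrix(m)[sel, grp, drop = FALSE] -
                    probMatrix(gen)[sel, grp, drop = FALSE]))
        }
        errs
    }
    big <- errStats(500, seed = 22)
    expect_gt(length(big), 100)
    # well-observed contexts are estimated closely on average
    expect_lt(mean(big), 0.03)
    # and the error shrinks as the corpus grows
    small <- errStats(50, seed = 23)
    smallAll <- abs(probMatrix(buildContextMatrix(
        sampleGenome(50, 300, gen, seed = 23))) - probMatrix(gen))
    bigAll <- abs(probMatrix(buildContextMatrix(
        sampleGenome(500, 300, gen, seed = 22))) - probMatrix(gen))
    expect_lt(mean(bigAll), mean(smallAll))
})
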