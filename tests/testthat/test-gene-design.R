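test_that("single-codon amino acids are rendered identically for every seed", {
    m <- metCysMatrix()
    for (s in c(1L, 17L, 999L)) {
        d <- designProbabilistic("MW", m, seed = s)
        expect_identical(designedDNA(d), "ATGTGG")
    }
})

test_that("the same (protein, matrix, seed) gives byte-identical designs", {
    gen <- randomContextMatrix(31)
    p <- randomProtein(40, seed = 32)
    d1 <- designProbabilistic(p, gen, seed = 7)
    d2 <- designProbabilistic(p, gen, seed = 7)
    expect_identical(designedDNA(d1), designedDNA(d2))
    expect_identical(rngSeed(d1), 7)
    # variants derive seeds seed, seed+1, ... and n = 1 matches the
    # single-design entry point
    v <- designVariants(p, gen, n = 3, seed = 7)
    expect_identical(designedDNA(v[[1]]), designedDNA(d1))
    expect_identical(vapply(v, rngSeed, numeric(1)), c(7, 8, 9))
})

test_that("designs translate back to their protein for every method and seed", {
    gen <- randomContextMatrix(33)
    genome <- sampleGenome(100, 100, gen, seed = 34)
    tab <- buildUsageTable(genome)
    set.seed(35)
    for (i in 1:25) {
        p <- randomProtein(sample(1:60, 1), seed = 3500 + i)
        aa <- as.character(p)[[1]]
        dp <- designProbabilistic(p, gen, seed = sample.int(1e6, 1))
        expect_identical(as.character(translateCds(designedDNA(dp)))[[1]], aa)
        dt <- designTable(p, tab)
        expect_identical(as.character(translateCds(designedDNA(dt)))[[1]], aa)
    }
})

test_that("table-based design picks the most frequent codon, ties alphabetical", {
    t <- buildUsageTable(c(a = "ATGTGT", b = "ATGTGT", c = "ATGTGC"))
    expect_identical(designedDNA(designTable("MC", t)), "ATGTGT")
    tw <- buildUsageTable(c(a = "ATGTGG"))
    expect_identical(designedDNA(designTable("MW", tw)), "ATGTGG")
    # TGT and TGC tie -> TGC (alphabetically smallest)
    tie <- buildUsageTable(c(a = "ATGTGTTGC"))
    expect_identical(designedDNA(designTable("MC", tie)), "ATGTGC")
    expect_error(designTable("MCH", t), "H")
})

test_that("table designs never use a codon outranked by a synonym", {
    gen <- randomContextMatrix(36)
    genome <- sampleGenome(60, 80, gen, seed = 37)
    t <- buildUsageTable(genome)
    d <- designTable(randomProtein(80, seed = 38), t)
    cod <- substring(designedDNA(d), seq(1, nchar(designedDNA(d)), 3),
        seq(3, nchar(designedDNA(d)), 3))
    for (c2 in unique(cod)) {
        aa <- geneticCode()$codonToAa[[c2]]
        expect_gte(relFreq(t)[c2], max(relFreq(t)[synonymGroups(aa)]))
    }
})

test_that("unseen contexts fall back to the marginal and are counted", {
    # trained only on Met-Cys pairs: context (TGT, Cys) is unseen
    m <- metCysMatrix()
    d <- designProbabilistic("MCC", m, seed = 5)
    expect_identical(as.character(translateCds(designedDNA(d)))[[1]], "MCC")
    expect_identical(fallbackEvents(d), 1)
    # an amino acid never observed at all: uniform over its group
    d2 <- designProbabilistic("MH", m, seed = 6)
    expect_identical(as.character(translateCds(designedDNA(d2)))[[1]], "MH")
    expect_identical(fallbackEvents(d2), 1)
})

test_that("empirical pair frequencies approach the model as designs accumulate", {
    gen <- randomContextMatrix(39)
    p <- randomProtein(30, seed = 40)
    audit <- function(n) {
        a <- pairFrequencyAudit(designVariants(p, gen, n = n, seed = 41), gen)
        # restrict to well-observed contexts of the designs
        max(a$abs_dev[a$n_context >= n / 2])
    }
    small <- audit(100)
    large <- audit(2000)
    expect_lt(large, small)
    expect_lt(large, 0.1)

    # a table design concentrates each used context on one codon
    t <- buildUsageTable(sampleGenome(60, 80, gen, seed = 42))
    aud <- pairFrequencyAudit(designTable(p, t), gen)
    byCtx <- split(aud$empirical_p, paste(aud$first_codon, aud$second_aa))
    expect_true(all(vapply(byCtx, max, numeric(1)) == 1))

    # no codon pairs at all -> empty audit
    empty <- pairFrequencyAudit(designProbabilistic("M", gen, seed = 1), gen)
    expect_identical(nrow(empty), 0L)
})

test_that("design FASTA headers record the method, seed and fallbacks", {
    m <- metCysMatrix()
    path <- tempfile(fileext = ".fasta")
    writeDesigns(designVariants("MC", m, n = 2, seed = 3), path)
    lines <- readLines(path)
    headers <- grep("^>", lines, value = TRUE)
    expect_length(headers, 2L)
    expect_match(headers[1], "method=matrix_probabilistic")
    expect_match(headers[1], "seed=3")
    expect_match(headers[2], "seed=4")
    expect_match(headers[1], "fallback_events=0")
})
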