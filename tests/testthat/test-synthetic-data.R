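test_that("synthetic generators are valid, skewed, and reproducible", {
    g1 <- randomContextMatrix(71)
    g2 <- randomContextMatrix(71)
    expect_identical(probMatrix(g1), probMatrix(g2))
    expect_true(all(probMatrix(g1) >= 0 & probMatrix(g1) <= 1))
    # every context is observed (fully specified generator)
    for (a in names(synonymGroups())) {
        s <- rowSums(probMatrix(g1)[, synonymGroups(a), drop = FALSE])
        expect_true(all(abs(s - 1) < 1e-9))
    }
    expect_error(randomContextMatrix(1, concentration = 0), "positive")
})

test_that("sampled genomes are reproducible, well-formed and recover the generator", {
    gen <- randomContextMatrix(72)
    one <- sampleGenome(1, 2, gen, seed = 73)
    expect_identical(Biostrings::width(one), 6L)
    expect_identical(names(one), "g000001")

    a <- sampleGenome(10, c(3, 9), gen, seed = 74)
    b <- sampleGenome(10, c(3, 9), gen, seed = 74)
    expect_identical(as.character(a), as.character(b))
    expect_true(all(validateCds(a)$accepted))

    expect_error(sampleGenome(0, 5, gen, seed = 1), "positive")
    expect_error(sampleGenome(5, 1, gen, seed = 1), ">= 2")
    expect_error(sampleGenome(5, 5, gen, seed = 1, biasFraction = 0.5),
        "biasGenerator")
})

test_that("bias mixtures flag a subset with genuinely different codon usage", {
    gen <- randomContextMatrix(75)
    biasGen <- randomContextMatrix(76)
    genome <- sampleGenome(200, 80, gen, seed = 77,
        biasGenerator = biasGen, biasFraction = 0.25)
    biased <- S4Vectors::mcols(genome)$biased
    expect_identical(sum(biased), 50L)
    mBias <- buildContextMatrix(genome[biased])
    mRest <- buildContextMatrix(genome[!biased])
    mAll <- buildContextMatrix(genome)
    # biased genes drift further from the pooled matrix than the bulk
    expect_gt(frobeniusDrift(mBias, mAll), frobeniusDrift(mRest, mAll))
})

test_that("synthetic expression tables separate biased genes and are reproducible", {
    ids <- sprintf("g%04d", 1:1000)
    biased <- ids[1:100]
    recovered <- vapply(1:5, function(s) {
        tbl <- sampleExpressionTable(ids, biased, seed = 80 + s)
        top <- selectTopExpressed(tbl, 100)
        sum(top %in% biased)
    }, numeric(1))
    expect_gte(median(recovered), 80)

    tbl <- sampleExpressionTable(ids, biased, seed = 81)
    expect_identical(tbl, sampleExpressionTable(ids, biased, seed = 81))
    expect_true(all(tbl$adj_p >= 0 & tbl$adj_p <= 1))
    # biased genes are also recovered through the differential filter
    de <- selectDifferential(tbl, n = 50)
    expect_gte(mean(de %in% biased), 0.9)

    # with no biased genes the top-N is just a random draw
    plain <- sampleExpressionTable(ids, character(0), seed = 82)
    expect_identical(sort(unique(plain$gene_id)), sort(ids))
    expect_error(sampleExpressionTable(ids, "not-a-gene", seed = 1),
        "subset")
})

test_that("random proteins start with Met and are reproducible", {
    expect_identical(as.character(randomProtein(1, seed = 90))[[1]], "M")
    p <- randomProtein(251, seed = 91)
    expect_identical(Biostrings::width(p), 251L)
    expect_identical(substr(as.character(p)[[1]], 1, 1), "M")
    expect_identical(as.character(randomProtein(40, seed = 92)),
        as.character(randomProtein(40, seed = 92)))
    expect_error(randomProtein(0, seed = 1), "positive")
})

test_that("the whole pipeline runs end to end on synthetic data", {
    gen <- randomContextMatrix(95)
    biasGen <- randomContextMatrix(96)
    genome <- sampleGenome(300, c(40, 120), gen, seed = 97,
        biasGenerator = biasGen, biasFraction = 0.2)
    biasedIds <- names(genome)[S4Vectors::mcols(genome)$biased]
    expr <- sampleExpressionTable(names(genome), biasedIds, seed = 98)
    top <- selectTopExpressed(expr, 60)
    condSeqs <- fetchSequences(top, genome)
    condMatrix <- buildContextMatrix(condSeqs, sourceLabel = "condition")
    control <- buildContextMatrix(genome, sourceLabel = "control")
    p <- randomProtein(60, seed = 99)
    designs <- designVariants(p, condMatrix, n = 3, seed = 100)
    for (d in designs)
        expect_identical(as.character(translateCds(designedDNA(d)))[[1]],
            as.character(p)[[1]])
    # condition matrix (biased-gene dominated) drifts further from the
    # control than equal-size random subsets do on average
    dc <- subsampleDrift(genome, control, sizes = 60L, replicates = 5L,
        seed = 101)
    expect_gt(frobeniusDrift(condMatrix, control),
        driftTable(dc)$mean_norm[1])
})
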