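# Shared fixtures, all built in code.

# five genes whose only variable context is (ATG, Cys): 60% TGT, 40% TGC
metCysSeqs <- function() {
    c(g1 = "ATGTGT", g2 = "ATGTGT", g3 = "ATGTGT",
      g4 = "ATGTGC", g5 = "ATGTGC")
}

metCysMatrix <- function() {
    buildContextMatrix(metCysSeqs(), sourceLabel = "met-cys-60-40")
}

# independent brute-force Frobenius norm: explicit double loop
bruteForceFrobenius <- function(A, B) {
    PA <- probMatrix(A)
    PB <- probMatrix(B)
    acc <- 0
    for (i in seq_len(nrow(PA))) {
        for (j in seq_len(ncol(PA))) {
            acc <- acc + (PA[i, j] - PB[i, j])^2
        }
    }
    sqrt(acc)
}

writeTempFasta <- function(lines) {
    path <- tempfile(fileext = ".fasta")
    writeLines(lines, path)
    path
}
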