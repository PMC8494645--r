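# shared small fixtures, built in code

# a small codebook reused across decoding tests
smallCodebook <- function(nGenes = 20, nBlanks = 4, seed = 7) {
    buildCodebook(16, 4, 4, genes = nGenes, nBlanks = nBlanks, seed = seed)
}

# a compact synthetic atlas (cached per session; generation is seeded)
.atlasCache <- new.env()
cachedAtlas <- function(nCells = 6000, seed = 1) {
    key <- paste0("a", nCells, "_", seed)
    if (is.null(.atlasCache[[key]]))
        .atlasCache[[key]] <- generateAtlas(
            atlasConfig(nCells = nCells, seed = seed))
    .atlasCache[[key]]
}

atlasTruth <- function(sce) S4Vectors::metadata(sce)$truth

# adjusted Rand index (independent implementation for recovery checks)
ari <- function(a, b) {
    t <- table(a, b)
    s <- sum(choose(t, 2))
    ra <- sum(choose(rowSums(t), 2))
    cb <- sum(choose(colSums(t), 2))
    n <- choose(sum(t), 2)
    (s - ra * cb / n) / ((ra + cb) / 2 - ra * cb / n)
}
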