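#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards. Every stochastic step in the package routes its
#' randomness through this helper so results are reproducible from the seed
#' alone.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Principal components of a cells x features matrix via the feature
# covariance eigendecomposition (features << cells throughout this package).
# Returns scores (cells x npc) and eigenvalues of all components.
.pca <- function(x, npc = NULL) {
    x <- sweep(x, 2, colMeans(x))
    cv <- crossprod(x) / (nrow(x) - 1)
    e <- eigen(cv, symmetric = TRUE)
    vals <- pmax(e$values, 0)
    if (is.null(npc)) npc <- ncol(x)
    npc <- min(npc, ncol(x))
    list(scores = x %*% e$vectors[, seq_len(npc), drop = FALSE],
         values = vals)
}

# top eigenvalue only (used by the shuffle calibration)
.topEigenvalue <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    cv <- crossprod(x) / (nrow(x) - 1)
    max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
}

# kNN indices (excluding self) in a cells x dims embedding
.knnIndex <- function(emb, k) {
    BiocNeighbors::findKNN(emb, k = k, get.distance = FALSE)$index
}

# undirected kNN graph as an igraph object
.knnGraph <- function(emb, k) {
    idx <- .knnIndex(emb, k)
    edges <- cbind(rep(seq_len(nrow(idx)), ncol(idx)), as.vector(idx))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::simplify(g)
}

# z-score columns; zero-variance columns map to 0
.zscore <- function(x) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0] <- Inf
    sweep(sweep(x, 2, mu), 2, sd, "/")
}
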