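# Shared fixtures, built in code.

# small abundance table with known cells
makeToyTable <- function() {
    bm <- matrix(c(2, 6, 0,
                   1, 0, 3,
                   0.5, 1.5, 2), nrow = 3, byrow = FALSE,
                 dimnames = list(paste0("sp", 1:3), paste0("s", 1:3)))
    AbundanceTable(bm)
}

# random abundance table: nsp species, nsamp samples, ~frac zeros
randomTable <- function(nsp = 8, nsamp = 12, zeroFrac = 0.3) {
    bm <- matrix(stats::rexp(nsp * nsamp), nsp, nsamp)
    bm[stats::runif(length(bm)) < zeroFrac] <- 0
    # ensure no constant rows / empty columns
    bm[, colSums(bm) == 0] <- 1
    dimnames(bm) <- list(sprintf("sp%02d", seq_len(nsp)),
                         sprintf("s%02d", seq_len(nsamp)))
    AbundanceTable(bm)
}

# unweighted path graph a-b-c as a TrustedNetwork
pathNetwork <- function() {
    S <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2),
                              x = 1, dims = c(3, 3))
    methods::new("TrustedNetwork", speciesIds = c("a", "b", "c"),
                 S = methods::as(S, "CsparseMatrix"), k = 1L)
}

# TrustedNetwork from an arbitrary symmetric weight matrix
networkFromMatrix <- function(W, k = 1L) {
    ids <- rownames(W)
    if (is.null(ids)) ids <- paste0("n", seq_len(nrow(W)))
    S <- methods::as(Matrix::drop0(Matrix::forceSymmetric(
        Matrix::Matrix(W, sparse = TRUE))), "generalMatrix")
    methods::new("TrustedNetwork", speciesIds = ids,
                 S = methods::as(S, "CsparseMatrix"), k = as.integer(k))
}

# random connected weighted graph (n nodes): spanning tree + extra edges
randomConnectedGraph <- function(n, pExtra = 0.3) {
    W <- matrix(0, n, n)
    for (v in 2:n) {                      # random spanning tree
        u <- sample.int(v - 1, 1)
        W[u, v] <- W[v, u] <- stats::runif(1, 0.2, 1)
    }
    extra <- which(upper.tri(W) & W == 0)
    on <- extra[stats::runif(length(extra)) < pExtra]
    W[on] <- stats::runif(length(on), 0.2, 1)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    rownames(W) <- colnames(W) <- paste0("n", seq_len(n))
    W
}

# brute-force diffusion distance: full dense eigendecomposition of the
# Laplacian, explicit double loop over all eigenpairs (the oracle)
bruteDiffusionDistance <- function(W) {
    L <- diag(rowSums(W)) - W
    eig <- eigen(L, symmetric = TRUE)
    n <- nrow(W)
    vals <- rev(eig$values)
    vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        s <- 0
        for (a in 2:n)                    # skip the zero mode
            s <- s + (vecs[i, a] - vecs[j, a])^2 / vals[a]^2
        D[i, j] <- sqrt(s)
    }
    dimnames(D) <- list(rownames(W), rownames(W))
    D
}

# brute-force Rao double sum
bruteRao <- function(p, D) {
    Q <- 0
    for (i in seq_along(p)) for (j in seq_along(p))
        Q <- Q + p[i] * p[j] * D[i, j]
    unname(Q)
}

# tiny simulation setup shared by simulator/validation tests
tinySimSetup <- function(nsp = 12, dims = c(3, 4), seed = 42) {
    traits <- sampleTraits(nsp, seed = seed)
    grid <- buildMetacommunity(dims, seed = seed + 1)
    list(traits = traits, grid = grid)
}

# the trait draw a reconstruction experiment makes internally
.seededTraits <- function(cfg) {
    set.seed(cfg$seed)
    sampleTraits(cfg$nSpecies)
}

# a 1 x 1 patch "grid" (chemostat) with given supply triple
singlePatchGrid <- function(supply) {
    supply <- matrix(supply, 1, 3, dimnames = list(NULL, paste0("S", 1:3)))
    L1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                               x = numeric(0), dims = c(1, 1))
    methods::new("PatchGrid", dims = c(1L, 1L), supply = supply,
                 Lpatch = methods::as(L1, "CsparseMatrix"))
}
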