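#' Spearman co-occurrence similarity between species
#'
#' Pairwise Spearman rank correlation of species biomass vectors across all
#' samples, the package's notion of co-occurrence similarity. Zeros
#' (absences) participate as tied ranks; ties receive average ranks.
#'
#' @param x an [AbundanceTable-class] with at least 3 species and 3
#'   samples, pre-filtered with [filterSpecies()].
#' @param method `"spearman"` (default) or `"pearson"` (alternative metric
#'   for sensitivity analyses).
#' @param ... unused.
#' @return dense symmetric matrix of correlations in `[-1, 1]` with species
#'   ids as dimnames; the diagonal is 1 but is ignored downstream.
#' @rdname spearmanSimilarity
#' @export
setMethod("spearmanSimilarity", "AbundanceTable",
    function(x, method = c("spearman", "pearson"), ...) {
        method <- match.arg(method)
        bm <- biomass(x)
        if (nrow(bm) < 3 || ncol(bm) < 3)
            stop("need at least 3 species and 3 samples")
        const <- apply(bm, 1, function(v) max(v) == min(v))
        if (any(const))
            stop("species with constant biomass vector (similarity ",
                 "undefined): ", paste(utils::head(rownames(bm)[const], 5),
                 collapse = ", "), "; raise minOccurrence in filterSpecies()")
        S <- stats::cor(t(bm), method = method)
        S <- (S + t(S)) / 2
        S
    })

#' Trusted-link network from a similarity matrix
#'
#' Sparsifies a dense similarity matrix by the union k-nearest-neighbour
#' rule: a comparison (i, j) is a trusted link iff it ranks among the top
#' `k` most similar comparisons for at least one of the two species.
#' Ranking uses the signed similarity; ties at the k-th rank are all
#' admitted (deterministic, order-independent). Retained weights are
#' `max(similarity, 0)`: a negative correlation cannot act as a diffusion
#' conductance, so the rare node whose whole neighbourhood is negative
#' becomes isolated (warned) and falls out of the giant component.
#'
#' @param sim dense symmetric similarity matrix with species dimnames.
#' @param k trusted-neighbour count (default 10, the method's single
#'   tunable parameter).
#' @return a [TrustedNetwork-class].
#' @export
trustedLinks <- function(sim, k = 10L) {
    stopifnot(is.matrix(sim), nrow(sim) == ncol(sim), k >= 1)
    n <- nrow(sim)
    ids <- rownames(sim)
    if (is.null(ids)) stop("similarity matrix must carry species dimnames")
    k <- as.integer(min(k, n - 1L))
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        s <- sim[i, ]
        s[i] <- -Inf
        thr <- sort(s, decreasing = TRUE)[k]
        keep[i, s >= thr] <- TRUE
    }
    keep <- keep | t(keep)           # union symmetrization
    diag(keep) <- FALSE
    W <- ifelse(keep, pmax(sim, 0), 0)
    diag(W) <- 0
    deg <- rowSums(W > 0)
    if (any(deg == 0))
        warning(sum(deg == 0), " species isolated after clipping negative ",
                "trusted links; they will be excluded from the embedding")
    S <- methods::as(Matrix::drop0(Matrix::forceSymmetric(
        Matrix::Matrix(W, sparse = TRUE))), "generalMatrix")
    methods::new("TrustedNetwork", speciesIds = ids,
                 S = methods::as(S, "CsparseMatrix"), k = k)
}

#' Connected components of a trusted network
#'
#' @param net a [TrustedNetwork-class].
#' @return an `igraph::components()` result (membership, csize, no).
#' @export
networkComponents <- function(net) {
    g <- igraph::graph_from_adjacency_matrix(net@S, mode = "undirected",
                                             weighted = TRUE)
    igraph::components(g)
}

#' Graph Laplacian of the giant component
#'
#' Restricts the trusted network to its largest connected component
#' (diffusion distances are undefined across components) and returns the
#' unnormalized Laplacian L = Diag(rowSums(S)) - S, a symmetric positive
#' semidefinite matrix with exactly one zero eigenvalue.
#'
#' @param net a [TrustedNetwork-class].
#' @return list with `L` (dense symmetric matrix, dimnames = retained
#'   species) and `dropped` (species outside the giant component).
#' @export
graphLaplacian <- function(net) {
    if (length(net@speciesIds) == 0 || length(net@S@x) == 0)
        stop("empty trusted network")
    comp <- networkComponents(net)
    giant <- which.max(comp$csize)
    inGiant <- comp$membership == giant
    dropped <- net@speciesIds[!inGiant]
    if (length(dropped) > 0)
        message(length(dropped), " species outside the giant component ",
                "excluded from the embedding")
    S <- as.matrix(net@S[inGiant, inGiant, drop = FALSE])
    L <- diag(rowSums(S)) - S
    dimnames(L) <- list(net@speciesIds[inGiant], net@speciesIds[inGiant])
    list(L = L, dropped = dropped)
}

#' Spectral embedding of the trusted network (i-trait space)
#'
#' Computes the `nAxes` smallest nonzero eigenpairs of the unnormalized
#' Laplacian of the giant component. The n-th i-trait of the species is the
#' unit-norm eigenvector v_n rescaled by its eigenvalue, v_n / lambda_n:
#' the eigenvalue is inversely proportional to the importance of the axis,
#' so i-trait 1 (smallest nonzero eigenvalue) is the most important.
#' Each eigenvector is oriented so that its largest-magnitude entry is
#' positive, making the output deterministic across eigensolvers (axis
#' signs are otherwise arbitrary).
#'
#' @param net a [TrustedNetwork-class].
#' @param nAxes number of retained axes m, with `1 <= m <` component size
#'   (default 20).
#' @param normalized experimental alternative: use the random-walk
#'   normalized Laplacian `I - D^-1 S` (generalized eigenproblem
#'   `L v = lambda D v`) instead of the unnormalized `L = D - S`.
#' @return a [TraitSpace-class].
#' @export
embedTraitSpace <- function(net, nAxes = 20L, normalized = FALSE) {
    gl <- graphLaplacian(net)
    L <- gl$L
    n <- nrow(L)
    nAxes <- as.integer(nAxes)
    if (nAxes < 1L || nAxes >= n)
        stop("need connected component size > nAxes >= 1 (component size ",
             n, ", nAxes ", nAxes, "); reduce nAxes or densify k")
    if (normalized) {
        d <- diag(L)
        Dih <- diag(1 / sqrt(d))
        M <- Dih %*% L %*% Dih      # symmetric normalized; same eigenvalues
        eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
    } else {
        eig <- eigen(L, symmetric = TRUE)
    }
    if (any(!is.finite(eig$values)))
        stop("eigensolver failed to converge; reduce nAxes or densify k")
    vals <- rev(eig$values)          # ascending
    vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
    tol <- 1e-9 * max(abs(vals), 1)
    if (sum(vals < tol) != 1L)
        warning("expected exactly one (near-)zero eigenvalue on the giant ",
                "component; found ", sum(vals < tol))
    sel <- seq(2L, nAxes + 1L)
    lam <- vals[sel]
    V <- vecs[, sel, drop = FALSE]
    # deterministic sign: largest-magnitude entry of each axis positive
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    rownames(V) <- rownames(L)
    coords <- sweep(V, 2, lam, "/")
    methods::new("TraitSpace", speciesIds = rownames(L), eigenvalues = lam,
                 vectors = V, coords = coords, nAxes = nAxes,
                 dropped = gl$dropped)
}

#' i-trait coordinates
#'
#' @param x a [TraitSpace-class].
#' @return matrix of eigenvalue-rescaled coordinates (species x axes).
#' @export
traitCoords <- function(x) {
    stopifnot(methods::is(x, "TraitSpace"))
    x@coords
}

#' Laplacian eigenvalues of a trait space
#'
#' @param x a [TraitSpace-class].
#' @return ascending nonzero eigenvalues, one per retained axis.
#' @export
traitEigenvalues <- function(x) {
    stopifnot(methods::is(x, "TraitSpace"))
    x@eigenvalues
}

#' Diffusion distances between species
#'
#' Pairwise functional dissimilarity d_ij = Euclidean distance between the
#' eigenvalue-rescaled embedding coordinates of species i and j,
#' `d_ij^2 = sum_n (v_n,i - v_n,j)^2 / lambda_n^2`. This takes all paths
#' through the trusted network into account; the 1/lambda^2 weighting makes
#' high-order axes contribute negligibly.
#'
#' @param ts a [TraitSpace-class].
#' @param species optional subset of species ids; all embedded species by
#'   default. Requesting a species outside the embedded component is an
#'   error naming the species.
#' @return symmetric nonnegative distance matrix with zero diagonal.
#' @export
diffusionDistance <- function(ts, species = NULL) {
    stopifnot(methods::is(ts, "TraitSpace"))
    X <- ts@coords
    if (!is.null(species)) {
        missing <- setdiff(species, ts@speciesIds)
        if (length(missing) > 0)
            stop("species not in the embedded component: ",
                 paste(utils::head(missing, 5), collapse = ", "))
        X <- X[species, , drop = FALSE]
    }
    D <- as.matrix(stats::dist(X))
    dimnames(D) <- list(rownames(X), rownames(X))
    D
}

#' Infer an i-trait space from an abundance table
#'
#' High-level convenience pipeline: occurrence filter, Spearman similarity,
#' union top-k trusted links, Laplacian embedding. With all defaults the
#' trusted-neighbour count `k` is the method's only tunable parameter.
#'
#' @param x an [AbundanceTable-class].
#' @param k trusted-neighbour count (default 10).
#' @param nAxes retained axes (default 20; clamped with a message if the
#'   giant component is too small).
#' @param minOccurrence occurrence filter passed to [filterSpecies()].
#' @return a [TraitSpace-class].
#' @export
inferTraits <- function(x, k = 10L, nAxes = 20L, minOccurrence = 5L) {
    xf <- filterSpecies(x, minOccurrence = minOccurrence)
    sim <- spearmanSimilarity(xf)
    net <- trustedLinks(sim, k = k)
    compMax <- max(networkComponents(net)$csize)
    if (nAxes >= compMax) {
        nAxes <- compMax - 1L
        message("nAxes clamped to giant component size - 1 = ", nAxes)
    }
    embedTraitSpace(net, nAxes = nAxes)
}

#' Serialize a trait space to CSV
#'
#' Writes `<prefix>_eigenvalues.csv` (axis, lambda) and
#' `<prefix>_coords.csv` (species_id, trait_1..trait_m).
#'
#' @param ts a [TraitSpace-class].
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
writeTraitSpace <- function(ts, prefix) {
    ev <- data.frame(axis = seq_along(ts@eigenvalues),
                     lambda = ts@eigenvalues)
    f1 <- paste0(prefix, "_eigenvalues.csv")
    utils::write.csv(ev, f1, row.names = FALSE)
    co <- data.frame(species_id = ts@speciesIds, ts@coords)
    names(co) <- c("species_id", paste0("trait_", seq_len(ts@nAxes)))
    f2 <- paste0(prefix, "_coords.csv")
    utils::write.csv(co, f2, row.names = FALSE)
    invisible(c(f1, f2))
}

setMethod("show", "TrustedNetwork", function(object) {
    n <- length(object@speciesIds)
    ne <- length(object@S@x) / 2
    cat("TrustedNetwork:", n, "species,", ne, "trusted links (k =",
        object@k, ")\n")
    comp <- networkComponents(object)
    cat("  components:", comp$no, "(giant:", max(comp$csize), "species)\n")
})

setMethod("show", "TraitSpace", function(object) {
    cat("TraitSpace:", length(object@speciesIds), "species,", object@nAxes,
        "i-trait axes\n")
    cat("  eigenvalues:", paste(signif(utils::head(object@eigenvalues, 4), 3),
        collapse = ", "),
        if (object@nAxes > 4) "...\n" else "\n")
    if (length(object@dropped) > 0)
        cat("  ", length(object@dropped),
            "species outside the giant component\n")
})
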