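test_that("Spearman similarity matches the rank-difference formula", {
    bm <- rbind(a = c(1, 2, 3, 4, 5),
                b = c(2, 1, 4, 3, 5),
                c = c(3, 2, 1, 5, 4))
    colnames(bm) <- paste0("s", 1:5)
    S <- spearmanSimilarity(AbundanceTable(bm))
    # rho = 1 - 6 * sum(d^2) / (n (n^2 - 1)) = 1 - 24/120
    expect_equal(S["a", "b"], 0.8)
    expect_true(isSymmetric(S))
    expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))

    # identical vectors -> 1; reversed ranks -> -1
    bm2 <- rbind(a = c(1, 2, 3), b = c(10, 20, 30), c = c(3, 2, 1))
    colnames(bm2) <- paste0("s", 1:3)
    S2 <- spearmanSimilarity(AbundanceTable(bm2))
    expect_equal(S2["a", "b"], 1)
    expect_equal(S2["a", "c"], -1)
})

test_that("a constant biomass vector is rejected with actionable advice", {
    bm <- rbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 1, 2))
    colnames(bm) <- paste0("s", 1:3)
    expect_error(spearmanSimilarity(AbundanceTable(bm)), "minOccurrence")
})

test_that("trusted links follow the union top-k rule (enumeration case)", {
    W <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
    W[1, 2] <- 0.9; W[1, 3] <- 0.5; W[1, 4] <- 0.1
    W[2, 3] <- 0.8; W[2, 4] <- 0.2; W[3, 4] <- 0.7
    W <- W + t(W); diag(W) <- 1
    net <- trustedLinks(W, k = 1L)
    edges <- which(as.matrix(net@S) > 0, arr.ind = TRUE)
    edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
    # nominations 1->2, 2->1, 3->2, 4->3
    expect_equal(unname(edges), rbind(c(1, 2), c(2, 3), c(3, 4)))
    expect_equal(as.matrix(net@S)[1, 2], 0.9)
})

test_that("k >= n-1 yields the complete graph; degrees respect union rule", {
    set.seed(21)
    x <- randomTable(nsp = 10, nsamp = 30, zeroFrac = 0.2)
    S <- spearmanSimilarity(x)
    full <- trustedLinks(S, k = 15L)
    A <- as.matrix(full@S) > 0
    expect_true(all(A[upper.tri(A)] == (S[upper.tri(S)] > 0)))

    for (k in c(1L, 2L, 4L)) {
        net <- trustedLinks(S, k = k)
        # signed ranking: node degree counts all retained links
        degNom <- sapply(seq_len(10), function(i) {
            s <- S[i, -i]
            sum(s >= sort(s, decreasing = TRUE)[k])
        })
        deg <- rowSums(as.matrix(net@S) != 0)
        # union rule can only add links beyond a node's own nominations,
        # but clipping negative weights may remove some; with positive
        # top-k similarities degrees are >= min(k, n-1)
        topkPos <- sapply(seq_len(10), function(i) {
            s <- S[i, -i]
            all(sort(s, decreasing = TRUE)[seq_len(k)] > 0)
        })
        expect_true(all(deg[topkPos] >= k))
    }
})

test_that("path-of-3 Laplacian has the known form and spectrum", {
    gl <- graphLaplacian(pathNetwork())
    L <- gl$L
    expect_equal(unname(L),
                 rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
    expect_equal(unname(rowSums(L)), c(0, 0, 0))
    expect_equal(sort(eigen(L, symmetric = TRUE)$values), c(0, 1, 3),
                 tolerance = 1e-12)
})

test_that("embedding of the path graph matches the closed-form eigenpairs", {
    ts <- embedTraitSpace(pathNetwork(), nAxes = 2L)
    expect_equal(traitEigenvalues(ts), c(1, 3), tolerance = 1e-12)
    v1 <- unname(ts@vectors[, 1])
    v2 <- unname(ts@vectors[, 2])
    expect_equal(abs(v1), c(1, 0, 1) / sqrt(2), tolerance = 1e-10)
    expect_equal(abs(v2), c(1, 2, 1) / sqrt(6), tolerance = 1e-10)
    # sign convention: largest-magnitude entry positive
    expect_true(v1[which.max(abs(v1))] > 0)
    expect_true(v2[which.max(abs(v2))] > 0)
    # coords are v / lambda
    expect_equal(unname(traitCoords(ts)[, 2]), v2 / 3)

    D <- diffusionDistance(ts)
    expect_equal(D["a", "c"], sqrt(2), tolerance = 1e-10)
    expect_equal(D["a", "b"], sqrt(0.5 + (1.2247449 / 3)^2),
                 tolerance = 1e-6)
    expect_equal(diag(D), c(a = 0, b = 0, c = 0))
})

test_that("equal-weight complete graph embeds all nodes equidistantly", {
    W <- matrix(1, 5, 5); diag(W) <- 0
    rownames(W) <- colnames(W) <- letters[1:5]
    ts <- embedTraitSpace(networkFromMatrix(W, k = 4L), nAxes = 4L)
    D <- diffusionDistance(ts)
    off <- D[upper.tri(D)]
    expect_equal(max(off) - min(off), 0, tolerance = 1e-10)
})

test_that("truncated distances are entrywise below the full ones", {
    set.seed(5)
    W <- randomConnectedGraph(10)
    net <- networkFromMatrix(W)
    D_prev <- NULL
    for (m in c(2, 5, 9)) {
        D <- diffusionDistance(embedTraitSpace(net, nAxes = m))
        if (!is.null(D_prev))
            expect_true(all(D + 1e-12 >= D_prev))
        D_prev <- D
    }
})

test_that("truncated diffusion distances match the dense brute-force oracle", {
    set.seed(99)
    for (rep in 1:30) {
        n <- sample(4:12, 1)
        W <- randomConnectedGraph(n)
        D <- diffusionDistance(embedTraitSpace(networkFromMatrix(W),
                                               nAxes = n - 1L))
        expect_equal(D, bruteDiffusionDistance(W), tolerance = 1e-8)
    }
})

test_that("the pipeline is equivariant under species permutation", {
    set.seed(31)
    x <- randomTable(nsp = 12, nsamp = 40, zeroFrac = 0.3)
    perm <- sample(nrow(x))
    xp <- AbundanceTable(biomass(x)[perm, ])

    ts1 <- suppressMessages(inferTraits(x, k = 3L, nAxes = 4L,
                                        minOccurrence = 1L))
    ts2 <- suppressMessages(inferTraits(xp, k = 3L, nAxes = 4L,
                                        minOccurrence = 1L))
    expect_equal(traitEigenvalues(ts1), traitEigenvalues(ts2),
                 tolerance = 1e-9)
    D1 <- diffusionDistance(ts1)
    D2 <- diffusionDistance(ts2)
    ids <- rownames(D1)
    expect_equal(D2[ids, ids], D1, tolerance = 1e-8)
})

test_that("nonexistent species in a distance query is reported by name", {
    ts <- embedTraitSpace(pathNetwork(), nAxes = 2L)
    expect_error(diffusionDistance(ts, species = c("a", "zz")), "zz")
})

test_that("disconnected networks embed only the giant component", {
    W <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
    W["a", "b"] <- W["b", "c"] <- 1        # component of 3
    W["d", "e"] <- 1                       # component of 2
    W <- W + t(W)
    net <- networkFromMatrix(W)
    expect_message(gl <- graphLaplacian(net), "giant component")
    expect_setequal(rownames(gl$L), c("a", "b", "c"))
    expect_setequal(gl$dropped, c("d", "e"))
})

test_that("truncation gap to a high-order reference shrinks as axes grow", {
    set.seed(71)
    tr <- sampleTraits(40, seed = 72)
    runs <- lapply(1:3, function(i)
        simulateMetacommunity(tr, buildMetacommunity(c(4, 5))))
    tab <- suppressMessages(collectSamples(runs))
    xf <- suppressMessages(filterSpecies(tab, 5L))
    net <- trustedLinks(spearmanSimilarity(xf), k = 10L)
    nGiant <- max(networkComponents(net)$csize)
    Dref <- diffusionDistance(embedTraitSpace(net, nAxes = nGiant - 1L))
    gaps <- sapply(c(5L, 10L, 20L), function(m) {
        D <- diffusionDistance(embedTraitSpace(net, nAxes = m))
        norm(Dref - D, "F") / norm(Dref, "F")
    })
    # 1/lambda^2 decay: the relative Frobenius gap decreases with m
    expect_true(all(diff(gaps) < 0))
})
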