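#' Coefficient of determination of a cubic regression
#'
#' Least-squares degree-3 polynomial fit of `y` on `x`;
#' `R^2 = 1 - SS_res / SS_tot`. A cubic absorbs the smooth monotone
#' distortion that a spectral embedding may introduce, so R^2 measures
#' concordance of the diversity estimates up to such distortion.
#'
#' @param x predictor (e.g. ground-truth diversity).
#' @param y response (e.g. inferred diversity).
#' @return R^2 in `[0, 1]`; constant `y` yields 0 (logged).
#' @export
cubicR2 <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 5)
    if (stats::sd(x) == 0) stop("x is constant; cubic fit undefined")
    if (stats::sd(y) == 0) {
        message("constant response: R^2 defined as 0")
        return(0)
    }
    fit <- stats::lm(y ~ stats::poly(x, 3))
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Spearman concordance between two distance matrices
#'
#' Rank correlation across all unordered species pairs between a reference
#' distance matrix and an inferred one; rank-based, so any monotone
#' distortion of the inferred distances leaves it at 1.
#'
#' @param Dtrue,Dinferred symmetric distance matrices with species
#'   dimnames; matched by shared species (an error if none match).
#' @return Spearman rS over the lower triangles.
#' @export
distanceConcordance <- function(Dtrue, Dinferred) {
    Dtrue <- as.matrix(Dtrue); Dinferred <- as.matrix(Dinferred)
    shared <- intersect(rownames(Dtrue), rownames(Dinferred))
    if (length(shared) < 3)
        stop("mismatched species sets between distance matrices")
    A <- Dtrue[shared, shared]; B <- Dinferred[shared, shared]
    lt <- lower.tri(A)
    stats::cor(A[lt], B[lt], method = "spearman")
}

#' Desk-scale default configuration for the reconstruction experiment
#'
#' @param nSpecies number of species (default 200).
#' @param dims patch lattice (default `c(10, 12)`).
#' @param nTrain training metacommunities used to build the map
#'   (default 200; the full-scale study design uses 800).
#' @param nTest held-out test simulations (default 30; full scale 100).
#' @param k trusted-neighbour count (default 10).
#' @param nAxes retained i-trait axes (default 20).
#' @param minOccurrence occurrence filter (default 5).
#' @param supplyRange uniform resource-supply range (default `c(2, 12)`).
#' @param params simulation parameters from [simParams()].
#' @param seed RNG seed for the whole experiment.
#' @return configuration list for [reconstructionExperiment()].
#' @export
reconstructionConfig <- function(nSpecies = 200L, dims = c(10L, 12L),
                                 nTrain = 200L, nTest = 30L, k = 10L,
                                 nAxes = 20L, minOccurrence = 5L,
                                 supplyRange = c(2, 12),
                                 params = simParams(), seed = 1L) {
    list(nSpecies = as.integer(nSpecies), dims = as.integer(dims),
         nTrain = as.integer(nTrain), nTest = as.integer(nTest),
         k = as.integer(k), nAxes = as.integer(nAxes),
         minOccurrence = as.integer(minOccurrence),
         supplyRange = supplyRange, params = params, seed = as.integer(seed))
}

.regionalComposition <- function(bm) {
    tot <- rowSums(bm)
    tot / sum(tot)
}

#' Reconstruction experiment: inferred vs ground-truth diversity
#'
#' End-to-end validation of the trait-inference pipeline on simulated
#' metacommunities with known traits: (1) simulate `nTrain` training
#' metacommunities, collect every patch as a sample, and build the
#' diffusion map (occurrence filter, Spearman similarity, top-`k` trusted
#' links, Laplacian embedding); (2) simulate `nTest` held-out
#' metacommunities; (3) for each test run compute regional Rao diversity
#' (composition = biomass summed across patches) and local Rao diversity
#' (per patch), both under ground-truth R* distances and under diffusion
#' distances from the existing map; (4) fit a cubic of inferred on true
#' and report R^2 at each level, plus the Spearman concordance of the two
#' distance matrices.
#'
#' @param config list from [reconstructionConfig()].
#' @param distances optional distance matrix to use in place of the
#'   diffusion distances (e.g. the ground truth itself as a
#'   self-consistency check).
#' @param verbose print progress messages.
#' @return a [ReconstructionReport-class].
#' @export
reconstructionExperiment <- function(config = reconstructionConfig(),
                                     distances = NULL, verbose = FALSE) {
    set.seed(config$seed)
    traits <- sampleTraits(config$nSpecies)
    Dtrue <- groundTruthDistance(traits)

    runOne <- function() {
        grid <- buildMetacommunity(config$dims, config$supplyRange)
        simulateMetacommunity(traits, grid, config$params)
    }
    if (verbose) message("simulating ", config$nTrain, " training runs")
    trainRuns <- lapply(seq_len(config$nTrain), function(i) runOne())
    tab <- suppressMessages(collectSamples(trainRuns))

    if (is.null(distances)) {
        ts <- suppressMessages(inferTraits(tab, k = config$k,
            nAxes = config$nAxes, minOccurrence = config$minOccurrence))
        nFiltered <- sum(rowSums(biomass(tab) > 0) >= config$minOccurrence)
        if (length(ts@speciesIds) < 0.8 * nFiltered)
            stop("giant component lost ",
                 nFiltered - length(ts@speciesIds), " of ", nFiltered,
                 " species (> 20%); k too small for this data volume")
        Dinf <- diffusionDistance(ts)
    } else {
        Dinf <- as.matrix(distances)
    }
    conc <- distanceConcordance(Dtrue, Dinf)

    if (verbose) message("simulating ", config$nTest, " test runs")
    embedded <- rownames(Dinf)
    regional <- vector("list", config$nTest)
    locals <- vector("list", config$nTest)
    for (r in seq_len(config$nTest)) {
        sim <- runOne()
        bm <- sim@biomass
        pReg <- .regionalComposition(bm)
        qT <- raoIndex(pReg, Dtrue)
        pe <- pReg[embedded]
        qI <- if (sum(pe) > 0) raoIndex(pe / sum(pe), Dinf) else NA_real_
        regional[[r]] <- data.frame(run = r, Qtrue = qT, Qinferred = qI)
        loc <- lapply(seq_len(ncol(bm)), function(p) {
            v <- bm[, p]
            if (sum(v) <= 0) return(NULL)
            qTl <- raoIndex(v / sum(v), Dtrue)
            ve <- v[embedded]
            qIl <- if (sum(ve) > 0) raoIndex(ve / sum(ve), Dinf)
                   else NA_real_
            data.frame(run = r, patch = p, Qtrue = qTl, Qinferred = qIl)
        })
        locals[[r]] <- do.call(rbind, loc)
    }
    regional <- do.call(rbind, regional)
    local <- do.call(rbind, locals)
    r2r <- cubicR2(regional$Qtrue, regional$Qinferred)
    okl <- stats::complete.cases(local[, c("Qtrue", "Qinferred")])
    r2l <- cubicR2(local$Qtrue[okl], local$Qinferred[okl])

    methods::new("ReconstructionReport", regional = regional, local = local,
        r2Regional = r2r, r2Local = r2l, concordance = conc,
        config = config[c("nSpecies", "dims", "nTrain", "nTest", "k",
                          "nAxes", "minOccurrence", "seed")])
}

#' Data-volume sensitivity of the reconstruction
#'
#' Re-runs [reconstructionExperiment()] over a grid of training-run counts
#' (and optionally species counts), reporting regional R^2 and distance
#' concordance per cell. More observations reduce the noise in individual
#' similarity comparisons, so reconstruction quality should be
#' non-decreasing in sample count up to Monte-Carlo noise.
#'
#' @param trainCounts vector of training-metacommunity counts.
#' @param nSpecies vector of species counts (recycled over the grid).
#' @param seeds seeds replicated per cell (median reported alongside).
#' @param ... further arguments to [reconstructionConfig()].
#' @return data.frame with one row per (trainCount, nSpecies, seed):
#'   `n_train`, `n_species`, `n_samples`, `seed`, `k`, `r2_regional`,
#'   `concordance`.
#' @export
dataVolumeSensitivity <- function(trainCounts, nSpecies = 200L,
                                  seeds = 1:3, ...) {
    grid <- expand.grid(nTrain = trainCounts, nSpecies = nSpecies,
                        seed = seeds)
    out <- lapply(seq_len(nrow(grid)), function(i) {
        cfg <- reconstructionConfig(nSpecies = grid$nSpecies[i],
            nTrain = grid$nTrain[i], seed = grid$seed[i], ...)
        rep <- reconstructionExperiment(cfg)
        data.frame(n_train = grid$nTrain[i], n_species = grid$nSpecies[i],
            n_samples = grid$nTrain[i] * prod(cfg$dims), seed = grid$seed[i],
            k = cfg$k, r2_regional = rep@r2Regional,
            concordance = rep@concordance)
    })
    do.call(rbind, out)
}

setMethod("show", "ReconstructionReport", function(object) {
    cat("ReconstructionReport\n")
    cat(sprintf("  regional: %d runs, cubic R^2 = %.3f\n",
        nrow(object@regional), object@r2Regional))
    cat(sprintf("  local:    %d patches, cubic R^2 = %.3f\n",
        nrow(object@local), object@r2Local))
    cat(sprintf("  distance concordance rS = %.3f\n", object@concordance))
})
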