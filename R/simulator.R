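## Three-essential-resource competition metacommunity on a patch lattice.
## Species i in patch p:
##   dB_ip/dt = B_ip (mu_i(R_p) - m) + a * sum_{q in N(p)} (B_iq - B_ip)
##   mu_i(R)  = mu_max * min_k R_k / (R_k + K_ik)      (Liebig-Monod)
##   K_ik     = Rstar_ik (mu_max - m) / m   so mu_i = m exactly at R = Rstar
##   dR_kp/dt = D (S_kp - R_kp) - sum_i c_k mu_i(R_p) B_ip
## Integrated with an adaptive Dormand-Prince 5(4) scheme in C++ with
## nonnegativity clipping and a quasi-steady early exit.

.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Default simulation parameters
#'
#' Rates are per day; resource and biomass units are arbitrary but
#' consistent. Defaults are calibrated so that heterogeneous supply
#' sustains regional coexistence of most species.
#'
#' @param muMax maximal growth rate (1 / d).
#' @param m mortality rate (0.25 / d; must be < `muMax`).
#' @param D resource dilution rate (0.25 / d).
#' @param cContent resource content coefficients `c_k` (length 3).
#' @param a diffusive dispersal rate between neighbouring patches (0.05 / d).
#' @param detectionLimit biomasses below this are recorded as exactly 0.
#' @param tMax integration horizon; the run stops earlier once
#'   `median(|dB/dt| / B) < steadyTol` (quasi-steady state).
#' @param steadyTol quasi-steady criterion on the median relative biomass
#'   derivative.
#' @param B0 initial biomass of every species in every patch.
#' @param rtol,atol integrator relative/absolute tolerances.
#' @return named list of parameters.
#' @export
simParams <- function(muMax = 1, m = 0.25, D = 0.25, cContent = c(1, 1, 1),
                      a = 0.05, detectionLimit = 1e-6, tMax = 300,
                      steadyTol = 1e-3, B0 = 0.01,
                      rtol = 1e-6, atol = 1e-9) {
    stopifnot(m < muMax, muMax > 0, D > 0, length(cContent) == 3, a >= 0)
    list(muMax = muMax, m = m, D = D, cContent = cContent, a = a,
         detectionLimit = detectionLimit, tMax = tMax,
         steadyTol = steadyTol, B0 = B0, rtol = rtol, atol = atol)
}

#' Sample ground-truth species traits on the trade-off triangle
#'
#' Draws R* triplets uniformly on the 2-simplex
#' `{x : x_k >= Rmin, sum_k x_k = Ctot}` (a flat Dirichlet on the shifted
#' simplex), the trade-off triangle on which greater competence for one
#' resource costs competence for the others.
#'
#' @param nSpecies number of species (default 200).
#' @param Ctot row-sum budget of the triangle (default 3, so the mean R*
#'   per resource is 1).
#' @param Rmin minimum requirement per resource (default 0.1); must satisfy
#'   `Ctot > 3 * Rmin`.
#' @param seed optional RNG seed for reproducibility.
#' @return a [SpeciesTraits-class].
#' @export
sampleTraits <- function(nSpecies = 200L, Ctot = 3, Rmin = 0.1,
                         seed = NULL) {
    if (Ctot <= 3 * Rmin)
        stop("infeasible triangle: need Ctot > 3 * Rmin")
    R <- .withSeed(seed, {
        e <- matrix(stats::rexp(nSpecies * 3), nSpecies, 3)
        w <- e / rowSums(e)                     # uniform Dirichlet(1,1,1)
        Rmin + w * (Ctot - 3 * Rmin)
    })
    rownames(R) <- sprintf("sp%03d", seq_len(nSpecies))
    colnames(R) <- paste0("R", 1:3)
    methods::new("SpeciesTraits", Rstar = R, Ctot = Ctot, Rmin = Rmin)
}

#' Build a patch lattice with random resource supply
#'
#' Patches form a rows x cols lattice coupled to 4-neighbours with
#' no-flux boundaries; each patch gets i.i.d. uniform supply of the three
#' resources, mimicking spatial environmental heterogeneity.
#'
#' @param dims lattice dimensions, default `c(10, 12)` (120 patches).
#' @param supplyRange uniform supply range per resource, default
#'   `c(2, 12)`.
#' @param seed optional RNG seed.
#' @return a [PatchGrid-class].
#' @export
buildMetacommunity <- function(dims = c(10L, 12L), supplyRange = c(2, 12),
                               seed = NULL) {
    dims <- as.integer(dims)
    stopifnot(length(dims) == 2, all(dims >= 1), length(supplyRange) == 2,
              all(supplyRange > 0), supplyRange[2] >= supplyRange[1])
    np <- prod(dims)
    supply <- .withSeed(seed,
        matrix(stats::runif(np * 3, supplyRange[1], supplyRange[2]), np, 3))
    colnames(supply) <- paste0("S", 1:3)
    g <- igraph::make_lattice(dimvector = dims, periodic = FALSE)
    Lp <- methods::as(igraph::laplacian_matrix(g, sparse = TRUE),
                      "CsparseMatrix")
    Lp <- methods::as(Lp, "dMatrix")
    Lp <- methods::as(Lp, "generalMatrix")
    methods::new("PatchGrid", dims = dims, supply = supply,
                 Lpatch = methods::as(Lp, "CsparseMatrix"))
}

#' Patch neighbour counts of a lattice
#'
#' @param grid a [PatchGrid-class].
#' @return integer vector of neighbour counts (2 at corners, 3 on edges,
#'   4 in the interior).
#' @export
patchDegrees <- function(grid) {
    as.integer(Matrix::diag(grid@Lpatch))
}

#' Half-saturation constants implied by R* values
#'
#' `K_ik = Rstar_ik (muMax - m) / m`, so that Monod growth on resource k
#' alone equals mortality exactly at `R_k = Rstar_ik`.
#'
#' @param traits a [SpeciesTraits-class].
#' @param muMax,m growth and mortality rates.
#' @return matrix of half-saturation constants, `n_species x 3`.
#' @export
halfSaturation <- function(traits, muMax = 1, m = 0.25) {
    traits@Rstar * (muMax - m) / m
}

#' Simulate a metacommunity to quasi-steady state
#'
#' Integrates the resource-competition metacommunity ODE (see
#' [simParams()]) from uniform initial biomass and resources at supply,
#' until the quasi-steady criterion or `tMax` is reached, then zeroes
#' biomasses below the detection limit.
#'
#' @param traits a [SpeciesTraits-class].
#' @param grid a [PatchGrid-class].
#' @param params list from [simParams()].
#' @return a [MetacommunitySim-class].
#' @export
simulateMetacommunity <- function(traits, grid, params = simParams()) {
    K <- halfSaturation(traits, params$muMax, params$m)
    np <- prod(grid@dims)
    nsp <- nrow(K)
    B0 <- matrix(params$B0, nsp, np)
    R0 <- t(grid@supply)                         # 3 x npatch
    res <- integrate_metacommunity(K, grid@supply, grid@Lpatch, B0, R0,
        params$muMax, params$m, params$D, params$cContent, params$a,
        params$tMax, params$rtol, params$atol, params$steadyTol)
    if (!res$ok)
        stop("integration failed (non-finite state); step-size control ",
             "failure at t = ", res$t)
    B <- res$B
    B[B < params$detectionLimit] <- 0
    dimnames(B) <- list(rownames(traits@Rstar),
                        sprintf("p%03d", seq_len(np)))
    R <- t(res$R)
    colnames(R) <- paste0("R", 1:3)
    methods::new("MetacommunitySim", biomass = B, resources = R,
        grid = grid, info = list(t = res$t, steps = res$steps,
            clipped = res$clipped, steady = res$steady,
            relDeriv = res$relDeriv))
}

#' Collect simulated patches into an abundance table
#'
#' Each patch of each metacommunity run becomes one sample; the patch's
#' three supply values are attached as per-sample covariates (synthetic
#' analogues of nutrient concentrations for interpretation tests).
#'
#' @param runs list of [MetacommunitySim-class] objects sharing one
#'   species set.
#' @param speciesIds common species identifiers (checked across runs).
#' @return an [AbundanceTable-class] with `n_species` rows and
#'   `sum(runs x patches)` columns; all-zero species are kept (they are
#'   flagged for [filterSpecies()]).
#' @export
collectSamples <- function(runs, speciesIds = NULL) {
    stopifnot(length(runs) >= 1)
    ids <- rownames(runs[[1]]@biomass)
    if (is.null(speciesIds)) speciesIds <- ids
    for (r in runs)
        if (!identical(rownames(r@biomass), speciesIds))
            stop("species traits differ across runs")
    bm <- do.call(cbind, lapply(runs, methods::slot, "biomass"))
    colnames(bm) <- sprintf("run%03d_p%03d",
        rep(seq_along(runs), vapply(runs, function(r) ncol(r@biomass), 1L)),
        unlist(lapply(runs, function(r) seq_len(ncol(r@biomass)))))
    supply <- do.call(rbind, lapply(runs, function(r) r@grid@supply))
    md <- data.frame(run = rep(seq_along(runs),
            vapply(runs, function(r) ncol(r@biomass), 1L)), supply)
    rownames(md) <- colnames(bm)
    nAllZero <- sum(rowSums(bm) == 0)
    if (nAllZero > 0)
        message(nAllZero, " species absent from every sample ",
                "(remove with filterSpecies)")
    AbundanceTable(bm, sampleData = md)
}

#' Ground-truth functional distances
#'
#' Euclidean distance between species' R* triplets: the reference
#' functional distance matrix against which diffusion distances are
#' validated.
#'
#' @param traits a [SpeciesTraits-class].
#' @return symmetric distance matrix with species dimnames.
#' @export
groundTruthDistance <- function(traits) {
    D <- as.matrix(stats::dist(traits@Rstar))
    dimnames(D) <- list(rownames(traits@Rstar), rownames(traits@Rstar))
    D
}

setMethod("show", "SpeciesTraits", function(object) {
    cat("SpeciesTraits:", nrow(object@Rstar),
        "species on the trade-off triangle (Ctot =", object@Ctot,
        ", Rmin =", object@Rmin, ")\n")
})

setMethod("show", "PatchGrid", function(object) {
    cat("PatchGrid:", object@dims[1], "x", object@dims[2], "lattice (",
        prod(object@dims), "patches ), supply in [",
        signif(min(object@supply), 3), ",", signif(max(object@supply), 3),
        "]\n")
})

setMethod("show", "MetacommunitySim", function(object) {
    cat("MetacommunitySim:", nrow(object@biomass), "species x",
        ncol(object@biomass), "patches\n")
    cat(sprintf("  t = %.1f, %d steps, steady = %s\n", object@info$t,
        object@info$steps, object@info$steady))
    cat(sprintf("  %d species above detection somewhere\n",
        sum(rowSums(object@biomass) > 0)))
})
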