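#' @import methods
#' @importFrom Matrix Matrix t diag rowSums colSums drop0 forceSymmetric
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Rcpp sourceCpp
#' @useDynLib ecotraitmap, .registration = TRUE
NULL

#' AbundanceTable: species-by-sample biomass with sample metadata
#'
#' An `AbundanceTable` holds a nonnegative species x sample biomass (or
#' abundance) matrix together with per-sample metadata. It extends
#' [SummarizedExperiment::SummarizedExperiment]: the single assay is named
#' `"biomass"`, rows are species and columns are samples; `colData()` carries
#' optional `station`, `date` and numeric environmental covariates.
#'
#' Invariants enforced by the validity method: all biomass entries are finite
#' and >= 0 (a species not recorded in a sample has biomass 0 -- the absence
#' convention of monitoring data), species and sample identifiers are unique
#' and non-empty, and every sample has positive total biomass.
#'
#' @seealso [readAbundanceTable()], [filterSpecies()], [relativeComposition()]
#' @aliases AbundanceTable-class
#' @exportClass AbundanceTable
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
    if (!"biomass" %in% SummarizedExperiment::assayNames(object))
        return("assay 'biomass' is missing")
    bm <- SummarizedExperiment::assay(object, "biomass")
    if (!is.numeric(bm))
        return("biomass must be numeric")
    if (anyNA(bm) || any(!is.finite(bm)))
        return("biomass contains NA/NaN/Inf; map missing values to 0 on ingest")
    if (any(bm < 0))
        return("biomass contains negative values")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("species identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        return("sample identifiers must be present and unique")
    if (ncol(bm) > 0 && any(colSums(bm) <= 0))
        return("every sample must have total biomass > 0 (drop empty samples)")
    TRUE
})

#' TrustedNetwork: sparse symmetric network of trusted similarity links
#'
#' Holds the union top-k ("trusted") similarity links between species as a
#' sparse symmetric weighted adjacency matrix with zero diagonal. Edge
#' weights are nonnegative similarities; an edge (i, j) is present iff j
#' ranked among i's k most similar species or vice versa.
#'
#' @slot speciesIds character vector of species identifiers.
#' @slot S symmetric sparse `dgCMatrix` of trusted similarity weights.
#' @slot k integer, the trusted-neighbour count used to build the network.
#'
#' @aliases TrustedNetwork-class
#' @exportClass TrustedNetwork
setClass("TrustedNetwork",
    representation(speciesIds = "character", S = "dgCMatrix", k = "integer"))

setValidity("TrustedNetwork", function(object) {
    n <- length(object@speciesIds)
    if (anyDuplicated(object@speciesIds))
        return("duplicated species identifiers")
    if (nrow(object@S) != n || ncol(object@S) != n)
        return("similarity matrix dimensions do not match species")
    if (any(abs(object@S - Matrix::t(object@S)) > 1e-12))
        return("trusted similarity matrix must be symmetric")
    if (any(Matrix::diag(object@S) != 0))
        return("trusted similarity matrix must have zero diagonal")
    if (any(object@S@x < 0))
        return("trusted edge weights must be nonnegative")
    if (object@k < 1L)
        return("k must be >= 1")
    TRUE
})

#' TraitSpace: eigenvalue-rescaled Laplacian embedding of species
#'
#' The inferred trait ("i-trait") space of the species in the giant
#' component of a trusted network. Column n of `coords` is the unit-norm
#' Laplacian eigenvector v_n divided by its eigenvalue lambda_n, so axis
#' importance (column norm 1/lambda_n) is non-increasing and Euclidean
#' distance between rows is the diffusion distance.
#'
#' @slot speciesIds species retained in the embedded (giant) component.
#' @slot eigenvalues nonzero Laplacian eigenvalues, ascending.
#' @slot vectors matrix of unit-norm eigenvectors (one column per axis).
#' @slot coords matrix of rescaled coordinates `vectors %*% diag(1/eigenvalues)`.
#' @slot nAxes number of retained axes.
#' @slot dropped species excluded because they fell outside the giant
#'   component.
#'
#' @aliases TraitSpace-class
#' @exportClass TraitSpace
setClass("TraitSpace",
    representation(speciesIds = "character", eigenvalues = "numeric",
        vectors = "matrix", coords = "matrix", nAxes = "integer",
        dropped = "character"))

setValidity("TraitSpace", function(object) {
    n <- length(object@speciesIds)
    m <- object@nAxes
    if (any(object@eigenvalues <= 0))
        return("all retained eigenvalues must be > 0 (zero mode discarded)")
    if (is.unsorted(object@eigenvalues))
        return("eigenvalues must be ascending")
    if (length(object@eigenvalues) != m)
        return("nAxes does not match number of eigenvalues")
    if (!identical(dim(object@coords), c(n, as.integer(m))))
        return("coords must be n_species x nAxes")
    if (!identical(dim(object@vectors), c(n, as.integer(m))))
        return("vectors must be n_species x nAxes")
    nrm <- sqrt(colSums(object@vectors^2))
    if (any(abs(nrm - 1) > 1e-6))
        return("eigenvectors must be unit norm")
    TRUE
})

#' SpeciesTraits: ground-truth R* requirements on the trade-off triangle
#'
#' Minimal resource requirements (R* values) of simulated species for three
#' essential resources. Rows lie on the trade-off triangle
#' `sum_k R*_k = Ctot` with `R*_k >= Rmin`, so competence in one resource
#' costs competence in the others.
#'
#' @slot Rstar numeric matrix `n_species x 3` of R* values.
#' @slot Ctot total requirement budget defining the triangle.
#' @slot Rmin lower bound for each R* coordinate.
#'
#' @aliases SpeciesTraits-class
#' @exportClass SpeciesTraits
setClass("SpeciesTraits",
    representation(Rstar = "matrix", Ctot = "numeric", Rmin = "numeric"))

setValidity("SpeciesTraits", function(object) {
    R <- object@Rstar
    if (ncol(R) != 3L) return("Rstar must have 3 columns (three resources)")
    if (is.null(rownames(R))) return("Rstar rows must be named by species")
    if (any(R < object@Rmin - 1e-9)) return("Rstar entries below Rmin")
    if (any(abs(rowSums(R) - object@Ctot) > 1e-8))
        return("Rstar rows must sum to Ctot (trade-off triangle)")
    TRUE
})

#' PatchGrid: lattice of habitat patches with random resource supply
#'
#' A rows x cols lattice of habitat patches. Each patch has an independent
#' uniform supply point for the three resources; dispersal couples
#' 4-neighbours with no-flux boundaries (represented by the patch graph
#' Laplacian).
#'
#' @slot dims integer vector `c(rows, cols)`.
#' @slot supply numeric matrix `n_patches x 3` of resource supply points.
#' @slot Lpatch sparse patch-graph Laplacian (degree minus adjacency).
#'
#' @aliases PatchGrid-class
#' @exportClass PatchGrid
setClass("PatchGrid",
    representation(dims = "integer", supply = "matrix", Lpatch = "dgCMatrix"))

setValidity("PatchGrid", function(object) {
    np <- prod(object@dims)
    if (length(object@dims) != 2L || any(object@dims < 1L))
        return("dims must be two positive integers")
    if (nrow(object@supply) != np || ncol(object@supply) != 3L)
        return("supply must be n_patches x 3")
    if (any(object@supply <= 0)) return("supply must be positive")
    if (nrow(object@Lpatch) != np) return("Lpatch dimension mismatch")
    TRUE
})

#' MetacommunitySim: end-state of one metacommunity simulation
#'
#' Species biomass and resource concentrations per patch at sampling time
#' (quasi-steady state), with biomasses below the detection limit set to
#' exactly zero, plus the per-patch supply record usable as synthetic
#' environmental covariates.
#'
#' @slot biomass numeric matrix `n_species x n_patches`.
#' @slot resources numeric matrix `n_patches x 3` of dissolved concentrations.
#' @slot grid the [PatchGrid-class] that was simulated.
#' @slot info list of integrator diagnostics (end time, steps, clip events,
#'   whether the quasi-steady criterion was met).
#'
#' @aliases MetacommunitySim-class
#' @exportClass MetacommunitySim
setClass("MetacommunitySim",
    representation(biomass = "matrix", resources = "matrix",
        grid = "PatchGrid", info = "list"))

setValidity("MetacommunitySim", function(object) {
    if (any(object@biomass < 0)) return("biomass must be nonnegative")
    if (nrow(object@resources) != prod(object@grid@dims))
        return("resources dimension mismatch")
    TRUE
})

#' ReconstructionReport: diversity-reconstruction scores against ground truth
#'
#' Pairs of ground-truth and inferred Rao diversities for held-out test
#' simulations, at the regional (whole metacommunity) and local (single
#' patch) level, with the cubic-regression R^2 for each level and the
#' Spearman concordance between ground-truth and diffusion distance
#' matrices.
#'
#' @slot regional data.frame with columns `run`, `Qtrue`, `Qinferred`.
#' @slot local data.frame with columns `run`, `patch`, `Qtrue`, `Qinferred`.
#' @slot r2Regional cubic-regression R^2 for regional diversity.
#' @slot r2Local cubic-regression R^2 for local diversity.
#' @slot concordance Spearman correlation between all unordered-pair
#'   ground-truth and diffusion distances.
#' @slot config list echoing the experiment configuration.
#'
#' @aliases ReconstructionReport-class
#' @exportClass ReconstructionReport
setClass("ReconstructionReport",
    representation(regional = "data.frame", local = "data.frame",
        r2Regional = "numeric", r2Local = "numeric",
        concordance = "numeric", config = "list"))

setValidity("ReconstructionReport", function(object) {
    if (!is.na(object@r2Regional) &&
        (object@r2Regional < 0 || object@r2Regional > 1))
        return("r2Regional must lie in [0, 1]")
    if (!is.na(object@concordance) && abs(object@concordance) > 1)
        return("concordance must lie in [-1, 1]")
    TRUE
})
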