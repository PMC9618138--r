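#' Biomass-weighted environmental means per species
#'
#' For each species, the mean value of an environmental covariate over the
#' samples where it occurs, weighted by the species' biomass in each
#' sample: the environmental conditions under which the species reaches
#' high abundance. Samples with a missing covariate value are excluded
#' pairwise (per covariate, not listwise).
#'
#' @param x an [AbundanceTable-class] whose sample metadata contains the
#'   covariate.
#' @param covariate covariate column name in `colData(x)`.
#' @return data.frame with `species_id`, `mean` (covariate units) and
#'   `total_weight`; species with zero usable weight are omitted with a
#'   warning.
#' @export
weightedEnvMean <- function(x, covariate) {
    cd <- SummarizedExperiment::colData(x)
    if (!covariate %in% colnames(cd))
        stop("unknown covariate: ", covariate)
    e <- as.numeric(cd[[covariate]])
    use <- !is.na(e)
    bm <- biomass(x)[, use, drop = FALSE]
    e <- e[use]
    w <- rowSums(bm)
    mean_ <- as.vector(bm %*% e) / w
    omit <- w <= 0
    if (any(omit))
        warning(sum(omit), " species with zero weight for covariate '",
                covariate, "' omitted")
    data.frame(species_id = rownames(bm)[!omit], mean = mean_[!omit],
               total_weight = w[!omit], row.names = NULL)
}

#' Correlate i-trait axes with environmental preferences
#'
#' Spearman correlation between each i-trait coordinate and each
#' covariate's biomass-weighted species means. Axis signs are arbitrary
#' (eigenvector orientation), so `abs_rS` is the headline statistic; the
#' signed value and a two-sided p-value are also reported. Alignments are
#' hypothesis-generating: a correlation does not imply a causal link.
#'
#' @param ts a [TraitSpace-class].
#' @param x an [AbundanceTable-class] carrying the covariates.
#' @param covariates covariate column names (default: all numeric columns
#'   of `colData(x)`).
#' @param nAxes number of leading axes to test (default 3).
#' @return data.frame with `axis`, `covariate`, `rS`, `abs_rS`, `p_value`,
#'   `n_species`.
#' @export
traitEnvCorrelation <- function(ts, x, covariates = NULL, nAxes = 3L) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(covariates))
        covariates <- colnames(cd)[vapply(cd, is.numeric, TRUE)]
    nAxes <- min(nAxes, ts@nAxes)
    out <- list()
    for (cv in covariates) {
        prof <- suppressWarnings(weightedEnvMean(x, cv))
        shared <- intersect(ts@speciesIds, prof$species_id)
        if (length(shared) < 5)
            stop("fewer than 5 species shared between trait space and ",
                 "profiles for covariate '", cv, "'")
        env <- prof$mean[match(shared, prof$species_id)]
        for (ax in seq_len(nAxes)) {
            co <- ts@coords[shared, ax]
            ct <- suppressWarnings(
                stats::cor.test(co, env, method = "spearman"))
            out[[length(out) + 1L]] <- data.frame(axis = ax,
                covariate = cv, rS = unname(ct$estimate),
                abs_rS = abs(unname(ct$estimate)),
                p_value = ct$p.value, n_species = length(shared))
        }
    }
    do.call(rbind, out)
}
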