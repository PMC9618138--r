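#' Rao's quadratic entropy
#'
#' Q = sum_i sum_j p_i p_j d_ij over all ordered species pairs (the
#' classical full double sum; each unordered pair counted twice). Combines
#' relative abundances with pairwise functional distances: Q is the
#' expected functional distance between two individuals drawn at random
#' with replacement from the sample.
#'
#' @param p composition vector (nonnegative, summing to 1). If named, it is
#'   matched to the distance matrix by name; otherwise lengths must agree.
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param halved if `TRUE`, return Q/2 (the convention counting each
#'   unordered pair once). Default `FALSE`.
#' @return Q, in units of distance. `0 <= Q <= max(D)`.
#' @examples
#' raoIndex(c(0.5, 0.5), matrix(c(0, 1, 1, 0), 2))  # 0.5
#' @export
raoIndex <- function(p, D, halved = FALSE) {
    D <- as.matrix(D)
    if (!is.null(names(p)) && !is.null(rownames(D))) {
        if (!all(names(p) %in% rownames(D)))
            stop("composition names not found in distance matrix: ",
                 paste(utils::head(setdiff(names(p), rownames(D)), 5),
                       collapse = ", "))
        D <- D[names(p), names(p), drop = FALSE]
    }
    if (length(p) != nrow(D))
        stop("dimension mismatch: composition has ", length(p),
             " species, distance matrix ", nrow(D))
    if (abs(sum(p) - 1) > 1e-8)
        stop("composition must sum to 1 (renormalize upstream)")
    Q <- drop(crossprod(p, D %*% p))
    if (halved) Q / 2 else Q
}

#' Per-sample Rao diversity series
#'
#' For every sample: species absent from the trait space are dropped, the
#' remaining biomass is renormalized to shares, and Rao's Q is computed
#' from the diffusion distances. The coverage column records the fraction
#' of sample biomass belonging to embedded species; low coverage flags an
#' unreliable estimate. A sample with zero covered biomass gets `Q = NA`
#' and is flagged, never silently zero.
#'
#' @param x an [AbundanceTable-class].
#' @param distances a [TraitSpace-class] (diffusion distances are computed)
#'   or a distance matrix with species dimnames.
#' @param coverageFloor samples with coverage below this are flagged
#'   (default 0.5).
#' @param halved passed to [raoIndex()].
#' @param ... unused.
#' @return data.frame with columns `sample_id`, `Q`, `coverage`,
#'   `n_effective_species`, `flagged`, plus `station`/`date` where present
#'   in the sample metadata.
#' @rdname sampleDiversity
#' @export
setMethod("sampleDiversity", "AbundanceTable",
    function(x, distances, coverageFloor = 0.5, halved = FALSE, ...) {
        D <- if (methods::is(distances, "TraitSpace"))
            diffusionDistance(distances) else as.matrix(distances)
        if (is.null(rownames(D)))
            stop("distance matrix must carry species dimnames")
        bm <- biomass(x)
        shared <- intersect(rownames(bm), rownames(D))
        if (length(shared) == 0)
            stop("no species shared between table and trait space")
        Ds <- D[shared, shared, drop = FALSE]
        out <- lapply(colnames(bm), function(s) {
            v <- bm[, s]
            tot <- sum(v)
            vs <- v[shared]
            cov <- sum(vs) / tot
            if (sum(vs) <= 0)
                return(data.frame(sample_id = s, Q = NA_real_,
                    coverage = 0, n_effective_species = 0L, flagged = TRUE))
            p <- vs / sum(vs)
            data.frame(sample_id = s, Q = raoIndex(p, Ds, halved = halved),
                coverage = cov, n_effective_species = sum(p > 0),
                flagged = cov < coverageFloor)
        })
        res <- do.call(rbind, out)
        cd <- SummarizedExperiment::colData(x)
        for (field in intersect(c("station", "date"), colnames(cd)))
            res[[field]] <- cd[res$sample_id, field]
        if (any(res$flagged))
            message(sum(res$flagged), " sample(s) flagged (coverage < ",
                    coverageFloor, " or no embedded species)")
        res
    })

#' Per-station diversity trends
#'
#' Ordinary least-squares regression of Rao's Q on decimal year, fitted
#' separately per station; the minimal reproducible estimator of a
#' monotone diversity trend over a monitoring period.
#'
#' @param records data.frame as returned by [sampleDiversity()], with
#'   `station` and `date` (Date or ISO-8601 string) columns. Undated
#'   records are excluded with a warning; stations with fewer than 3 dated
#'   records are skipped.
#' @return data.frame with one row per station: `station`, `n`, `slope`
#'   (Q units per year), `intercept`, `p_value`, `mean_Q`, plus ranks by
#'   slope and by mean Q.
#' @export
stationTrend <- function(records) {
    stopifnot(all(c("station", "date", "Q") %in% names(records)))
    dates <- as.Date(records$date)
    bad <- is.na(dates) | is.na(records$Q)
    if (any(bad)) {
        warning(sum(bad), " undated or Q-less record(s) excluded from trends")
        records <- records[!bad, , drop = FALSE]
        dates <- dates[!bad]
    }
    yr <- as.POSIXlt(dates)$year + 1900 +
        (as.POSIXlt(dates)$yday) / 365.25
    out <- lapply(split(seq_len(nrow(records)), records$station),
        function(idx) {
            if (length(idx) < 3) return(NULL)
            fit <- stats::lm(records$Q[idx] ~ yr[idx])
            cf <- summary(fit)$coefficients
            pv <- if (nrow(cf) >= 2) cf[2, 4] else NA_real_
            sl <- if (nrow(cf) >= 2) cf[2, 1] else 0
            data.frame(station = records$station[idx[1]], n = length(idx),
                slope = sl, intercept = cf[1, 1], p_value = pv,
                mean_Q = mean(records$Q[idx]))
        })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res$rank_by_slope <- rank(-res$slope, ties.method = "first")
    res$rank_by_meanQ <- rank(-res$mean_Q, ties.method = "first")
    res
}
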