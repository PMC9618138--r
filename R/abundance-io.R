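#' Construct an AbundanceTable
#'
#' Build an [AbundanceTable-class] from a species x sample biomass matrix
#' and optional per-sample metadata. `NA`/`NaN` cells are mapped to 0 under
#' the absence convention of monitoring data (with a message reporting the
#' count); samples whose total biomass is zero are dropped with a warning.
#'
#' @param biomass numeric matrix, species in rows and samples in columns,
#'   with row and column names.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample
#'   metadata, one row per sample (matched to `colnames(biomass)` by
#'   rownames or a `sample_id` column; otherwise by position).
#' @return a validated [AbundanceTable-class].
#' @examples
#' bm <- matrix(c(2, 6, 0, 1, 0, 3), nrow = 3,
#'              dimnames = list(paste0("sp", 1:3), c("s1", "s2")))
#' AbundanceTable(bm)
#' @export
AbundanceTable <- function(biomass, sampleData = NULL) {
    biomass <- as.matrix(biomass)
    storage.mode(biomass) <- "double"
    if (is.null(rownames(biomass)) || is.null(colnames(biomass)))
        stop("biomass matrix must have species rownames and sample colnames")
    nNA <- sum(is.na(biomass))
    if (nNA > 0) {
        message(nNA, " missing biomass cell(s) set to 0 (absence convention)")
        biomass[is.na(biomass)] <- 0
    }
    bad <- which(biomass < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop("negative biomass at species '", rownames(biomass)[bad[1, 1]],
             "', sample '", colnames(biomass)[bad[1, 2]], "'")
    if (anyDuplicated(rownames(biomass)))
        stop("duplicated species identifiers")
    if (anyDuplicated(colnames(biomass)))
        stop("duplicated sample identifiers")
    cd <- .matchSampleData(sampleData, colnames(biomass))
    empty <- colSums(biomass) <= 0
    if (any(empty)) {
        warning(sum(empty), " sample(s) with zero total biomass dropped: ",
                paste(utils::head(colnames(biomass)[empty], 5), collapse = ", "))
        biomass <- biomass[, !empty, drop = FALSE]
        cd <- cd[!empty, , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(biomass = biomass), colData = cd)
    methods::new("AbundanceTable", se)
}

.matchSampleData <- function(sampleData, sampleIds) {
    if (is.null(sampleData))
        return(S4Vectors::DataFrame(row.names = sampleIds))
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData)) {
        rownames(sampleData) <- sampleData$sample_id
        sampleData$sample_id <- NULL
    }
    if (!is.null(rownames(sampleData)) &&
        all(sampleIds %in% rownames(sampleData))) {
        sampleData <- sampleData[sampleIds, , drop = FALSE]
    } else if (nrow(sampleData) != length(sampleIds)) {
        stop("sampleData rows cannot be matched to samples")
    }
    rownames(sampleData) <- sampleIds
    S4Vectors::DataFrame(sampleData)
}

#' Extract the biomass matrix
#'
#' @param x an [AbundanceTable-class].
#' @return the species x sample biomass matrix.
#' @export
biomass <- function(x) {
    stopifnot(methods::is(x, "AbundanceTable"))
    SummarizedExperiment::assay(x, "biomass")
}

#' Read a species-by-sample abundance table from delimited text
#'
#' Reads either a wide table (species rows x sample columns, or the
#' transpose with `speciesAsRows = FALSE` -- orientation is never guessed)
#' or a long table with one `(species, sample, value)` record per row.
#' Extra columns of a long table are treated as per-sample metadata; a
#' separate metadata table keyed by `sample_id` can be supplied for either
#' layout. In the long layout a (species, sample) pair occurring twice is
#' an error, never silently summed, and absent pairs get biomass 0.
#'
#' @param path path to a UTF-8 delimited text file.
#' @param layout `"wide"` or `"long"`.
#' @param speciesAsRows wide layout only: are species the rows?
#' @param sep field separator (default `","`).
#' @param sampleMeta optional path to a per-sample metadata table with a
#'   `sample_id` column (dates ISO-8601).
#' @return an [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, layout = c("wide", "long"),
                               speciesAsRows = TRUE, sep = ",",
                               sampleMeta = NULL) {
    layout <- match.arg(layout)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.table(path, header = TRUE, sep = sep,
        check.names = FALSE, stringsAsFactors = FALSE, encoding = "UTF-8")
    md <- if (!is.null(sampleMeta)) {
        utils::read.table(sampleMeta, header = TRUE, sep = sep,
            check.names = FALSE, stringsAsFactors = FALSE, encoding = "UTF-8")
    } else NULL
    if (layout == "wide") {
        ids <- as.character(raw[[1]])
        mat <- raw[, -1, drop = FALSE]
        num <- .parseNumericCells(mat, ids)
        rownames(num) <- ids
        if (!speciesAsRows) num <- t(num)
        AbundanceTable(num, sampleData = md)
    } else {
        if (ncol(raw) < 3)
            stop("long layout needs at least (species, sample, value) columns")
        sp <- as.character(raw[[1]])
        sa <- as.character(raw[[2]])
        val <- raw[[3]]
        if (!is.numeric(val)) {
            conv <- suppressWarnings(as.numeric(val))
            bad <- which(is.na(conv) & !is.na(val) & val != "")
            if (length(bad) > 0)
                stop("malformed numeric cell '", val[bad[1]], "' at row ",
                     bad[1], ", column '", names(raw)[3], "'")
            val <- conv
        }
        if (anyDuplicated(paste(sp, sa, sep = "\r")))
            stop("duplicate (species, sample) records in long table")
        spLev <- unique(sp)
        saLev <- unique(sa)
        mat <- matrix(0, length(spLev), length(saLev),
                      dimnames = list(spLev, saLev))
        mat[cbind(match(sp, spLev), match(sa, saLev))] <- val
        extra <- raw[, -(1:3), drop = FALSE]
        if (ncol(extra) > 0 && is.null(md)) {
            md <- extra[!duplicated(sa), , drop = FALSE]
            rownames(md) <- sa[!duplicated(sa)]
        }
        AbundanceTable(mat, sampleData = md)
    }
}

.parseNumericCells <- function(df, rowIds) {
    out <- matrix(NA_real_, nrow(df), ncol(df),
                  dimnames = list(NULL, names(df)))
    for (j in seq_along(df)) {
        v <- df[[j]]
        if (!is.numeric(v)) {
            conv <- suppressWarnings(as.numeric(v))
            bad <- which(is.na(conv) & !is.na(v) & v != "")
            if (length(bad) > 0)
                stop("malformed numeric cell '", v[bad[1]], "' at species '",
                     rowIds[bad[1]], "', column '", names(df)[j], "'")
            v <- conv
        }
        out[, j] <- v
    }
    out
}

#' Write an AbundanceTable to delimited text
#'
#' Inverse of [readAbundanceTable()]; numeric cells round-trip exactly
#' (full double precision).
#'
#' @param x an [AbundanceTable-class].
#' @param path output file path.
#' @param layout `"wide"` or `"long"` (long omits zero cells).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeAbundanceTable <- function(x, path, layout = c("wide", "long"),
                                sep = ",") {
    layout <- match.arg(layout)
    bm <- biomass(x)
    if (layout == "wide") {
        df <- data.frame(species_id = rownames(bm),
                         format(bm, digits = 17, trim = TRUE,
                                scientific = FALSE), check.names = FALSE)
        names(df) <- c("species_id", colnames(bm))
        utils::write.table(df, path, sep = sep, row.names = FALSE,
                           quote = FALSE)
    } else {
        idx <- which(bm > 0, arr.ind = TRUE)
        df <- data.frame(species_id = rownames(bm)[idx[, 1]],
                         sample_id = colnames(bm)[idx[, 2]],
                         biomass = format(bm[idx], digits = 17, trim = TRUE,
                                          scientific = FALSE))
        utils::write.table(df, path, sep = sep, row.names = FALSE,
                           quote = FALSE)
    }
    invisible(path)
}

#' Filter species by occurrence
#'
#' Retains species present (biomass > 0) in at least `minOccurrence`
#' samples. Rank correlation over species seen in very few samples is
#' dominated by ties, so sparse species are removed before similarity
#' computation; the sample set is unchanged.
#'
#' @param x an [AbundanceTable-class].
#' @param minOccurrence minimum number of samples with positive biomass
#'   (default 5).
#' @param ... unused.
#' @return the filtered [AbundanceTable-class]; errors if fewer than 3
#'   species survive (trait inference impossible).
#' @rdname filterSpecies
#' @export
setMethod("filterSpecies", "AbundanceTable",
    function(x, minOccurrence = 5L, ...) {
        stopifnot(minOccurrence >= 1)
        bm <- biomass(x)
        keep <- rowSums(bm > 0) >= minOccurrence
        nDropped <- sum(!keep)
        if (nDropped > 0)
            message(nDropped, " species below occurrence threshold removed (",
                    sum(keep), " retained)")
        if (sum(keep) < 3)
            stop("fewer than 3 species retained at minOccurrence = ",
                 minOccurrence, "; trait inference impossible")
        x[keep, ]
    })

#' Relative composition of one sample
#'
#' Biomass shares p_i = B_i / sum_j B_j of all species in one sample;
#' the weights used by Rao's quadratic entropy.
#'
#' @param x an [AbundanceTable-class].
#' @param sample sample identifier or column index.
#' @return named numeric vector over species, nonnegative, summing to 1.
#' @rdname relativeComposition
#' @export
setMethod("relativeComposition", "AbundanceTable", function(x, sample) {
    bm <- biomass(x)
    if (is.character(sample) && !sample %in% colnames(bm))
        stop("unknown sample: ", sample)
    v <- bm[, sample]
    tot <- sum(v)
    if (tot <= 0) stop("sample has zero total biomass")
    v / tot
})

setMethod("show", "AbundanceTable", function(object) {
    cat("AbundanceTable:", nrow(object), "species x", ncol(object),
        "samples\n")
    bm <- biomass(object)
    cat(sprintf("  occupancy: %.1f%% of cells > 0\n", 100 * mean(bm > 0)))
    if (ncol(SummarizedExperiment::colData(object)) > 0)
        cat("  sample metadata:",
            paste(colnames(SummarizedExperiment::colData(object)),
                  collapse = ", "), "\n")
})
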