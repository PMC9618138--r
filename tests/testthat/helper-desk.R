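# Desk-scale reconstruction runs shared across acceptance checks.
# Computed once per test session (a few minutes each); criteria that need
# the same study conditions reuse the cached reports.
.deskCache <- new.env(parent = emptyenv())

deskReports <- function(seeds = 1:3) {
    key <- paste0("seeds_", paste(seeds, collapse = "_"))
    if (is.null(.deskCache[[key]])) {
        .deskCache[[key]] <- lapply(seeds, function(s) {
            cfg <- reconstructionConfig(seed = s)
            suppressMessages(reconstructionExperiment(cfg))
        })
    }
    .deskCache[[key]]
}
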