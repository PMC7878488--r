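# Shared fixtures: small synthetic counties and a cached default pipeline
# run (several tests inspect the same run; the cache keeps the suite fast).

tiny_grid <- function(n = 8, cs = 5) county_grid(0, 0, n * cs, n * cs, cs)

tiny_county <- function(seed = 11, n_parcels = 6, extent = c(0, 0, 80, 80)) {
  make_county(county_spec(extent, 5, n_parcels, seed))
}

.pipeline_cache <- new.env(parent = emptyenv())

cached_run <- function(key = "base", mutate = identity) {
  if (is.null(.pipeline_cache[[key]])) {
    cfg <- default_config(seed = 1,
                          output_dir = file.path(tempdir(),
                                                 paste0("rangecap_", key)))
    cfg <- mutate(cfg)
    acc <- run_all(cfg)
    .pipeline_cache[[key]] <- list(cfg = cfg, acc = acc)
  }
  .pipeline_cache[[key]]
}

run_file <- function(run, ...) file.path(run$cfg$output_dir, ...)
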