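# Stage-by-stage pipeline orchestration. Each stage reads its inputs from
# and writes its artifacts to the run directory, so stages can be run
# individually (e.g. from the command line) or composed by run_all().

run_path <- function(cfg, ...) file.path(cfg$output_dir, ...)

cfg_grid <- function(cfg) {
  e <- cfg$synthetic$extent
  county_grid(e[1], e[2], e[3], e[4], cfg$synthetic$cell_size)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: generate the synthetic county
#'
#' Writes parcels (GeoJSON), covariate and NDVI rasters (.asc), latent
#' truth rasters, the transect survey table and the livestock table into
#' the run directory.
#'
#' @param cfg configuration from [load_config()].
#' @return list of written paths, invisibly.
#' @export
stage_generate <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- county_spec(cfg$synthetic$extent, cfg$synthetic$cell_size,
                      cfg$synthetic$n_parcels, cfg$seed)
  county <- make_county(spec)
  truth <- make_truth(county, cfg_species_params(cfg), seed = cfg$seed)
  surveys <- simulate_surveys(truth, cfg_survey_design(cfg), seed = cfg$seed)
  stock <- simulate_livestock(county$parcels,
                              total_sheep_units = cfg$synthetic$livestock$total_sheep_units,
                              mix = unlist(cfg$synthetic$livestock$mix),
                              rates = unlist(cfg$livestock_rates),
                              heterogeneity = cfg$synthetic$livestock$heterogeneity,
                              seed = cfg$seed)
  nd <- cfg$synthetic$ndvi
  ndvi <- simulate_ndvi(county$grid, n_layers = nd$n_layers, mean = nd$mean,
                        sd = nd$sd, cloud_frac = nd$cloud_frac,
                        seed = cfg$seed)
  write_parcels_geojson(county$parcels, run_path(cfg, "parcels.geojson"))
  for (nm in names(county$covariates))
    write_asc(county$covariates[[nm]], run_path(cfg, paste0(nm, ".asc")))
  for (k in seq_along(ndvi$layers))
    write_asc(ndvi$layers[[k]], run_path(cfg, sprintf("ndvi_%02d.asc", k)))
  for (id in names(truth)) {
    write_asc(truth[[id]]$density, run_path(cfg, paste0("truth_density_", id, ".asc")))
    write_asc(truth[[id]]$suitability, run_path(cfg, paste0("truth_suit_", id, ".asc")))
  }
  write_table(surveys, run_path(cfg, "transects.csv"))
  write_table(stock, run_path(cfg, "livestock.csv"))
  truth_summary <- lapply(truth, function(t)
    list(total = t$total,
         suitable_area_km2 = sum(t$suitability$values) * spec$grid$cellsize^2))
  writeLines(jsonlite::toJSON(truth_summary, auto_unbox = TRUE, digits = NA),
             run_path(cfg, "truth_summary.json"))
  invisible(run_path(cfg, c("parcels.geojson", "transects.csv", "livestock.csv")))
}

#' Pipeline stage: per-line abundance densities
#'
#' Reads the transect table, computes strip-transect densities per line and
#' season, merges seasons by the configured rule and writes both the
#' seasonal and merged density tables.
#'
#' @param cfg configuration list.
#' @return the merged density data.frame, invisibly.
#' @export
stage_density <- function(cfg) {
  path <- run_path(cfg, "transects.csv")
  if (!file.exists(path)) stop("missing upstream artifact: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  sad <- estimate_sad(rec, halfwidth_km = cfg$density$halfwidth_km)
  write_table(sad, run_path(cfg, "sad_seasonal.csv"))
  merged <- seasonal_merge(sad, rule = cfg$density$merge_rule)
  write_table(merged, run_path(cfg, "sad.csv"))
  invisible(merged)
}

#' Pipeline stage: ordinary kriging per species
#'
#' Fits a semivariogram to the merged per-line densities of each species
#' and kriges them onto the county grid; writes prediction and variance
#' rasters and the fitted variogram parameters.
#'
#' @param cfg configuration list.
#' @return named list of [krige()] results, invisibly.
#' @export
stage_krige <- function(cfg) {
  path <- run_path(cfg, "sad.csv")
  if (!file.exists(path)) stop("missing upstream artifact: ", path)
  sad <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- cfg_grid(cfg)
  out <- list()
  for (sp in unique(sad$species)) {
    d <- sad[sad$species == sp, ]
    emp <- empirical_semivariogram(d$x, d$y, d$sad,
                                   lag_width = cfg$kriging$lag_width,
                                   max_lag = cfg$kriging$max_lag)
    vg <- fit_semivariogram(emp, model = cfg$kriging$model)
    kr <- krige(d$x, d$y, d$sad, vg, g,
                neighborhood = cfg$kriging$neighborhood)
    write_asc(kr$prediction, run_path(cfg, paste0("density_", sp, ".asc")))
    write_asc(kr$variance, run_path(cfg, paste0("variance_", sp, ".asc")))
    vj <- list(model = vg$model, nugget = vg$nugget, psill = vg$psill,
               range_km = vg$range_km, n_clamped = kr$n_clamped,
               diagnostics = attr(vg, "diagnostics"))
    writeLines(jsonlite::toJSON(vj, auto_unbox = TRUE, digits = NA),
               run_path(cfg, paste0("variogram_", sp, ".json")))
    out[[sp]] <- kr
  }
  invisible(out)
}

read_covariates <- function(cfg) {
  nms <- c("elevation", "slope", "aspect", "temperature", "precipitation")
  covs <- list()
  for (nm in nms) {
    p <- run_path(cfg, paste0(nm, ".asc"))
    if (!file.exists(p)) stop("missing upstream artifact: ", p)
    covs[[nm]] <- read_asc(p, nm)
  }
  covs
}

#' Pipeline stage: habitat suitability and range masking
#'
#' Builds the feature space from the covariate rasters, fits the
#' maximum-entropy model per species on the cells of transects with
#' positive density, thresholds the suitability into a binary range mask
#' and clips the kriged density surfaces with it.
#'
#' @param cfg configuration list.
#' @return named list per species (`model`, `mask`, `masked_density`),
#'   invisibly.
#' @export
stage_suitability <- function(cfg) {
  sadp <- run_path(cfg, "sad.csv")
  if (!file.exists(sadp)) stop("missing upstream artifact: ", sadp)
  sad <- utils::read.csv(sadp, stringsAsFactors = FALSE)
  covs <- read_covariates(cfg)
  fs <- build_features(covs)
  g <- fs$grid
  out <- list()
  for (sp in unique(sad$species)) {
    d <- sad[sad$species == sp & sad$sad > 0, ]
    presence <- unique(cell_at(g, d$x, d$y))
    presence <- presence[!is.na(presence)]
    if (!length(presence)) {
      # species never observed: empty range, zero surface
      densp <- run_path(cfg, paste0("density_", sp, ".asc"))
      if (!file.exists(densp)) stop("missing upstream artifact: ", densp)
      dens <- read_asc(densp)
      zero <- grid_raster(g, 0, "range_mask")
      masked <- mask_density(dens, zero)
      write_asc(grid_raster(g, 0, "suitability"),
                run_path(cfg, paste0("suitability_", sp, ".asc")))
      write_asc(zero, run_path(cfg, paste0("mask_", sp, ".asc")))
      write_asc(masked, run_path(cfg, paste0("masked_density_", sp, ".asc")))
      rj <- list(threshold = NA, rule = "empty", suitable_area_km2 = 0,
                 masked_out_animals = attr(masked, "masked_out"),
                 population_estimate = 0)
      writeLines(jsonlite::toJSON(rj, auto_unbox = TRUE, digits = NA),
                 run_path(cfg, paste0("range_", sp, ".json")))
      out[[sp]] <- list(model = NULL, mask = NULL, masked_density = masked)
      next
    }
    model <- fit_maxent(presence, fs, beta = cfg$habitat$beta,
                        max_iter = cfg$habitat$max_iter,
                        tol = cfg$habitat$tol)
    mask <- threshold_range(model, rule = cfg$habitat$threshold_rule)
    densp <- run_path(cfg, paste0("density_", sp, ".asc"))
    if (!file.exists(densp)) stop("missing upstream artifact: ", densp)
    dens <- read_asc(densp)
    masked <- mask_density(dens, mask)
    write_asc(model$suitability, run_path(cfg, paste0("suitability_", sp, ".asc")))
    write_asc(mask$mask, run_path(cfg, paste0("mask_", sp, ".asc")))
    write_asc(masked, run_path(cfg, paste0("masked_density_", sp, ".asc")))
    rj <- list(threshold = mask$threshold, rule = mask$rule,
               suitable_area_km2 = mask$suitable_area_km2,
               masked_out_animals = attr(masked, "masked_out"),
               population_estimate = raster_integral(masked))
    writeLines(jsonlite::toJSON(rj, auto_unbox = TRUE, digits = NA),
               run_path(cfg, paste0("range_", sp, ".json")))
    out[[sp]] <- list(model = model, mask = mask, masked_density = masked)
  }
  invisible(out)
}

#' Pipeline stage: forage yield and theoretical capacity surfaces
#'
#' Maximal-value composite of the NDVI stack, NDVI-to-yield conversion and
#' the per-area theoretical carrying capacity raster.
#'
#' @param cfg configuration list.
#' @return list (`composite`, `yield`, `ctp`), invisibly.
#' @export
stage_yield <- function(cfg) {
  paths <- sort(list.files(cfg$output_dir, pattern = "^ndvi_[0-9]+\\.asc$",
                           full.names = TRUE))
  if (!length(paths)) stop("missing upstream artifact: ndvi_*.asc in ",
                           cfg$output_dir)
  layers <- lapply(paths, read_asc)
  comp <- max_value_composite(layers)
  yld <- ndvi_to_yield(comp, cfg_yield_params(cfg))
  ctp <- theoretical_capacity_per_area(yld, cfg_capacity_params(cfg))
  write_asc(comp, run_path(cfg, "ndvi_composite.asc"))
  write_asc(yld, run_path(cfg, "yield.asc"))
  write_asc(ctp, run_path(cfg, "ctp_per_km2.asc"))
  invisible(list(composite = comp, yield = yld, ctp = ctp))
}

#' Pipeline stage: per-parcel coexistence accounting
#'
#' Aggregates the theoretical-capacity and masked density surfaces over the
#' parcels, converts the livestock table, closes the per-parcel ledger and
#' writes the parcel accounts, the county summary and a GeoJSON with RCC
#' joined onto the parcels.
#'
#' @param cfg configuration list.
#' @return the parcel accounts data.frame, invisibly.
#' @export
stage_account <- function(cfg) {
  pp <- run_path(cfg, "parcels.geojson")
  if (!file.exists(pp)) stop("missing upstream artifact: ", pp)
  parcels <- read_parcels_geojson(pp)
  ctp <- read_asc(run_path(cfg, "ctp_per_km2.asc"))
  species <- names(cfg$conversions)
  dz <- list()
  for (sp in species) {
    mp <- run_path(cfg, paste0("masked_density_", sp, ".asc"))
    if (!file.exists(mp)) stop("missing upstream artifact: ", mp)
    dz[[sp]] <- zonal_stats(read_asc(mp), parcels)
  }
  stock <- utils::read.csv(run_path(cfg, "livestock.csv"),
                           stringsAsFactors = FALSE)
  acc <- parcel_accounts(parcels, zonal_stats(ctp, parcels), dz, stock,
                         conversions = unlist(cfg$conversions),
                         rates = unlist(cfg$livestock_rates))
  write_table(acc, run_path(cfg, "parcel_accounts.csv"))
  yld <- read_asc(run_path(cfg, "yield.asc"))
  # integral is (yield unit) x km2; convert to kg then tons
  yield_total_t <- raster_integral(yld) * yield_unit_kg_km2(cfg$yield$unit) / 1000
  summary <- data.frame(
    quantity = c(paste0("population_", species), "yield_total_t",
                 "C_tp", "C_w", "C_t", "actual_su", "RCC",
                 "n_overloaded_parcels"),
    value = c(vapply(species, function(sp)
                sum(dz[[sp]]$mean * acc$area_km2[match(dz[[sp]]$parcel_id,
                                                       acc$parcel_id)],
                    na.rm = TRUE), numeric(1)),
              yield_total_t, sum(acc$C_tp), sum(acc$C_w), sum(acc$C_t),
              sum(acc$actual_su), sum(acc$RCC), sum(acc$overloaded)))
  write_table(summary, run_path(cfg, "county_summary.csv"))
  write_parcels_geojson(parcels, run_path(cfg, "parcels_rcc.geojson"),
                        properties = acc[match(parcels$id, acc$parcel_id),
                                         c("C_tp", "C_w", "C_t", "actual_su",
                                           "RCC")])
  invisible(acc)
}

#' Pipeline stage: plain-text run report
#'
#' Collects provenance (full configuration, seed, package version), the
#' county summary and the recorded warnings (clamped cells, empty parcels,
#' masked-out animals) into `report.txt`. Idempotent over a run directory.
#'
#' @param cfg configuration list.
#' @return path to the report, invisibly.
#' @export
stage_report <- function(cfg) {
  sm <- run_path(cfg, "county_summary.csv")
  if (!file.exists(sm)) stop("missing upstream artifact: ", sm)
  summary <- utils::read.csv(sm, stringsAsFactors = FALSE)
  lines <- c("rangecap run report",
             sprintf("package version: %s",
                     as.character(utils::packageVersion("rangecap"))),
             sprintf("seed: %d", cfg$seed), "",
             "county summary (sheep units unless noted):",
             sprintf("  %-24s %.6g", summary$quantity, summary$value), "")
  for (sp in names(cfg$conversions)) {
    vp <- run_path(cfg, paste0("variogram_", sp, ".json"))
    rp <- run_path(cfg, paste0("range_", sp, ".json"))
    if (file.exists(vp)) {
      v <- jsonlite::fromJSON(vp)
      lines <- c(lines, sprintf(
        "variogram %s: %s(nugget=%.4g, psill=%.4g, range=%.4g km), %d cells clamped",
        sp, v$model, v$nugget, v$psill, v$range_km, v$n_clamped))
    }
    if (file.exists(rp)) {
      r <- jsonlite::fromJSON(rp)
      lines <- c(lines, sprintf(
        "range %s: threshold %.4g (%s), suitable %.6g km2, %.4g animals masked out, population %.6g",
        sp, r$threshold, r$rule, r$suitable_area_km2, r$masked_out_animals,
        r$population_estimate))
    }
  }
  lines <- c(lines, "", "configuration:",
             paste0("  ", strsplit(yaml::as.yaml(cfg), "\n")[[1]]))
  writeLines(lines, run_path(cfg, "report.txt"))
  invisible(run_path(cfg, "report.txt"))
}

#' Run the full pipeline
#'
#' Executes generate, density, kriging, suitability, yield, accounting and
#' report in order. Deterministic for a fixed configuration and seed.
#'
#' @param cfg configuration from [load_config()] / [default_config()].
#' @return the parcel accounts data.frame, invisibly.
#' @export
run_all <- function(cfg = default_config()) {
  stages <- list(generate = stage_generate, density = stage_density,
                 krige = stage_krige, suitability = stage_suitability,
                 yield = stage_yield, account = stage_account,
                 report = stage_report)
  res <- NULL
  for (nm in names(stages)) {
    res_try <- tryCatch(stages[[nm]](cfg), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE))
    if (nm == "account") res <- res_try
  }
  invisible(res)
}

#' Command-line dispatcher
#'
#' Thin argument parser behind the `rangecap` command-line script:
#' `rangecap <subcommand> [--config=FILE] [--seed=N] [--out=DIR]` with
#' subcommands `generate`, `density`, `krige`, `suitability`, `yield`,
#' `account`, `report`, `run`.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
rangecap_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subs <- c("generate", "density", "krige", "suitability", "yield",
            "account", "report", "run")
  if (!length(args) || !(args[1] %in% subs)) {
    message("usage: rangecap <", paste(subs, collapse = "|"),
            "> [--config=FILE] [--seed=N] [--out=DIR]")
    return(invisible(1L))
  }
  opt <- function(name) {
    hit <- grep(paste0("^--", name, "="), args, value = TRUE)
    if (length(hit)) sub(paste0("^--", name, "="), "", hit[1]) else NULL
  }
  cfg <- load_config(opt("config"), seed = opt("seed"),
                     output_dir = opt("out"))
  switch(args[1],
         generate = stage_generate(cfg), density = stage_density(cfg),
         krige = stage_krige(cfg), suitability = stage_suitability(cfg),
         yield = stage_yield(cfg), account = stage_account(cfg),
         report = stage_report(cfg), run = run_all(cfg))
  invisible(0L)
}
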