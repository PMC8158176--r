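# End-to-end orchestration: indicators -> zones -> change -> risk -> SCS,
# with optional plain-text outputs and a run log.

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one scenario: baseline and per-GCM future
#' indicators, life-zone maps (baseline and ensemble-median future), change
#' magnitude/direction against the ensemble-median future, area-weighted
#' quartile classes for change and resilience (with optional threshold reuse
#' from a reference scheme), the 16-class production risk table, the crop
#' and livestock safe climatic spaces with per-GCM outside shares,
#' likelihood classes and country aggregation. Deterministic given the
#' inputs.
#'
#' @param data list as produced by [generate_climate()] +
#'   [generate_production()] or [make_known_outside_scenario()]: `baseline`,
#'   `futures` (list of [monthly_climate()]), `production` (with `crop`,
#'   `livestock_au` or `livestock` headcounts), `resilience`, optionally
#'   `countries`.
#' @param coverage SCS coverage target.
#' @param bins SCS bin resolution `c(nx, ny)`.
#' @param change_scheme optional `quantile_scheme` reused for the change
#'   classes (the cross-scenario comparability rule); derived from this run's
#'   change field when `NULL`.
#' @param resilience_percentiles percentiles for the sensitivity table.
#' @param delta optional additive bias-correction array applied to every
#'   min/max temperature midpoint (see [baseline_offset()]).
#' @param out_dir if non-`NULL`, writes rasters/tables/log there.
#' @return List with components `indicators` (baseline, per-GCM futures,
#'   ensemble median), `zones`, `zone_areas`, `change` (magnitude, direction,
#'   classes, scheme), `resilience_classes`, `risk` (a `risk_table`),
#'   `sensitivity`, `scs` (per sector: mask, share, likelihood, countries).
#' @export
run_pipeline <- function(data, coverage = 0.95, bins = c(60, 60),
                         change_scheme = NULL,
                         resilience_percentiles = 20:30,
                         delta = 0, out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines,
                    paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                           sprintf(...)))
  }
  grid <- data$baseline$grid
  areas <- cell_areas(grid)
  say("stage indicators: baseline + %d GCMs", length(data$futures))
  base_ind <- climate_indicators(data$baseline, delta = delta)
  fut_ind <- lapply(data$futures, climate_indicators, delta = delta)
  med_ind <- ensemble_median_indicators(fut_ind)

  say("stage zones")
  base_tri <- to_triangle(base_ind$P, base_ind$R)
  med_tri <- to_triangle(med_ind$P, med_ind$R)
  zones_base <- classify_zone(base_tri, base_ind$frost_free)
  zones_fut <- classify_zone(med_tri, med_ind$frost_free)
  zarea <- list(baseline = zone_areas(zones_base, areas),
                future = zone_areas(zones_fut, areas))

  say("stage change: magnitude + direction vs ensemble median")
  magnitude <- change_magnitude(base_tri, med_tri)
  direction <- change_direction(base_tri, med_tri)
  qc <- quantile_classes(magnitude, areas, scheme = change_scheme,
                         reference = data$baseline$scenario)

  crop <- data$production$crop
  ls_au <- data$production$livestock_au %||%
    to_animal_units(data$production$livestock)
  say("stage risk: 4x4 crosstab + sensitivity")
  rc <- quantile_classes(data$resilience, areas)
  risk <- risk_crosstab(qc$classes, rc$classes, crop, ls_au)
  sens <- resilience_sensitivity(qc$classes, data$resilience, areas,
                                 crop, ls_au,
                                 percentiles = resilience_percentiles)

  say("stage scs: coverage %.2f, bins %d x %d", coverage, bins[1], bins[2])
  fut_tri <- lapply(fut_ind, function(i) to_triangle(i$P, i$R))
  scs <- lapply(c(crop = "crop", livestock = "livestock"), function(sector) {
    prod <- if (sector == "crop") crop else ls_au
    mask <- build_scs(base_tri, prod, coverage = coverage, bins = bins,
                      sector = sector)
    share <- outside_scs_share(fut_tri, base_tri, prod, mask)
    lik <- likelihood_map(share$outside)
    ctab <- country_aggregate(share, prod, data$countries, sector = sector)
    list(mask = mask, share = share, likelihood = lik, countries = ctab)
  })

  out <- list(grid = grid, areas = areas,
              indicators = list(baseline = base_ind, futures = fut_ind,
                                ensemble = med_ind),
              zones = list(baseline = zones_base, future = zones_fut),
              zone_areas = zarea,
              change = list(magnitude = magnitude, direction = direction,
                            classes = qc$classes, scheme = qc$scheme),
              resilience_classes = rc$classes,
              risk = risk, sensitivity = sens, scs = scs)
  if (!is.null(out_dir)) {
    say("stage write: %s", out_dir)
    files <- write_pipeline_outputs(out, out_dir)
    sums <- tools::md5sum(files)
    log_lines <- c(log_lines, sprintf("%s  %s", sums, basename(files)))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  attr(out, "log") <- log_lines
  out
}

# Write the main pipeline products as .asc rasters and .csv tables;
# returns the file paths.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- res$grid
  fp <- function(...) file.path(out_dir, sprintf(...))
  files <- character(0)
  put_r <- function(x, name) {
    path <- fp("%s.asc", name)
    write_raster(x, path, g)
    files <<- c(files, path)
  }
  put_t <- function(df, name) {
    path <- fp("%s.csv", name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  for (v in c("P", "Tbio", "PET", "R"))
    put_r(res$indicators$baseline[[v]], paste0("baseline_", tolower(v)))
  put_r(res$zones$baseline + 0L, "zones_baseline")
  put_r(res$zones$future + 0L, "zones_future")
  put_r(res$change$magnitude, "change_magnitude")
  put_r(res$change$classes + 0L, "change_classes")
  put_r(res$resilience_classes + 0L, "resilience_classes")
  put_t(hlz_legend(), "zone_legend")
  put_t(res$zone_areas$baseline, "zone_areas_baseline")
  put_t(res$zone_areas$future, "zone_areas_future")
  put_t(as.data.frame(res$risk$crop), "risk_crop")
  put_t(as.data.frame(res$risk$livestock), "risk_livestock")
  put_t(res$sensitivity, "resilience_sensitivity")
  for (sector in names(res$scs)) {
    s <- res$scs[[sector]]
    put_t(data.frame(gcm = names(s$share$per_gcm),
                     outside_share = s$share$per_gcm),
          sprintf("scs_%s_outside", sector))
    put_t(s$countries, sprintf("scs_%s_countries", sector))
    put_r(s$likelihood$category + 0L, sprintf("scs_%s_likelihood", sector))
  }
  files
}

#' Read a flat key-value pipeline configuration
#'
#' Same format as [read_manifest()]; recognised numeric keys are coerced.
#' Defaults mirror the analysis conventions (coverage 0.95, 60 x 60 bins,
#' quartile probabilities, 8 GCMs).
#'
#' @param path config file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  raw <- read_manifest(path)
  defaults <- list(seed = 1, nlat = 90, nlon = 180, n_gcm = 8,
                   coverage = 0.95, bins_x = 60, bins_y = 60,
                   concentration = 4)
  for (k in names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[k]]))
    defaults[[k]] <- if (!is.na(v)) v else raw[[k]]
  }
  defaults
}
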