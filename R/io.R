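## Column schemas of the CSV dialects the pipeline reads and writes.
## Each column: type ("character"|"numeric"|"integer"|"date"|"datetime") and
## an optional row-level check returning TRUE or an error message.
table_schemas <- function() {
  pos <- function(x) if (all(x > 0, na.rm = TRUE)) TRUE else "must be positive"
  nonneg <- function(x) if (all(x >= 0, na.rm = TRUE)) TRUE else "must be non-negative"
  list(
    flux_campaign = list(
      plot_id = list(type = "character"),
      datetime = list(type = "datetime"),
      chamber_id = list(type = "character"),
      conc_slope_ppm_s = list(type = "numeric"),
      air_temp_c = list(type = "numeric",
                        check = function(x) if (all(x > -60 & x < 60, na.rm = TRUE))
                          TRUE else "implausible air temperature"),
      pressure_pa = list(type = "numeric",
                         check = function(x) if (all(x >= 50e3 & x <= 110e3, na.rm = TRUE))
                           TRUE else "outside 50-110 kPa"),
      volume_m3 = list(type = "numeric", check = pos),
      area_m2 = list(type = "numeric", check = pos),
      soil_temp_5cm_c = list(type = "numeric")),
    temperature_log = list(
      plot_id = list(type = "character"),
      timestamp = list(type = "datetime"),
      soil_temp_5cm_c = list(type = "numeric")),
    inventory = list(
      plot_id = list(type = "character"),
      treatment = list(type = "character"),
      layer = list(type = "character"),
      soc_pct = list(type = "numeric",
                     check = function(x) if (all(x >= 0 & x <= 60, na.rm = TRUE))
                       TRUE else "outside 0-60 %"),
      core_total_mass_g = list(type = "numeric", check = pos),
      core_rock_mass_g = list(type = "numeric", check = nonneg),
      core_total_vol_cm3 = list(type = "numeric", check = pos),
      core_rock_vol_cm3 = list(type = "numeric", check = nonneg),
      nominal_thickness_cm = list(type = "numeric", check = pos)),
    atmospheric_curve = list(
      year = list(type = "numeric", check = pos),
      delta14c_permil = list(type = "numeric")),
    radiocarbon_obs = list(
      year = list(type = "numeric", check = pos),
      pool = list(type = "character"),
      depth = list(type = "character"),
      treatment = list(type = "character"),
      delta14c_permil = list(type = "numeric"),
      sd_permil = list(type = "numeric", check = pos))
  )
}

#' Read and validate a pipeline CSV table
#'
#' Reads one of the package's CSV dialects, checks the header against the
#' schema, coerces column types, and applies row-level validity checks,
#' reporting offending line numbers.
#'
#' @param path CSV file path.
#' @param schema_name one of `"flux_campaign"`, `"temperature_log"`,
#'   `"inventory"`, `"atmospheric_curve"`, `"radiocarbon_obs"`.
#' @return A validated data frame.
#' @export
load_table <- function(path, schema_name) {
  schemas <- table_schemas()
  if (!schema_name %in% names(schemas))
    stop("unknown schema: ", schema_name)
  schema <- schemas[[schema_name]]
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty table: ", path)
  missing <- setdiff(names(schema), names(tab))
  if (length(missing))
    stop("schema `", schema_name, "`: missing column(s) ",
         paste(missing, collapse = ", "), " in ", path)
  errors <- character()
  for (col in names(schema)) {
    spec <- schema[[col]]
    raw <- tab[[col]]
    val <- switch(spec$type,
      character = as.character(raw),
      numeric = suppressWarnings(as.numeric(raw)),
      integer = suppressWarnings(as.integer(raw)),
      date = as.Date(raw),
      datetime = as.POSIXct(raw, tz = "UTC"))
    bad <- which(is.na(val) & !is.na(raw) & raw != "")
    if (length(bad))
      errors <- c(errors, sprintf("column %s: unparseable value at line %s",
                                  col, paste(bad + 1L, collapse = ",")))
    tab[[col]] <- val
    if (!is.null(spec$check)) {
      ok <- spec$check(val)
      if (!isTRUE(ok)) {
        viol <- which(!vapply(seq_along(val),
                              function(i) isTRUE(spec$check(val[i])), TRUE))
        errors <- c(errors, sprintf("column %s: %s (line %s)", col, ok,
                                    paste(viol + 1L, collapse = ",")))
      }
    }
  }
  if (length(errors))
    stop("validation of ", path, " failed:\n  ",
         paste(errors, collapse = "\n  "))
  tab
}

#' Serialize a fitted compartment model (or fit) to JSON
#'
#' @param x a [compartment_model()] or `c14_fit`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_model_json <- function(x, path = NULL) {
  if (inherits(x, "c14_fit")) {
    doc <- list(pool_names = x$model$pool_names, u = unname(x$model$u),
                B = x$model$B, depth = x$model$depth,
                treatment = x$model$treatment,
                params = as.list(x$params), se = as.list(x$se),
                ssr = x$ssr, converged = x$converged,
                at_bounds = as.list(x$at_bounds), n_obs = x$n_obs)
  } else if (inherits(x, "compartment_model")) {
    doc <- list(pool_names = x$pool_names, u = unname(x$u), B = x$B,
                depth = x$depth, treatment = x$treatment)
  } else stop("cannot serialize object of class ", class(x)[1L])
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the configured stages against synthetic inputs: `simulate`
#' (climate, flux campaign, inventory, atmospheric curve), `flux` (annual
#' budgets by model and interpolation), `response` (warming-response
#' statistics and surplus efflux), `stocks` (corrected SOC stocks and budget
#' closure), `c14` (radiocarbon fit and age/transit distributions for one
#' depth x treatment system). Every stage consumes the previous stages'
#' outputs; all randomness derives from the config seed.
#'
#' @param config a [synthetic_config()], or a YAML/JSON file path / named
#'   list of `synthetic_config()` arguments.
#' @param stages character subset of
#'   `c("simulate", "flux", "response", "stocks", "c14")`; dependencies are
#'   added automatically.
#' @param true_params generating temperature response for the flux stage.
#' @param response_gain multiplicative warming gain passed to
#'   [synth_flux_campaign()] (`NULL` for a purely temperature-driven warmed
#'   flux).
#' @param c14_model generating [compartment_model()] for the c14 stage.
#' @param autotrophic_fraction fraction used in the budget closure.
#' @return A list of class `results_bundle` with stage outputs and a
#'   `manifest` (see [run_manifest()]).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "flux", "response",
                                    "stocks", "c14"),
                         true_params = list(R0 = 0.8, a = 0.12, b = -0.002),
                         response_gain = 0.13,
                         c14_model = three_pool_model(
                           0.9, 0.35, 0.0075, 0.10, 0.15, input = 190,
                           depth = "0-10", treatment = "control"),
                         autotrophic_fraction = 0.4) {
  if (is.character(config)) {
    config <- do.call(synthetic_config, yaml::read_yaml(config))
  } else if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  stages <- match.arg(stages, several.ok = TRUE)
  if (any(c("flux", "response", "stocks", "c14") %in% stages))
    stages <- union(stages, "simulate")
  if ("response" %in% stages) stages <- union(stages, "flux")
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  bundle <- list(config = config)

  if ("simulate" %in% stages) {
    note("simulate: %d blocks, years %d-%d, seed %d", config$n_blocks,
         min(config$years), max(config$years), config$seed)
    bundle$climate <- synth_soil_climate(config)
    bundle$campaign <- synth_flux_campaign(config, bundle$climate,
                                           true_params,
                                           response_gain = response_gain)
    bundle$inventory <- synth_soc_inventory(config)
    bundle$curve <- synth_atmospheric_curve()
  }
  pairs <- config_plot_pairs(config)
  if ("flux" %in% stages) {
    note("flux: Gaussian T-response fits and annual budgets")
    ab <- annual_budgets(bundle$campaign, bundle$climate)
    bundle$budgets <- ab$budgets
    bundle$response_fits <- ab$fits
  }
  if ("response" %in% stages) {
    note("response: per-degree statistic, >2 C filter, suspension year %d",
         config$suspension_year)
    rec <- pair_response_records(bundle$campaign)
    kept <- filter_valid_pairs(rec, pairs)
    bundle$response_records <- kept
    bundle$annual_response <- annual_response_series(kept)
    bundle$surplus <- surplus_efflux(bundle$budgets, pairs,
                                     range(config$years))
  }
  if ("stocks" %in% stages) {
    note("stocks: equivalent-mass corrected SOC stocks")
    st <- inventory_corrected_stocks(bundle$inventory, pairs)
    bundle$stocks <- st
    surplus_to_assessment <- if (!is.null(bundle$surplus))
      bundle$surplus$surplus_kg_m2[1L] else NA_real_
    if (is.finite(surplus_to_assessment)) {
      bundle$budget_closure <- closed_budget(
        surplus_to_assessment, autotrophic_fraction,
        -(st$summary$stock_difference),
        years = length(config$years))
    }
  }
  if ("c14" %in% stages) {
    note("c14: forward simulation, LM fit, age/transit distributions")
    obs <- synth_radiocarbon_obs(c14_model, bundle$curve,
                                 noise_sigma = config$c14_noise_sigma,
                                 seed = config$seed)
    bundle$c14_obs <- obs
    bundle$c14_fit <- fit_radiocarbon_model(
      obs, bundle$curve, input = unname(c14_model$u[1L]),
      stocks = steady_state_stocks(c14_model),
      seed = config$seed)
    bundle$c14_age <- age_distribution(bundle$c14_fit$model, scope = "pool",
                                       pool = "bulk_soc")
    bundle$c14_transit <- transit_time_distribution(bundle$c14_fit$model)
  }
  bundle$log <- log
  bundle$manifest <- run_manifest(config, stages)
  class(bundle) <- "results_bundle"
  bundle
}

#' Reproducibility manifest of a pipeline run
#'
#' @param config the [synthetic_config()] used.
#' @param stages stages executed.
#' @param input_files optional named character vector of input file paths to
#'   digest (MD5).
#' @return List: `config`, `seed`, `stages`, `input_digests`,
#'   `package_version`, `timestamp`.
#' @export
run_manifest <- function(config, stages, input_files = character()) {
  digests <- if (length(input_files)) tools::md5sum(input_files) else character()
  list(config = unclass(config), seed = config$seed, stages = stages,
       input_digests = as.list(digests),
       package_version = as.character(utils::packageVersion("warmsoil")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Write a results bundle to disk
#'
#' Tidy CSV per result table, JSON for fitted models and distributions, and
#' the run manifest (with MD5 digests of every file written) alongside.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character()
  put_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE), p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  tables <- c("climate", "campaign", "inventory", "budgets", "response_fits",
              "response_records", "annual_response", "surplus", "c14_obs")
  for (nm in tables)
    if (!is.null(bundle[[nm]]) && is.data.frame(bundle[[nm]]))
      put_csv(bundle[[nm]], nm)
  if (!is.null(bundle$c14_fit)) {
    p <- file.path(out_dir, "c14_fit.json")
    write_model_json(bundle$c14_fit, p)
    written <- c(written, p)
  }
  if (!is.null(bundle$budget_closure)) {
    p <- file.path(out_dir, "budget_closure.json")
    writeLines(jsonlite::toJSON(unclass(bundle$budget_closure),
                                auto_unbox = TRUE, digits = NA), p)
    written <- c(written, p)
  }
  manifest <- bundle$manifest %||% list()
  manifest$output_digests <- as.list(tools::md5sum(written))
  mp <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), mp)
  invisible(mp)
}
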