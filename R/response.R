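#' Relative CO2 efflux increase per degree of warming
#'
#' The paired-plot warming-response statistic: the percent increase in soil
#' CO2 efflux per 1 degree C of realized soil warming,
#' `100 * (Rw - Rc) / ((Tw - Tc) * Rc)`. Equal fluxes give 0 % per degree.
#'
#' @param r_warming,r_control efflux in warmed and control plot,
#'   umol m-2 s-1.
#' @param t_warming,t_control soil temperature in warmed and control plot,
#'   degrees C.
#' @return Response in percent per degree C.
#' @export
relative_increase_per_degc <- function(r_warming, r_control,
                                       t_warming, t_control) {
  if (any(r_control <= 0)) stop("control flux must be positive")
  if (any(t_warming == t_control)) stop("temperature difference is zero")
  100 * (r_warming - r_control) / ((t_warming - t_control) * r_control)
}

#' Paired-plot design description
#'
#' @param block_id block identifiers.
#' @param control_plot_id,warmed_plot_id plot identifiers per block.
#' @param first_warming_year first warming year per block (cohorts).
#' @param suspension_years calendar years during which warming was suspended.
#' @return Data frame of class `plot_pairs`.
#' @export
plot_pairs <- function(block_id, control_plot_id, warmed_plot_id,
                       first_warming_year,
                       suspension_years = integer()) {
  stopifnot(length(block_id) == length(control_plot_id),
            length(block_id) == length(warmed_plot_id),
            length(block_id) == length(first_warming_year),
            all(control_plot_id != warmed_plot_id))
  structure(
    data.frame(block_id = block_id, control_plot_id = control_plot_id,
               warmed_plot_id = warmed_plot_id,
               first_warming_year = as.integer(first_warming_year),
               stringsAsFactors = FALSE),
    suspension_years = as.integer(suspension_years),
    class = c("plot_pairs", "data.frame")
  )
}

## pairs implied by a synthetic_config
config_plot_pairs <- function(config) {
  layout <- plot_layout(config)
  ctl <- layout[layout$treatment == "control", ]
  wrm <- layout[layout$treatment == "warmed", ]
  plot_pairs(ctl$block_id, ctl$plot_id, wrm$plot_id,
             ctl$first_warming_year,
             suspension_years = config$suspension_year)
}

#' Build paired response records from a flux campaign
#'
#' Averages chamber replicates per plot and date, joins control and warmed
#' measurements within each block and date, and computes the per-degree
#' response statistic for every pair.
#'
#' @param campaign chamber flux table with `block_id, treatment, date,
#'   flux_umol_m2_s, soil_temp_5cm_c`.
#' @return Data frame: `block_id, date, r_control, r_warming, t_control,
#'   t_warming, response_pct_per_degc`.
#' @export
pair_response_records <- function(campaign) {
  agg <- stats::aggregate(
    campaign[, c("flux_umol_m2_s", "soil_temp_5cm_c")],
    by = list(block_id = campaign$block_id, date = campaign$date,
              treatment = campaign$treatment),
    FUN = mean)
  ctl <- agg[agg$treatment == "control", ]
  wrm <- agg[agg$treatment == "warmed", ]
  key_c <- paste(ctl$block_id, ctl$date)
  key_w <- paste(wrm$block_id, wrm$date)
  m <- match(key_w, key_c)
  if (anyNA(m)) stop("unmatched block/date between treatments")
  out <- data.frame(
    block_id = wrm$block_id, date = wrm$date,
    r_control = ctl$flux_umol_m2_s[m], r_warming = wrm$flux_umol_m2_s,
    t_control = ctl$soil_temp_5cm_c[m], t_warming = wrm$soil_temp_5cm_c,
    stringsAsFactors = FALSE)
  dt <- out$t_warming - out$t_control
  out$response_pct_per_degc <- ifelse(
    dt != 0 & out$r_control > 0,
    100 * (out$r_warming - out$r_control) / (dt * out$r_control), NA_real_)
  out[order(out$date, out$block_id), ]
}

#' Filter response records to valid warming measurements
#'
#' Applies the retention rules of the warming-response analysis: drops
#' records whose realized temperature difference is <= 2 degrees C (warming
#' system off or failing) and records falling in suspension years, then
#' relabels calendar years to a per-cohort warming-year index (each cohort's
#' first warming year is warming year 1).
#'
#' @param records output of [pair_response_records()].
#' @param pairs a [plot_pairs()] carrying cohort start and suspension years.
#' @param min_delta_t retention threshold on `Tw - Tc` (degrees C).
#' @return Retained records with an added `warming_year` column.
#' @export
filter_valid_pairs <- function(records, pairs, min_delta_t = 2) {
  m <- match(records$block_id, pairs$block_id)
  if (anyNA(m)) stop("records reference blocks missing from `pairs`")
  year <- as.integer(strftime(records$date, "%Y"))
  suspension <- attr(pairs, "suspension_years") %||% integer()
  keep <- (records$t_warming - records$t_control) > min_delta_t &
    !(year %in% suspension)
  out <- records[keep, , drop = FALSE]
  out$warming_year <- year[keep] - pairs$first_warming_year[m][keep] + 1L
  out <- out[out$warming_year >= 1L, , drop = FALSE]
  out
}

#' Annual warming-response series
#'
#' Date-level responses are first averaged within block and warming year,
#' then summarized across blocks: the mean and SD across blocks per
#' warming-year index.
#'
#' @param records filtered records from [filter_valid_pairs()] (must carry
#'   `warming_year` and `response_pct_per_degc`).
#' @return Data frame: `warming_year, mean_response, sd_response, n_blocks`.
#' @export
annual_response_series <- function(records) {
  if (nrow(records) == 0L) stop("no retained records")
  block_year <- stats::aggregate(
    list(response = records$response_pct_per_degc),
    by = list(warming_year = records$warming_year,
              block_id = records$block_id),
    FUN = mean, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(block_year, block_year$warming_year),
    function(g) data.frame(
      warming_year = g$warming_year[1L],
      mean_response = mean(g$response),
      sd_response = if (nrow(g) > 1L) stats::sd(g$response) else 0,
      n_blocks = nrow(g))))
  rownames(out) <- NULL
  out[order(out$warming_year), ]
}

#' Cumulative surplus CO2 efflux of warming
#'
#' Per block, sums the annual warmed-minus-control efflux difference over the
#' requested years (respecting each cohort's first warming year) and reports
#' the mean and standard error across blocks, separately for the modeled and
#' the interpolation budgets.
#'
#' @param budgets annual budget table `plot_id, year, cumulative_c_g_m2,
#'   method` covering both treatments (plot ids matched through `pairs`).
#' @param pairs a [plot_pairs()].
#' @param years calendar-year range to accumulate, `c(first, last)`.
#' @return Data frame per method: `method, surplus_kg_m2, se_kg_m2,
#'   n_blocks`.
#' @export
surplus_efflux <- function(budgets, pairs, years) {
  stopifnot(length(years) == 2L)
  yr <- budgets$year >= years[1] & budgets$year <= years[2]
  budgets <- budgets[yr, ]
  out <- list()
  for (meth in unique(budgets$method)) {
    b <- budgets[budgets$method == meth, ]
    per_block <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      yrs_i <- max(years[1], pairs$first_warming_year[i]):years[2]
      ctl <- b[b$plot_id == pairs$control_plot_id[i] & b$year %in% yrs_i, ]
      wrm <- b[b$plot_id == pairs$warmed_plot_id[i] & b$year %in% yrs_i, ]
      m <- match(yrs_i, ctl$year); mw <- match(yrs_i, wrm$year)
      if (anyNA(m) || anyNA(mw))
        stop(sprintf("missing treatment-year budgets for block %s",
                     pairs$block_id[i]))
      per_block[i] <- sum(wrm$cumulative_c_g_m2[mw] -
                            ctl$cumulative_c_g_m2[m]) / 1000
    }
    out[[meth]] <- data.frame(
      method = meth, surplus_kg_m2 = mean(per_block),
      se_kg_m2 = stats::sd(per_block) / sqrt(length(per_block)),
      n_blocks = length(per_block), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate annual warming responses with an environmental driver
#'
#' Pearson correlation (with two-sided p value) between the annual mean
#' response and the annual mean of a driver (soil temperature, air
#' temperature, or vapor pressure deficit) over corresponding periods.
#'
#' @param annual_response data frame `warming_year, mean_response` (see
#'   [annual_response_series()]).
#' @param driver data frame `warming_year, value`.
#' @return List: `r`, `p_value`, `n`.
#' @export
correlate_with_driver <- function(annual_response, driver) {
  m <- merge(annual_response[, c("warming_year", "mean_response")],
             driver, by = "warming_year")
  if (nrow(m) < 3L) stop("need at least 3 paired years")
  if (stats::sd(m$value) == 0 || stats::sd(m$mean_response) == 0)
    stop("zero variance in response or driver")
  ct <- stats::cor.test(m$mean_response, m$value, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}
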