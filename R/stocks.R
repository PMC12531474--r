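#' Fine-soil bulk density from a core
#'
#' `(total mass - rock mass) / (total volume - rock volume)`: the bulk
#' density of the fine earth after removing rock fragments (rock volume
#' measured by water displacement).
#'
#' @param total_mass_g total oven-dry core mass, g.
#' @param rock_mass_g mass of rock fragments, g.
#' @param total_vol_cm3 core volume, cm^3.
#' @param rock_vol_cm3 rock fragment volume, cm^3.
#' @return Bulk density of the fine soil, g cm-3.
#' @export
fine_soil_bulk_density <- function(total_mass_g, rock_mass_g,
                                   total_vol_cm3, rock_vol_cm3) {
  if (any(rock_mass_g > total_mass_g))
    stop("rock mass exceeds total mass")
  fine_vol <- total_vol_cm3 - rock_vol_cm3
  if (any(fine_vol <= 0)) stop("rock volume leaves no fine-soil volume")
  (total_mass_g - rock_mass_g) / fine_vol
}

#' SOC stock of one soil layer
#'
#' `concentration/100 x bulk density x thickness`, converted from g cm-2 to
#' kg C m-2 (factor 10).
#'
#' @param soc_pct SOC concentration of the fine soil, percent.
#' @param bulk_density_g_cm3 fine-soil bulk density, g cm-3.
#' @param thickness_cm layer thickness, cm.
#' @return Stock in kg C m-2.
#' @export
soc_stock_layer <- function(soc_pct, bulk_density_g_cm3, thickness_cm) {
  if (any(soc_pct < 0) || any(bulk_density_g_cm3 < 0) || any(thickness_cm < 0))
    stop("negative inputs")
  soc_pct / 100 * bulk_density_g_cm3 * thickness_cm * 10
}

#' Equivalent-mass corrected layer thickness
#'
#' Thickness of warmed (possibly compacted) soil containing the same
#' fine-soil mass per area as the control layer at its nominal thickness:
#' `nominal x bd_control / bd_warmed`. For sub-layers, any surplus thickness
#' of the corrected layer(s) above is subtracted so corrected layers tile
#' the profile without overlap.
#'
#' @param bd_control,bd_warmed fine-soil bulk densities, g cm-3.
#' @param nominal_thickness_cm nominal layer thickness, cm.
#' @param surplus_above surplus corrected thickness of overlying layers, cm
#'   (>= 0; nonzero only when an overlying layer expanded).
#' @return Corrected thickness, cm.
#' @export
corrected_thickness <- function(bd_control, bd_warmed, nominal_thickness_cm,
                                surplus_above = 0) {
  stopifnot(all(bd_control > 0), all(bd_warmed > 0), all(surplus_above >= 0))
  out <- nominal_thickness_cm * bd_control / bd_warmed - surplus_above
  if (any(out < 0))
    stop("compaction correction exceeds the layer thickness")
  out
}

#' Compaction-corrected SOC stocks for a plot-pair profile
#'
#' Applies the equivalent-soil-mass correction layer by layer for one
#' control/warmed plot pair: the corrected thickness of each warmed layer is
#' its nominal thickness scaled by the control:warmed bulk-density ratio
#' (sub-layers additionally give up any surplus thickness of the layers
#' above), and the corrected warmed stock is the uncorrected stock scaled by
#' corrected/nominal thickness. Control stocks are unchanged.
#'
#' @param layers data frame with one row per layer (top first): `layer`,
#'   `nominal_thickness_cm`, `soc_pct_control`, `soc_pct_warmed`,
#'   `bd_control`, `bd_warmed`.
#' @return `layers` with added columns `corrected_thickness_cm`,
#'   `corrected_top_cm`, `corrected_bottom_cm`, `stock_control`,
#'   `stock_warmed_uncorrected`, `stock_warmed_corrected` (kg C m-2),
#'   plus attribute `totals` (profile sums).
#' @export
corrected_stock_profile <- function(layers) {
  need <- c("nominal_thickness_cm", "soc_pct_control", "soc_pct_warmed",
            "bd_control", "bd_warmed")
  if (!all(need %in% names(layers)))
    stop("missing columns: ", paste(setdiff(need, names(layers)), collapse = ", "))
  n <- nrow(layers)
  corr <- numeric(n)
  surplus <- 0
  for (i in seq_len(n)) {
    corr[i] <- corrected_thickness(layers$bd_control[i], layers$bd_warmed[i],
                                   layers$nominal_thickness_cm[i],
                                   surplus_above = surplus)
    ## surplus accumulates only when corrected layers extend beyond the
    ## nominal depth of the profile so far
    surplus <- max(0, sum(corr[seq_len(i)]) -
                     sum(layers$nominal_thickness_cm[seq_len(i)]))
  }
  out <- layers
  out$corrected_thickness_cm <- corr
  out$corrected_bottom_cm <- cumsum(corr)
  out$corrected_top_cm <- out$corrected_bottom_cm - corr
  out$stock_control <- soc_stock_layer(layers$soc_pct_control,
                                       layers$bd_control,
                                       layers$nominal_thickness_cm)
  out$stock_warmed_uncorrected <- soc_stock_layer(layers$soc_pct_warmed,
                                                  layers$bd_warmed,
                                                  layers$nominal_thickness_cm)
  out$stock_warmed_corrected <- out$stock_warmed_uncorrected *
    corr / layers$nominal_thickness_cm
  attr(out, "totals") <- c(
    stock_control = sum(out$stock_control),
    stock_warmed_uncorrected = sum(out$stock_warmed_uncorrected),
    stock_warmed_corrected = sum(out$stock_warmed_corrected))
  out
}

#' Plot-pair corrected stocks from an inventory table
#'
#' Computes fine-soil bulk density per core, pools seasonal SOC samples by
#' arithmetic mean per plot and layer, applies the compaction correction per
#' plot pair, and averages across pairs (mean of per-pair values, matching a
#' blocked paired design).
#'
#' @param inventory inventory table (see the `inventory` schema /
#'   [synth_soc_inventory()]).
#' @param pairs a [plot_pairs()].
#' @return List: `per_pair` (data frame of per-block layer results) and
#'   `summary` (across-block means of control, uncorrected and corrected
#'   warmed stocks, per layer and 0-20 cm total, plus mean corrected depths).
#' @export
inventory_corrected_stocks <- function(inventory, pairs) {
  inv <- inventory
  inv$bd <- fine_soil_bulk_density(inv$core_total_mass_g, inv$core_rock_mass_g,
                                   inv$core_total_vol_cm3, inv$core_rock_vol_cm3)
  agg <- stats::aggregate(
    inv[, c("soc_pct", "bd", "nominal_thickness_cm")],
    by = list(plot_id = inv$plot_id, layer = inv$layer), FUN = mean)
  per_pair <- list()
  for (i in seq_len(nrow(pairs))) {
    ctl <- agg[agg$plot_id == pairs$control_plot_id[i], ]
    wrm <- agg[agg$plot_id == pairs$warmed_plot_id[i], ]
    ctl <- ctl[order(ctl$layer), ]; wrm <- wrm[order(wrm$layer), ]
    if (!identical(ctl$layer, wrm$layer)) stop("mismatched layers in pair")
    lay <- data.frame(layer = ctl$layer,
                      nominal_thickness_cm = ctl$nominal_thickness_cm,
                      soc_pct_control = ctl$soc_pct,
                      soc_pct_warmed = wrm$soc_pct,
                      bd_control = ctl$bd, bd_warmed = wrm$bd,
                      stringsAsFactors = FALSE)
    prof <- corrected_stock_profile(lay)
    prof$block_id <- pairs$block_id[i]
    per_pair[[i]] <- prof
  }
  pp <- do.call(rbind, per_pair)
  by_layer <- stats::aggregate(
    pp[, c("stock_control", "stock_warmed_uncorrected",
           "stock_warmed_corrected", "corrected_thickness_cm",
           "corrected_bottom_cm")],
    by = list(layer = pp$layer), FUN = mean)
  totals <- stats::aggregate(
    pp[, c("stock_control", "stock_warmed_uncorrected",
           "stock_warmed_corrected")],
    by = list(block_id = pp$block_id), FUN = sum)
  summary <- list(
    by_layer = by_layer,
    total_control = mean(totals$stock_control),
    total_warmed_uncorrected = mean(totals$stock_warmed_uncorrected),
    total_warmed_corrected = mean(totals$stock_warmed_corrected))
  summary$stock_difference <- summary$total_control -
    summary$total_warmed_corrected
  list(per_pair = pp, summary = summary)
}

#' Dissolved organic carbon flux
#'
#' Multiplies DOC concentrations by the water flux of the corresponding
#' period: `mg C L-1 x mm` (1 mm = 1 L m-2) `/ 1000 -> g C m-2`. Biweekly
#' concentration samples are pooled to monthly values by volume-weighted
#' mean before multiplication.
#'
#' @param month period label (e.g. "2019-05"); biweekly samples share a
#'   label.
#' @param conc_mg_l DOC concentration per sample, mg C L-1.
#' @param water_mm water flux associated with each sample, mm.
#' @return List: `per_period` (data frame `month, conc_mg_l, water_mm,
#'   doc_g_m2`) and `annual` (data frame `year, doc_g_m2`).
#' @export
doc_flux <- function(month, conc_mg_l, water_mm) {
  stopifnot(length(month) == length(conc_mg_l),
            length(month) == length(water_mm))
  if (any(conc_mg_l < 0) || any(water_mm < 0)) stop("negative inputs")
  ## volume-weighted monthly pooling
  per <- do.call(rbind, lapply(split(seq_along(month), month), function(ii) {
    w <- water_mm[ii]
    conc <- if (sum(w) > 0) sum(conc_mg_l[ii] * w) / sum(w)
            else mean(conc_mg_l[ii])
    data.frame(month = month[ii][1L], conc_mg_l = conc, water_mm = sum(w),
               stringsAsFactors = FALSE)
  }))
  per$doc_g_m2 <- per$conc_mg_l * per$water_mm / 1000
  per <- per[order(per$month), ]
  rownames(per) <- NULL
  yr <- substr(per$month, 1L, 4L)
  annual <- stats::aggregate(list(doc_g_m2 = per$doc_g_m2),
                             by = list(year = yr), FUN = sum)
  list(per_period = per, annual = annual)
}

#' Heterotrophic carbon-budget closure
#'
#' Partitions the cumulative warming-induced surplus CO2 efflux into its
#' heterotrophic share, compares it with the observed SOC stock change, and
#' annualizes the unexplained portion (the belowground C input needed to
#' close the budget):
#' `heterotrophic = surplus x (1 - autotrophic_fraction)`;
#' `missing = heterotrophic - |delta_soc|`; `missing_annual = missing /
#' years`.
#'
#' @param surplus_cum cumulative warming-induced efflux up to the stock
#'   assessment, kg C m-2.
#' @param autotrophic_fraction fraction of the efflux of root/mycorrhizal
#'   origin, 0-1.
#' @param delta_soc SOC stock change, kg C m-2 (negative = loss; the budget
#'   uses its magnitude).
#' @param years number of warming years covered.
#' @return List of class `budget_components` with the inputs plus
#'   `heterotrophic_cum`, `missing_input`, `missing_input_annual`
#'   (kg C m-2 and kg C m-2 yr-1).
#' @export
closed_budget <- function(surplus_cum, autotrophic_fraction, delta_soc,
                          years) {
  stopifnot(autotrophic_fraction >= 0, autotrophic_fraction <= 1)
  if (years <= 0) stop("years must be positive")
  het <- surplus_cum * (1 - autotrophic_fraction)
  missing <- het - abs(delta_soc)
  structure(
    list(surplus_cum = surplus_cum,
         autotrophic_fraction = autotrophic_fraction,
         delta_soc = delta_soc, years = years,
         heterotrophic_cum = het, missing_input = missing,
         missing_input_annual = missing / years),
    class = "budget_components"
  )
}

#' @export
print.budget_components <- function(x, ...) {
  cat(sprintf(paste0(
    "carbon budget closure over %g yr\n",
    "  surplus efflux        %6.3f kg C m-2\n",
    "  heterotrophic share   %6.3f kg C m-2 (autotrophic fraction %.2f)\n",
    "  SOC stock change      %6.3f kg C m-2\n",
    "  missing input         %6.3f kg C m-2 (%.4f kg C m-2 yr-1)\n"),
    x$years, x$surplus_cum, x$heterotrophic_cum, x$autotrophic_fraction,
    x$delta_soc, x$missing_input, x$missing_input_annual))
  invisible(x)
}
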