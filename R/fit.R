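#' Fit the three-pool radiocarbon model to Delta-14C observations
#'
#' Levenberg-Marquardt estimation ([minpack.lm::nls.lm()]) of the five free
#' parameters `(k1, k2, k3, a31, a32)` of a [three_pool_model()] from
#' Delta-14C observations of the litter, fine-root and bulk-SOC pools at one
#' or more sampling years (fitted jointly as a time series). Residuals are
#' `(predicted - observed) / sd`; observed pool stocks can enter the cost as
#' additional weighted residuals (soft constraint) rather than being imposed
#' exactly. The optimizer restarts from `n_starts` jittered initializations
#' and keeps the best solution.
#'
#' @param observations data frame `year, pool, delta14c_permil, sd_permil`
#'   (pool names matching the model's); extra columns ignored.
#' @param curve an [atmospheric_curve()] covering 1900 to the last
#'   observation.
#' @param input external input, as in [three_pool_model()] (fixed, not
#'   fitted).
#' @param stocks optional named vector of observed pool stocks (g C m-2)
#'   used as soft constraints.
#' @param stock_rel_sd relative sd assigned to stock residuals (default 0.1,
#'   i.e. a 10% soft constraint, chosen so stock and Delta-14C residuals
#'   contribute comparably).
#' @param init named starting values for `k1, k2, k3, a31, a32`.
#' @param lower,upper parameter bounds.
#' @param n_starts number of jittered starts (>= 1).
#' @param t_span,step forward-simulation controls (see
#'   [forward_delta14c()]).
#' @param depth,treatment labels for the fitted model.
#' @param seed seed for the jitter stream.
#' @return List of class `c14_fit`: `model` (the fitted
#'   [compartment_model()]), `params`, `se`, `vcov`, `ssr`, `residuals`,
#'   `converged`, `at_bounds`, `n_obs`, `starts_tried`.
#' @export
fit_radiocarbon_model <- function(observations, curve, input = 190,
                                  stocks = NULL, stock_rel_sd = 0.1,
                                  init = c(k1 = 0.5, k2 = 0.3, k3 = 0.01,
                                           a31 = 0.2, a32 = 0.2),
                                  lower = c(k1 = 1e-3, k2 = 1e-3, k3 = 1e-5,
                                            a31 = 0, a32 = 0),
                                  upper = c(k1 = 20, k2 = 20, k3 = 2,
                                            a31 = 1, a32 = 1),
                                  n_starts = 5L, t_span = NULL, step = 0.2,
                                  depth = NA_character_,
                                  treatment = NA_character_, seed = 1L) {
  obs <- as.data.frame(observations)
  need <- c("year", "pool", "delta14c_permil", "sd_permil")
  if (!all(need %in% names(obs)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  ref <- three_pool_model(init["k1"], init["k2"], init["k3"],
                          init["a31"], init["a32"], input = input)
  if (!all(obs$pool %in% ref$pool_names))
    stop("unknown pool names in observations")
  if (any(obs$sd_permil <= 0)) stop("observation sd must be positive")
  n_res <- nrow(obs) + if (is.null(stocks)) 0L else length(stocks)
  if (n_res < 5L)
    stop("under-determined: ", n_res, " residuals for 5 free parameters; ",
         "observations of more pools/years (or stock constraints) required")
  if (length(unique(obs$pool)) < 2L && is.null(stocks))
    stop("under-determined: observations cover a single pool only")
  if (is.null(t_span)) t_span <- c(1900, max(obs$year))

  pool_idx <- match(obs$pool, ref$pool_names)
  ## pre-compute forcing grid once
  n_steps <- ceiling((t_span[2] - t_span[1]) / step)
  years <- t_span[1] + step * (0:n_steps)
  f_atm <- 1 + curve_at(curve, years, rule = "clamp") / 1000
  yr_idx <- vapply(obs$year, function(y) which.min(abs(years - y)), 0L)

  residual_fn <- function(par) {
    m <- tryCatch(
      three_pool_model(par["k1"], par["k2"], par["k3"], par["a31"],
                       par["a32"], input = input),
      error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, n_res))
    x_star <- steady_state_stocks(m)
    Bl <- m$B - diag(LAMBDA_14C, 3L)
    m0 <- solve(-Bl, m$u * f_atm[1L])
    traj <- solve_linear_forced(Bl, m$u, m0, f_atm, step)
    pred <- 1000 * (traj[cbind(yr_idx, pool_idx)] / x_star[pool_idx] - 1)
    res <- (pred - obs$delta14c_permil) / obs$sd_permil
    if (!is.null(stocks)) {
      si <- match(names(stocks), m$pool_names)
      res <- c(res, (x_star[si] - stocks) / (stock_rel_sd * stocks))
    }
    res
  }

  jitter_starts <- with_stream_seed(seed, "c14_fit_starts", {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) return(init)
      p <- init * exp(stats::rnorm(length(init), 0, 0.5))
      pmin(pmax(p, lower * 1.0000001), upper * 0.9999999)
    })
  })

  best <- NULL
  tried <- 0L
  for (st in jitter_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    tried <- tried + 1L
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("no start converged")
  par <- best$par
  at_bounds <- par <= lower * 1.001 | par >= upper * 0.999
  dof <- max(n_res - length(par), 1L)
  sigma2 <- best$deviance / dof
  vc <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(par)) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(par)
  model <- three_pool_model(par["k1"], par["k2"], par["k3"], par["a31"],
                            par["a32"], input = input,
                            depth = depth, treatment = treatment)
  structure(
    list(model = model, params = par, se = se, vcov = vc,
         ssr = best$deviance, residuals = best$fvec,
         converged = best$info %in% 1:4, info = best$info,
         at_bounds = at_bounds, n_obs = n_res, starts_tried = tried),
    class = "c14_fit"
  )
}

#' @export
print.c14_fit <- function(x, ...) {
  cat("<c14_fit>\n  parameters:\n")
  for (nm in names(x$params))
    cat(sprintf("    %-4s %10.5g  (se %.3g)%s\n", nm, x$params[nm], x$se[nm],
                if (x$at_bounds[nm]) "  [at bound]" else ""))
  cat(sprintf("  ssr %.4g on %d residuals; converged: %s (%d starts)\n",
              x$ssr, x$n_obs, x$converged, x$starts_tried))
  invisible(x)
}
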