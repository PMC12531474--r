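#' Linear compartmental carbon model
#'
#' Container for a steady-state linear compartment system
#' `dC/dt = u + B C`: an input vector `u` (g C m-2 yr-1 per pool) and a
#' compartmental matrix `B` (yr-1) with negative decay rates on the diagonal
#' and non-negative transfer rates off it. Construction enforces
#' compartmental validity: `diag(B) < 0`, off-diagonals `>= 0`, every column
#' sum `<= 0` (no pool exports more than it decays), `u >= 0` with at least
#' one positive entry.
#'
#' @param u input vector, g C m-2 yr-1.
#' @param B square compartmental matrix, yr-1.
#' @param pool_names pool labels (default litter / fine roots / bulk SOC).
#' @param depth,treatment bookkeeping labels.
#' @return Object of class `compartment_model`.
#' @export
compartment_model <- function(u, B,
                              pool_names = c("aboveground_litter",
                                             "fine_roots", "bulk_soc"),
                              depth = NA_character_,
                              treatment = NA_character_) {
  B <- as.matrix(B)
  n <- nrow(B)
  stopifnot(ncol(B) == n, length(u) == n, length(pool_names) == n)
  if (any(!is.finite(B)) || any(!is.finite(u))) stop("non-finite model entries")
  if (any(diag(B) >= 0)) stop("diagonal of B must be negative (decay rates)")
  off <- B; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal transfer rates must be non-negative")
  if (any(colSums(B) > 1e-12)) stop("column sums of B must be <= 0")
  if (any(u < 0) || all(u == 0)) stop("u must be non-negative with an input")
  dimnames(B) <- list(pool_names, pool_names)
  names(u) <- pool_names
  structure(list(u = u, B = B, pool_names = pool_names,
                 depth = depth, treatment = treatment),
            class = "compartment_model")
}

#' Three-pool litter / fine-root / SOC model
#'
#' The standard serial-parallel topology: aboveground litter and fine roots
#' receive external input and decay at `k1`, `k2`; fractions `a31`, `a32` of
#' the decayed carbon transfer into bulk SOC, which decays at `k3`. Inputs
#' default to equal litter and fine-root inputs and none directly to SOC.
#'
#' @param k1,k2,k3 decay rates of litter, fine roots and bulk SOC, yr-1.
#' @param a31,a32 transfer fractions litter->SOC and roots->SOC, 0-1.
#' @param input either a single value (applied to litter and fine roots
#'   equally) or a length-3 vector, g C m-2 yr-1.
#' @param depth,treatment bookkeeping labels.
#' @return A [compartment_model()].
#' @export
three_pool_model <- function(k1, k2, k3, a31, a32, input = 190,
                             depth = NA_character_,
                             treatment = NA_character_) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0, a31 >= 0, a31 <= 1, a32 >= 0, a32 <= 1)
  u <- if (length(input) == 1L) c(input, input, 0) else input
  B <- matrix(c(-k1,       0,        0,
                 0,       -k2,       0,
                 a31 * k1, a32 * k2, -k3),
              nrow = 3L, byrow = TRUE)
  compartment_model(u, B, depth = depth, treatment = treatment)
}

#' @export
print.compartment_model <- function(x, ...) {
  k <- -diag(x$B)
  cat(sprintf("<compartment_model: %d pools (%s), depth %s, %s>\n",
              length(x$u), paste(x$pool_names, collapse = ", "),
              x$depth, x$treatment))
  cat("  decay rates (yr-1):", paste(signif(k, 4), collapse = ", "), "\n")
  cat("  inputs (g C m-2 yr-1):", paste(signif(x$u, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Steady-state carbon stocks
#'
#' Solves `0 = u + B x` for the equilibrium stocks `x* = -B^-1 u`.
#'
#' @param model a [compartment_model()].
#' @return Named vector of stocks, g C m-2 (all positive for a valid model).
#' @export
steady_state_stocks <- function(model) {
  stopifnot(inherits(model, "compartment_model"))
  x <- tryCatch(solve(-model$B, model$u),
                error = function(e) stop("singular compartmental matrix"))
  stats::setNames(as.numeric(x), model$pool_names)
}

## matrix exponential as a plain matrix
expm_mat <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Forward Delta-14C trajectories of a compartment model
#'
#' Solves the pool 14C balance `dm/dt = u F_atm(t) + (B - lambda I) m` (m =
#' fraction-modern-weighted stock) against an atmospheric forcing curve,
#' with radioactive decay `lambda = 1/8267` yr-1 and initialization at
#' equilibrium with the pre-bomb curve level at the start of the span. The
#' 12C stocks are held at steady state. Integration uses an exact
#' exponential integrator for piecewise-linear forcing (eigen-decomposition
#' of `B - lambda I` with a recursive-filter update per mode; a
#' matrix-exponential step loop handles near-degenerate eigenvalues), so the
#' solution is exact for constant forcing.
#'
#' @param model a [compartment_model()].
#' @param curve an [atmospheric_curve()]; years before its support use its
#'   first value (pre-bomb plateau).
#' @param t_span simulation span, decimal years (default 1900-2022).
#' @param step time step, years.
#' @return Data frame: `year` plus one Delta-14C column (per mil) per pool.
#' @export
forward_delta14c <- function(model, curve, t_span = c(1900, 2022),
                             step = 0.2) {
  stopifnot(inherits(model, "compartment_model"),
            inherits(curve, "atmospheric_curve"))
  if (max(curve$years) < t_span[2])
    stop("atmospheric curve support too short for the simulation span")
  n_steps <- ceiling((t_span[2] - t_span[1]) / step)
  years <- t_span[1] + step * (0:n_steps)
  f_atm <- 1 + curve_at(curve, years, rule = "clamp") / 1000
  x_star <- steady_state_stocks(model)
  Bl <- model$B - diag(LAMBDA_14C, length(model$u))
  m0 <- solve(-Bl, model$u * f_atm[1L])
  m <- solve_linear_forced(Bl, model$u, m0, f_atm, step)
  delta <- sweep(m, 2L, x_star, "/") - 1
  out <- data.frame(year = years)
  for (j in seq_along(model$pool_names))
    out[[model$pool_names[j]]] <- 1000 * delta[, j]
  out
}

## Solve dm/dt = A m + u f(t) with f piecewise linear on a uniform grid.
## Returns an (n_steps+1) x npool matrix including the initial state.
solve_linear_forced <- function(A, u, m0, f, h) {
  n <- length(u)
  eg <- eigen(A)
  distinct <- all(abs(diff(sort(Re(eg$values)))) > 1e-9 * max(abs(eg$values)))
  real_ok <- all(abs(Im(eg$values)) < 1e-12)
  N <- length(f) - 1L
  if (distinct && real_ok && rcond(Re(eg$vectors)) > 1e-12) {
    V <- Re(eg$vectors)
    d <- Re(eg$values)
    g <- solve(V, u)
    y0 <- solve(V, m0)
    e <- exp(d * h)
    psi0 <- (e - 1) / d
    psi1 <- -1 / d + (e - 1) / (d^2 * h)
    y <- matrix(0, N + 1L, n)
    dF <- diff(f)
    for (i in seq_len(n)) {
      z <- g[i] * (psi0[i] * f[-(N + 1L)] + psi1[i] * dF)
      y[, i] <- c(y0[i],
                  as.numeric(stats::filter(z, e[i], method = "recursive",
                                           init = y0[i])))
    }
    y %*% t(V)
  } else {
    ## scaling-and-squaring step loop (exact for piecewise-linear forcing)
    E <- expm_mat(A * h)
    Ainv <- solve(A)
    v0 <- Ainv %*% (E - diag(n)) %*% u
    v1 <- (-h * Ainv + Ainv %*% Ainv %*% (E - diag(n))) %*% u / h
    m <- matrix(0, N + 1L, n)
    m[1L, ] <- m0
    cur <- m0
    for (j in seq_len(N)) {
      cur <- E %*% cur + v0 * f[j] + v1 * (f[j + 1L] - f[j])
      m[j + 1L, ] <- cur
    }
    m
  }
}
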