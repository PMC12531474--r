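#' Atmospheric Delta-14C curve
#'
#' A lookup of atmospheric Delta-14C (per mil) against decimal calendar year,
#' evaluable at any year inside its support by linear interpolation. Real
#' records (IntCal-style pre-bomb tables spliced with post-bomb station
#' records) and the package's synthetic bomb curve share this container.
#'
#' @param years numeric vector of decimal calendar years, strictly increasing.
#' @param delta14c Delta-14C values (per mil), same length as `years`.
#' @param provenance `"observational splice"` or `"synthetic"`.
#' @return An object of class `atmospheric_curve`: a list with `years`,
#'   `delta14c`, `provenance`, callable through [curve_at()].
#' @export
atmospheric_curve <- function(years, delta14c, provenance = "observational splice") {
  stopifnot(is.numeric(years), is.numeric(delta14c),
            length(years) == length(delta14c), length(years) >= 2L)
  if (any(diff(years) <= 0)) stop("`years` must be strictly increasing")
  if (anyNA(years) || anyNA(delta14c)) stop("curve contains missing values")
  structure(
    list(years = as.numeric(years), delta14c = as.numeric(delta14c),
         provenance = provenance),
    class = "atmospheric_curve"
  )
}

#' Evaluate an atmospheric curve at decimal years
#'
#' Linear interpolation between knots; evaluation outside the support is an
#' error unless `rule = "clamp"`, which extends the end values (used when an
#' age distribution reaches back beyond the curve start, where the pre-bomb
#' level is effectively constant).
#'
#' @param curve an [atmospheric_curve()].
#' @param year numeric vector of decimal years.
#' @param rule `"strict"` or `"clamp"`.
#' @return Delta-14C (per mil) at `year`.
#' @export
curve_at <- function(curve, year, rule = c("strict", "clamp")) {
  rule <- match.arg(rule)
  stopifnot(inherits(curve, "atmospheric_curve"))
  if (rule == "strict" &&
      (any(year < min(curve$years)) || any(year > max(curve$years)))) {
    stop("year outside atmospheric curve support [",
         min(curve$years), ", ", max(curve$years), "]")
  }
  stats::approx(curve$years, curve$delta14c, xout = year, rule = 2)$y
}

#' @export
print.atmospheric_curve <- function(x, ...) {
  cat(sprintf("<atmospheric_curve: %s, %.1f-%.1f, %d knots>\n",
              x$provenance, min(x$years), max(x$years), length(x$years)))
  invisible(x)
}

#' Splice atmospheric Delta-14C records into one curve
#'
#' Joins a pre-bomb record with one or more post-bomb station records into a
#' single continuous curve, the way composite atmospheric forcing curves are
#' assembled for radiocarbon modelling. Where two sources overlap, the
#' later-period source (later element of `records`) wins. The result is
#' interpolated onto a regular 0.1-year grid.
#'
#' @param records list of data frames with columns `year` and
#'   `delta14c_permil`, ordered from earliest period to latest; each sorted by
#'   year.
#' @param max_gap maximum tolerated gap (years) between consecutive sources.
#' @return An [atmospheric_curve()] with provenance `"observational splice"`.
#' @export
splice_atmospheric_curve <- function(records, max_gap = 2) {
  stopifnot(is.list(records), length(records) >= 1L)
  records <- lapply(records, function(r) {
    r <- as.data.frame(r)
    if (!all(c("year", "delta14c_permil") %in% names(r)))
      stop("each record needs columns `year` and `delta14c_permil`")
    if (is.unsorted(r$year, strictly = TRUE)) stop("record years must be sorted")
    r[, c("year", "delta14c_permil")]
  })
  ## Later sources take precedence: truncate each source at the start of the
  ## next one.
  n <- length(records)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    if (i < n) {
      cutoff <- min(records[[i + 1L]]$year)
      if (min(r$year) < cutoff && max(r$year) < cutoff - max_gap + 1e-9) {
        ## still check the gap below
      }
      r <- r[r$year < cutoff, , drop = FALSE]
    }
    pieces[[i]] <- r
  }
  spliced <- do.call(rbind, pieces)
  gaps <- diff(spliced$year)
  if (any(gaps > max_gap))
    stop(sprintf("temporal gap of %.2f yr between sources exceeds %.1f yr",
                 max(gaps), max_gap))
  grid <- seq(min(spliced$year), max(spliced$year), by = 0.1)
  vals <- stats::approx(spliced$year, spliced$delta14c_permil, xout = grid)$y
  atmospheric_curve(grid, vals, provenance = "observational splice")
}

#' Read an atmospheric curve from a two-column CSV
#'
#' @param path CSV with columns `year, delta14c_permil` (decimal years
#'   accepted).
#' @param provenance provenance tag for the resulting curve.
#' @return An [atmospheric_curve()].
#' @export
read_atmospheric_curve <- function(path, provenance = "observational splice") {
  tab <- load_table(path, "atmospheric_curve")
  o <- order(tab$year)
  atmospheric_curve(tab$year[o], tab$delta14c_permil[o], provenance = provenance)
}
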