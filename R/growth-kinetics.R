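#' Maximum specific growth rate from an OD600 time series
#'
#' The classical rolling log-linear estimator: the natural logarithm of the
#' blank-corrected OD is regressed on time in every contiguous window of
#' `windowPoints` readings, and `mu_max` is the largest fitted slope.
#' Windows containing non-positive blank-corrected readings are skipped.
#'
#' @param curve data.frame with columns `time_h` (strictly increasing,
#'   hours) and `od600`, e.g. from [generateGrowthCurve()] or a plain CSV.
#' @param windowPoints Window width in readings (>= 3; default 5).
#' @param blank OD offset subtracted before the log transform.
#' @return List of class `growthRateEstimate`: `mu_max` (per hour),
#'   `window` (`c(t_start, t_end)` of the winning window) and `r_squared`
#'   of the winning within-window fit.
#' @examples
#' gc <- generateGrowthCurve("exponential", mu = 0.6, od0 = 0.02)
#' growthRate(gc)$mu_max
#' @export
growthRate <- function(curve, windowPoints = 5, blank = 0) {
  if (!all(c("time_h", "od600") %in% names(curve)))
    stop("curve needs columns 'time_h' and 'od600'")
  if (windowPoints < 3) stop("windowPoints must be >= 3")
  t <- curve$time_h
  if (any(diff(t) <= 0)) stop("time_h must be strictly increasing")
  y <- curve$od600 - blank
  usable <- y > 0
  if (sum(usable) < windowPoints)
    stop("fewer usable (blank-corrected > 0) readings than the window width")
  ly <- ifelse(usable, log(pmax(y, .Machine$double.xmin)), NA_real_)
  n <- length(t)
  best <- list(mu = -Inf, window = c(NA_real_, NA_real_), r2 = NA_real_)
  for (i in seq_len(n - windowPoints + 1L)) {
    ix <- i:(i + windowPoints - 1L)
    if (any(!usable[ix])) next
    tw <- t[ix]; lw <- ly[ix]
    tc <- tw - mean(tw); lc <- lw - mean(lw)
    sxx <- sum(tc^2)
    slope <- sum(tc * lc) / sxx
    if (slope > best$mu) {
      sst <- sum(lc^2)
      r2 <- if (sst > 0) (sum(tc * lc)^2 / sxx) / sst else 1
      best <- list(mu = slope, window = c(tw[1], tw[windowPoints]), r2 = r2)
    }
  }
  if (!is.finite(best$mu)) stop("no usable window found")
  structure(list(mu_max = best$mu, window = best$window,
                 r_squared = best$r2),
            class = "growthRateEstimate")
}

#' @export
print.growthRateEstimate <- function(x, ...) {
  cat(sprintf("mu_max = %.4f / h  (window %.2f-%.2f h, R^2 = %.3f)\n",
              x$mu_max, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Cumulative cell divisions across serial passages
#'
#' Standard adaptive-laboratory-evolution bookkeeping: the divisions in one
#' passage equal the net new cells (final minus inoculum), and the
#' cumulative count is their running sum. Cell numbers may be given
#' directly (`inoculum_cells`, `final_cells`) or derived from ODs
#' (`od_start`, `od_end`, `volume_ml`) via a cells-per-OD-per-mL
#' conversion.
#'
#' @param passages data.frame with either `inoculum_cells`/`final_cells`
#'   or `od_start`/`od_end`/`volume_ml` columns.
#' @param cellsPerOD Conversion factor, cells per OD unit per mL (default
#'   8e8), used only for the OD layout.
#' @return data.frame with columns `passage`, `divisions`, `ccd` (running
#'   cumulative cell divisions).
#' @examples
#' cumulativeCellDivisions(data.frame(inoculum_cells = 1, final_cells = 8))
#' @export
cumulativeCellDivisions <- function(passages, cellsPerOD = 8e8) {
  if (all(c("inoculum_cells", "final_cells") %in% names(passages))) {
    n0 <- passages$inoculum_cells
    nf <- passages$final_cells
  } else if (all(c("od_start", "od_end", "volume_ml") %in% names(passages))) {
    n0 <- passages$od_start * passages$volume_ml * cellsPerOD
    nf <- passages$od_end * passages$volume_ml * cellsPerOD
  } else {
    stop("passages needs inoculum_cells/final_cells or ",
         "od_start/od_end/volume_ml columns")
  }
  if (any(n0 <= 0)) stop("inoculum cell counts must be positive")
  if (any(nf < n0)) stop("final cells must be >= inoculum cells")
  div <- nf - n0
  data.frame(passage = seq_along(div), divisions = div, ccd = cumsum(div))
}

# Monotone piecewise-cubic Hermite interpolant (PCHIP): node slopes are the
# Fritsch-Butland weighted harmonic means of adjacent secants (zero across
# sign changes or flats), which keeps every slope within three times the
# smaller neighbouring secant -- the sufficient condition for monotonicity
# on each interval. Endpoints use the standard one-sided three-point rule,
# clamped into the monotone region.
.pchip <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  d <- diff(y) / h
  m <- numeric(n)
  edge <- function(h1, h2, d1, d2) {
    s <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (d1 == 0 || sign(s) != sign(d1)) return(0)
    if (sign(d1) != sign(d2) && abs(s) > 3 * abs(d1)) return(3 * d1)
    s
  }
  for (i in seq(2, n - 1)) {
    if (d[i - 1] * d[i] <= 0) m[i] <- 0
    else {
      w1 <- 2 * h[i] + h[i - 1]
      w2 <- h[i] + 2 * h[i - 1]
      m[i] <- (w1 + w2) / (w1 / d[i - 1] + w2 / d[i])
    }
  }
  m[1] <- edge(h[1], h[2], d[1], d[2])
  m[n] <- edge(h[n - 1], h[n - 2], d[n - 1], d[n - 2])
  function(xq) {
    i <- findInterval(xq, x, all.inside = TRUE)
    t <- (xq - x[i]) / h[i]
    t2 <- t * t; t3 <- t2 * t
    (2 * t3 - 3 * t2 + 1) * y[i] + (t3 - 2 * t2 + t) * h[i] * m[i] +
      (-2 * t3 + 3 * t2) * y[i + 1] + (t3 - t2) * h[i] * m[i + 1]
  }
}

#' Monotone cubic spline fit of fitness versus cumulative divisions
#'
#' Fits a smooth, monotone non-decreasing cubic curve to fitness (growth
#' rate) against cumulative cell divisions: values at tied x are averaged,
#' y is projected onto the nearest non-decreasing sequence (isotonic
#' regression, so locally decreasing noise cannot bend the curve downward)
#' and a monotonicity-preserving piecewise-cubic Hermite interpolant
#' (PCHIP with Fritsch--Butland slope limiting) is drawn through the
#' projected points. The result is continuously differentiable and
#' non-decreasing on the whole fitted range.
#'
#' @param x Cumulative cell divisions (any non-decreasing abscissa).
#' @param y Fitness values (e.g. per-hour growth rates), same length.
#' @return List of class `monotoneSplineFit`: `fun` (vectorised evaluator),
#'   `knots` (data.frame x, y of the projected points fitted through) and
#'   `range`.
#' @examples
#' fit <- fitMonotoneSpline(c(0, 1, 2), c(0.30, 0.29, 0.50))
#' fit$fun(seq(0, 2, length.out = 5))
#' @export
fitMonotoneSpline <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (anyDuplicated(x)) {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
    if (length(x) < 3) stop("fewer than 3 distinct x values")
  }
  iso <- stats::isoreg(x, y)
  yf <- iso$yf
  f <- .pchip(x, yf)
  structure(list(fun = f, knots = data.frame(x = x, y = yf),
                 range = range(x)),
            class = "monotoneSplineFit")
}

#' @export
print.monotoneSplineFit <- function(x, ...) {
  cat(sprintf("Monotone cubic fit through %d knots on [%g, %g]\n",
              nrow(x$knots), x$range[1], x$range[2]))
  invisible(x)
}

#' Assemble an ALE fitness trajectory
#'
#' Pairs passage-wise cumulative cell divisions with measured fitness
#' (growth rates) and attaches the monotone spline fit, the machinery used
#' to summarise fitness gains over an adaptive laboratory evolution
#' experiment.
#'
#' @param passages As in [cumulativeCellDivisions()].
#' @param fitness Per-passage growth rates (per hour), same number of rows.
#' @param cellsPerOD Passed to [cumulativeCellDivisions()].
#' @return List of class `aleTrajectory`: `trajectory` (data.frame passage,
#'   ccd, fitness, spline_eval) and `spline` (a `monotoneSplineFit`).
#' @export
aleTrajectory <- function(passages, fitness, cellsPerOD = 8e8) {
  ccd <- cumulativeCellDivisions(passages, cellsPerOD = cellsPerOD)
  if (length(fitness) != nrow(ccd))
    stop("fitness must have one value per passage")
  fit <- fitMonotoneSpline(ccd$ccd, fitness)
  traj <- data.frame(passage = ccd$passage, ccd = ccd$ccd,
                     fitness = fitness, spline_eval = fit$fun(ccd$ccd))
  structure(list(trajectory = traj, spline = fit), class = "aleTrajectory")
}

#' @export
print.aleTrajectory <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("ALE trajectory: %d passages, %.3g cumulative divisions, ",
              nrow(tr), tr$ccd[nrow(tr)]))
  cat(sprintf("fitness %.3f -> %.3f /h\n", tr$fitness[1],
              tr$fitness[nrow(tr)]))
  invisible(x)
}
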