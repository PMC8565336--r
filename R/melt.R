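## UV melting curves: two-state simulation, smoothing, first-derivative
## Tm estimation, and Delta-Tm / DeltaDelta-Tm bookkeeping.

.R_KJ <- 8.31446e-3  # gas constant, kJ/mol/K

#' Two-state melt model parameters
#'
#' Parameters of the bimolecular two-state (all-or-none) duplex melting
#' model used by the simulator. `dH` and `dS` are the standard van't
#' Hoff enthalpy (kJ/mol) and entropy (kJ/mol/K) of duplex *formation*
#' (both negative for a stable duplex); `CT` is the total strand
#' concentration (mol/L). Linear upper/lower absorbance baselines
#' represent the single- and double-stranded extinction envelopes.
#'
#' @param dH Formation enthalpy, kJ/mol (negative).
#' @param dS Formation entropy, kJ/mol/K. Default: chosen via
#'   [entropy_for_tm()] so the alpha = 1/2 midpoint sits at `tm`.
#' @param tm Target midpoint (deg C) used only when `dS` is missing.
#' @param CT Total strand concentration, mol/L (default 1e-6, the
#'   conventional melt concentration variable for conjugate duplexes
#'   measured at 1 uM).
#' @param self_complementary Is the duplex formed from one
#'   self-complementary strand?
#' @param lower_intercept,lower_slope,upper_intercept,upper_slope
#'   Baseline parameters (absorbance units; slopes per deg C).
#' @return List of class `melt_params`.
#' @export
melt_params <- function(dH = -670, dS = NULL, tm = 65, CT = 1e-6,
                        self_complementary = FALSE,
                        lower_intercept = 0.60, lower_slope = 2e-4,
                        upper_intercept = 0.75, upper_slope = 6e-4) {
  stopifnot(dH < 0, CT > 0)
  if (is.null(dS)) dS <- entropy_for_tm(dH, tm, CT, self_complementary)
  stopifnot(dS < 0)
  structure(list(dH = dH, dS = dS, CT = CT,
                 self_complementary = self_complementary,
                 lower_intercept = lower_intercept, lower_slope = lower_slope,
                 upper_intercept = upper_intercept, upper_slope = upper_slope),
            class = "melt_params")
}

#' Entropy that places the two-state midpoint at a given Tm
#'
#' Inverts the closed-form midpoint `Tm = dH / (dS + R log(CT/4))`
#' (non-self-complementary; `log(CT)` for self-complementary strands).
#'
#' @inheritParams melt_params
#' @param tm Midpoint in deg C.
#' @export
entropy_for_tm <- function(dH, tm, CT, self_complementary = FALSE) {
  conc <- if (self_complementary) CT else CT / 4
  dH / (tm + 273.15) - .R_KJ * log(conc)
}

#' Analytic two-state midpoint
#'
#' The temperature at which half of the strands are single-stranded:
#' `Tm = dH / (dS + R log(CT/4))` for a non-self-complementary duplex
#' (`log(CT)` if self-complementary), returned in deg C.
#'
#' @param params A [melt_params()] object.
#' @export
two_state_tm <- function(params) {
  conc <- if (params$self_complementary) params$CT else params$CT / 4
  params$dH / (params$dS + .R_KJ * log(conc)) - 273.15
}

#' Fraction of single strands at given temperatures
#'
#' Solves the two-state equilibrium at total strand concentration `CT`.
#' For a non-self-complementary duplex with equimolar strands the
#' association constant obeys `Ka = 2 (1 - alpha) / (alpha^2 CT)`, so
#' `alpha(Tm) = 1/2` exactly at the closed-form midpoint.
#'
#' @param params A [melt_params()] object.
#' @param temp_c Temperatures, deg C.
#' @return Numeric vector of alpha in (0, 1].
#' @export
melt_fraction_ss <- function(params, temp_c) {
  TK <- temp_c + 273.15
  lnKa <- -(params$dH - TK * params$dS) / (.R_KJ * TK)
  ## guard against overflow deep below the transition
  lnKa <- pmin(lnKa, 600)
  b <- exp(lnKa) * params$CT
  if (params$self_complementary) {
    ## A2 <-> 2A with [A] = alpha CT: Ka = (1 - alpha) / (2 alpha^2 CT)
    alpha <- (-1 + sqrt(1 + 8 * b)) / (4 * b)
  } else {
    alpha <- (-1 + sqrt(1 + 2 * b)) / b
  }
  ## series expansion for tiny b where the quadratic cancels
  small <- b < 1e-8
  alpha[small] <- 1 - (if (params$self_complementary) 2 else 0.5) * b[small]
  alpha
}

#' Construct a melting curve
#'
#' @param temperature Strictly increasing temperature grid, deg C,
#'   length >= 10.
#' @param absorbance Absorbance at 260 nm, same length.
#' @param label Trace label.
#' @return Object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, absorbance, label = "trace") {
  temperature <- as.numeric(temperature)
  absorbance <- as.numeric(absorbance)
  if (length(temperature) != length(absorbance))
    stop("temperature and absorbance must have equal length")
  if (length(temperature) < 10L)
    stop("melting curve needs at least 10 points")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  structure(list(temperature = temperature, absorbance = absorbance,
                 label = label), class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> '%s': %d points, %.1f-%.1f degC\n", x$label,
              length(x$temperature), min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Simulate a two-state UV melting curve
#'
#' Absorbance is the lower (duplex) baseline plus the single-strand
#' fraction times the baseline separation:
#' `A(T) = L(T) + alpha(T) (U(T) - L(T))`. Deterministic; add noise
#' separately if wanted (see [simulate_melt_replicates()]).
#'
#' @param params A [melt_params()] object.
#' @param temperature Temperature grid, deg C (default 15-90 in 0.5
#'   steps, mirroring a 1 deg C/min heating ramp sampled twice per
#'   degree).
#' @param label Trace label.
#' @return A [melt_curve()].
#' @export
simulate_melt_curve <- function(params, temperature = seq(15, 90, by = 0.5),
                                label = "simulated") {
  stopifnot(inherits(params, "melt_params"))
  if (any(temperature < -90) || any(temperature > 150))
    stop("temperature grid outside the physical range of an aqueous melt")
  a <- melt_fraction_ss(params, temperature)
  lower <- params$lower_intercept + params$lower_slope * temperature
  upper <- params$upper_intercept + params$upper_slope * temperature
  melt_curve(temperature, lower + a * (upper - lower), label = label)
}

#' Local-polynomial smoothing of a melting curve
#'
#' Fits a polynomial of the given degree in a centred sliding window of
#' `window` points and evaluates it at the window centre. Near the ends
#' the window shrinks symmetrically-as-possible rather than padding, so
#' `window = 1` is the identity and a constant curve is returned
#' unchanged.
#'
#' @param curve A [melt_curve()].
#' @param window Odd window length in points (default 11).
#' @param degree Polynomial degree (default 2).
#' @return The smoothed [melt_curve()].
#' @export
smooth_curve <- function(curve, window = 11L, degree = 2L) {
  stopifnot(inherits(curve, "melt_curve"))
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  n <- length(curve$temperature)
  if (window > n) stop("smoothing window longer than the curve")
  if (window == 1L) return(curve)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    tt <- curve$temperature[lo:hi] - curve$temperature[i]
    yy <- curve$absorbance[lo:hi]
    deg <- min(degree, length(tt) - 1L)
    X <- outer(tt, 0:deg, `^`)
    fit <- stats::lm.fit(X, yy)
    out[i] <- fit$coefficients[[1L]]
  }
  melt_curve(curve$temperature, out, label = curve$label)
}

#' First-derivative melting temperature
#'
#' The standard first-derivative method: the curve is smoothed
#' ([smooth_curve()]), dA/dT is computed by central differences, and Tm
#' is the location of the interior derivative maximum refined by a
#' quadratic fit through the three points around the discrete maximum.
#' A maximum on the grid boundary means the transition was not captured
#' and raises an error. Ties between equal discrete maxima resolve to
#' the lower temperature (with a message).
#'
#' @param curve A [melt_curve()].
#' @param window,degree Smoothing settings, see [smooth_curve()].
#' @return Object of class `tm_fit`: list with `tm` (deg C), `window`,
#'   `degree`, `curve`, `smoothed`, and the derivative trace
#'   (`deriv_temperature`, `deriv`).
#' @export
tm_from_curve <- function(curve, window = 11L, degree = 2L) {
  stopifnot(inherits(curve, "melt_curve"))
  sm <- smooth_curve(curve, window = window, degree = degree)
  tt <- sm$temperature; aa <- sm$absorbance
  n <- length(tt)
  idx <- 2:(n - 1L)
  dAdT <- (aa[idx + 1L] - aa[idx - 1L]) / (tt[idx + 1L] - tt[idx - 1L])
  dT <- tt[idx]
  imax <- which(dAdT == max(dAdT))
  if (length(imax) > 1L) {
    message("tm_from_curve: tie between equal derivative maxima; ",
            "taking the lower temperature")
    imax <- imax[[1L]]
  }
  if (imax == 1L || imax == length(dT))
    stop("transition not captured: derivative maximum at the grid boundary")
  x <- dT[(imax - 1L):(imax + 1L)]
  y <- dAdT[(imax - 1L):(imax + 1L)]
  ## vertex of the parabola through three points
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) + x[1] * (y[3] - y[2])) / denom
  B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) + x[1]^2 * (y[2] - y[3])) / denom
  tm <- if (A < 0) -B / (2 * A) else x[2]
  structure(list(tm = tm, window = window, degree = degree, curve = curve,
                 smoothed = sm, deriv_temperature = dT, deriv = dAdT),
            class = "tm_fit")
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("<tm_fit> Tm = %.2f degC (first-derivative, window %d, degree %d)\n",
              x$tm, x$window, x$degree))
  invisible(x)
}

#' @method plot tm_fit
#' @export
plot.tm_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$curve$temperature, x$curve$absorbance, type = "p",
                 pch = 20, cex = 0.4, col = "grey50",
                 xlab = "temperature (degC)", ylab = "A260",
                 main = x$curve$label, ...)
  graphics::lines(x$smoothed$temperature, x$smoothed$absorbance, col = "blue3")
  graphics::abline(v = x$tm, lty = 2)
  graphics::plot(x$deriv_temperature, x$deriv, type = "l",
                 xlab = "temperature (degC)", ylab = "dA/dT")
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Tm from replicate melting curves
#'
#' Applies [tm_from_curve()] to each replicate trace and reports the
#' per-replicate values with their mean, mirroring the convention of
#' reporting the average of at least two independent measurements.
#'
#' @param curves List of [melt_curve()] objects.
#' @inheritParams tm_from_curve
#' @return List of class `tm_result`: `tm` (mean), `replicates`
#'   (per-curve values), `window`, `degree`.
#' @export
tm_replicates <- function(curves, window = 11L, degree = 2L) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  reps <- vapply(curves, function(cv)
    tm_from_curve(cv, window = window, degree = degree)$tm, numeric(1))
  structure(list(tm = mean(reps), replicates = reps,
                 window = window, degree = degree),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> mean Tm = %.2f degC over %d replicate(s): %s\n",
              x$tm, length(x$replicates),
              paste(sprintf("%.2f", x$replicates), collapse = ", ")))
  invisible(x)
}

#' Delta-Tm / DeltaDelta-Tm table
#'
#' For each duplex with a parent, `delta_tm = Tm - Tm(parent)`; for
#' each duplex with a reference (the native-GNA sibling of an
#' isonucleotide duplex), `ddelta_tm = delta_tm - delta_tm(reference)`.
#' Parents carry `NA` in the delta column; duplexes without a reference
#' carry `NA` in the ddelta column. Full precision is kept in
#' `delta_tm`/`ddelta_tm`; display columns rounded to 0.1 deg C are
#' appended as `delta_tm_r`/`ddelta_tm_r`.
#'
#' @param tm Data frame with columns `duplex_id` and `tm_c`, e.g.
#'   [galnac_duplex_tm()] or [tm_replicates()] output assembled by the caller.
#' @param parent_map Named character vector `duplex_id -> parent_id`
#'   (or data frame columns `duplex_id`, `parent_id`); `NA` for
#'   parents.
#' @param reference_map Same shape, mapping isonucleotide duplexes to
#'   their native-modification reference.
#' @return Data frame with columns `duplex_id`, `tm_c`, `parent_id`,
#'   `delta_tm`, `reference_id`, `ddelta_tm`, `delta_tm_r`,
#'   `ddelta_tm_r`.
#' @examples
#' tab <- galnac_duplex_tm()
#' delta_tm_table(tab)
#' @export
delta_tm_table <- function(tm, parent_map = NULL, reference_map = NULL) {
  stopifnot(all(c("duplex_id", "tm_c") %in% names(tm)))
  as_map <- function(m, col) {
    if (is.null(m)) {
      if (!col %in% names(tm)) return(NULL)
      return(stats::setNames(tm[[col]], tm$duplex_id))
    }
    if (is.data.frame(m)) return(stats::setNames(m[[col]], m$duplex_id))
    m
  }
  parent_map <- as_map(parent_map, "parent_id")
  reference_map <- as_map(reference_map, "reference_id")
  if (is.null(parent_map))
    stop("delta_tm_table: no parent map supplied or found in `tm`")
  tmv <- stats::setNames(tm$tm_c, tm$duplex_id)
  parent <- unname(parent_map[tm$duplex_id])
  no_parent <- is.na(parent)
  missing_parent <- !no_parent & !(parent %in% names(tmv))
  if (any(missing_parent))
    stop("delta_tm_table: missing parent Tm for duplex ",
         paste(tm$duplex_id[missing_parent], collapse = ", "))
  delta <- ifelse(no_parent, NA_real_, tm$tm_c - tmv[parent])
  dmap <- stats::setNames(delta, tm$duplex_id)
  refid <- if (is.null(reference_map)) rep(NA_character_, nrow(tm)) else
    unname(reference_map[tm$duplex_id])
  no_ref <- is.na(refid)
  missing_ref <- !no_ref & !(refid %in% names(dmap))
  if (any(missing_ref))
    stop("delta_tm_table: missing reference delta for duplex ",
         paste(tm$duplex_id[missing_ref], collapse = ", "))
  ddelta <- ifelse(no_ref, NA_real_, delta - dmap[refid])
  data.frame(duplex_id = tm$duplex_id, tm_c = tm$tm_c,
             parent_id = parent, delta_tm = unname(delta),
             reference_id = refid, ddelta_tm = unname(ddelta),
             delta_tm_r = round(unname(delta), 1),
             ddelta_tm_r = round(unname(ddelta), 1),
             stringsAsFactors = FALSE)
}
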