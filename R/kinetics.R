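# Force-channel processing: spring-platform voltage-to-force calibration,
# 50 Hz mains removal, and decimation to the kinematic rate.

#' Fit a voltage-to-force calibration curve
#'
#' Implements the spring-platform procedure: during each repetition the
#' fingertip sensor presses a platform against a spring of known constant, so
#' the applied force is `k * displacement`. The three repetitions are pooled,
#' averaged on a common voltage grid, and monotonized with isotonic
#' regression into a non-decreasing piecewise-linear voltage -> newton map
#' anchored at 0 N for the baseline voltage.
#'
#' @param rec a `grasp_calibration_recording` (see [generate_calibration()]
#'   or [read_calibration_csv()]): list with `finger`, `repetitions` (data
#'   frames with columns `voltage`, `displacement_mm`) and `spring_constant`.
#' @param n_grid number of voltage grid points of the fitted curve.
#' @return an object of class `grasp_calibration`: list with `finger`,
#'   `voltage` (grid, V), `force` (fitted, N) and `range` (valid voltages).
#' @export
fit_calibration <- function(rec, n_grid = 101) {
  if (is.null(rec$repetitions) || length(rec$repetitions) < 1)
    stop_graspid("graspid_calibration_error", "no calibration repetitions")
  k <- rec$spring_constant
  if (is.null(k) || k <= 0)
    stop_graspid("graspid_calibration_error", "spring constant must be > 0")

  reps <- lapply(rec$repetitions, function(d) {
    data.frame(voltage = d$voltage, force = k * d$displacement_mm)
  })
  rng <- vapply(reps, function(d) range(d$voltage), numeric(2))
  v_lo <- min(rng[1, ]); v_hi <- max(rng[2, ])
  if (v_hi - v_lo < 1e-12) {
    # degenerate: platform never moved and the sensor sat at baseline
    return(structure(list(finger = rec$finger, voltage = c(v_lo, v_lo + 1e-9),
                          force = c(0, 0), range = c(v_lo, v_hi)),
                     class = "grasp_calibration"))
  }
  if (length(reps) > 1 && max(rng[1, ]) >= min(rng[2, ]))
    stop_graspid("graspid_calibration_error",
                 "calibration repetitions cover non-overlapping voltage ranges")

  grid <- seq(v_lo, v_hi, length.out = n_grid)
  interp <- vapply(reps, function(d) {
    d <- d[order(d$voltage), ]
    # collapse duplicate voltages before interpolation
    d <- aggregate(force ~ voltage, d, mean)
    approx(d$voltage, d$force, xout = grid, rule = 1)$y
  }, numeric(n_grid))
  force <- rowMeans(interp, na.rm = TRUE)
  force[is.nan(force)] <- NA
  # extend with nearest defined value (can only happen at the extremes)
  force <- approx(grid[!is.na(force)], force[!is.na(force)], xout = grid,
                  rule = 2)$y
  iso <- isoreg(grid, force)
  force <- pmax(iso$yf - iso$yf[1], 0)
  structure(list(finger = rec$finger, voltage = grid, force = force,
                 range = c(v_lo, v_hi)),
            class = "grasp_calibration")
}

#' @export
print.grasp_calibration <- function(x, ...) {
  cat(sprintf("Calibration curve (%s): %.3f-%.3f V -> 0-%.2f N (%d grid points)\n",
              x$finger %||% "?", x$range[1], x$range[2], max(x$force),
              length(x$voltage)))
  invisible(x)
}

#' Remove 50 Hz mains interference from force channels
#'
#' Zero-phase 2nd-order Butterworth bandstop (default 48-52 Hz notch)
#' applied per channel.
#'
#' @param force_block numeric vector or `samples x channels` matrix (V).
#' @param stop_hz centre of the stop band (Hz).
#' @param rate_hz sampling rate (Hz); must exceed `2 * stop_hz`.
#' @param half_width half-width of the stop band (Hz).
#' @return filtered block, same shape.
#' @export
bandstop_mains <- function(force_block, stop_hz = 50, rate_hz = 960,
                           half_width = 2) {
  if (rate_hz <= 2 * stop_hz)
    stop_graspid("graspid_config_error",
                 "sampling rate %g Hz must exceed twice the stop frequency %g Hz",
                 rate_hz, stop_hz)
  filt <- signal::butter(2, c(stop_hz - half_width, stop_hz + half_width) /
                           (rate_hz / 2), "stop")
  if (is.matrix(force_block)) {
    out <- force_block
    for (j in seq_len(ncol(force_block)))
      out[, j] <- .zerophase(filt, force_block[, j])
    out
  } else {
    .zerophase(filt, force_block)
  }
}

#' Decimate force channels to the kinematic rate
#'
#' Anti-aliased decimation by the integer rate ratio (960/120 = 8 in the
#' reference design): zero-phase low-pass at 80% of the target Nyquist
#' frequency, then subsampling. Trailing samples short of a full block are
#' truncated, so the output length is `floor(n / factor)`.
#'
#' @param force_block numeric vector or `samples x channels` matrix.
#' @param factor integer decimation factor.
#' @return decimated block.
#' @export
downsample_to_kinematic_rate <- function(force_block, factor = 8) {
  if (factor < 1 || factor != round(factor))
    stop_graspid("graspid_config_error", "decimation factor must be an integer >= 1")
  if (factor == 1) return(force_block)
  dec1 <- function(x) {
    filt <- signal::butter(6, 0.8 / factor, "low")
    y <- .zerophase(filt, x)
    y[seq.int(1L, by = factor, length.out = floor(length(x) / factor))]
  }
  if (is.matrix(force_block)) {
    out <- apply(force_block, 2, dec1)
    colnames(out) <- colnames(force_block)
    out
  } else dec1(force_block)
}

#' Convert force-channel voltages to newtons
#'
#' Elementwise application of a fitted monotone calibration curve. Voltages
#' outside the calibrated range are clamped to the curve endpoints with a
#' warning (sensor drift beyond the calibration should degrade, not crash).
#'
#' @param curve a `grasp_calibration` from [fit_calibration()], or a named
#'   list of curves (one per channel/column of `force_block_volts`).
#' @param force_block_volts numeric vector or `samples x channels` matrix (V).
#' @return forces in newtons, same shape, non-negative.
#' @export
voltage_to_force <- function(curve, force_block_volts) {
  if (is.matrix(force_block_volts) && !inherits(curve, "grasp_calibration")) {
    cn <- colnames(force_block_volts) %||% names(curve)[seq_len(ncol(force_block_volts))]
    out <- force_block_volts
    for (j in seq_len(ncol(out))) {
      cc <- curve[[cn[j]]]
      if (is.null(cc))
        stop_graspid("graspid_calibration_error",
                     "no calibration curve for channel '%s'", cn[j])
      out[, j] <- voltage_to_force(cc, force_block_volts[, j])
    }
    return(out)
  }
  if (!inherits(curve, "grasp_calibration"))
    stop_graspid("graspid_calibration_error", "curve must be a grasp_calibration")
  v <- as.numeric(force_block_volts)
  # small excursions (sensor noise / filter ringing around baseline) are
  # clamped silently; only drift beyond 2% of the calibrated span warns
  span <- diff(curve$range)
  tol <- 0.02 * span
  n_out <- if (span < 1e-9) 0 else
    sum(v < curve$range[1] - tol | v > curve$range[2] + tol)
  if (n_out > 0)
    warning(sprintf("%d voltage sample(s) outside the calibrated range %.3f-%.3f V were clamped",
                    n_out, curve$range[1], curve$range[2]))
  out <- approx(curve$voltage, curve$force, xout = pmin(pmax(v, curve$range[1]),
                                                        curve$range[2]),
                rule = 2)$y
  out <- pmax(out, 0)
  if (is.matrix(force_block_volts))
    out <- matrix(out, nrow(force_block_volts),
                  dimnames = dimnames(force_block_volts))
  out
}
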