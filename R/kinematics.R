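# Joint-angle extraction from labeled hand markers.
#
# Ten angles per trial: for each finger, theta1 = angle between the palm-
# plane normal and the line from the palm-marker centroid to the finger's
# proximal-phalange marker (thumb: metacarpal marker), and theta2 = flexion
# angle between the successive phalange segment directions (0 deg = straight
# finger, flexion increases the angle).

# zero-phase forward-backward IIR filtering with odd-reflection edge padding
# and steady-state initial conditions, so edge transients (including the
# long ring of narrow notch filters) do not leak into the series
.zerophase <- function(filt, x) {
  b <- filt$b; a <- filt$a
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  nfact <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= nfact + 1)
    stop_graspid("graspid_short_input_error",
                 "series of length %d too short for zero-phase filtering (need > %d)",
                 n, nfact + 1)
  # run the filter from its steady-state response to a step of the first
  # sample (previous inputs x0, previous outputs kdc * x0)
  kdc <- sum(b) / sum(a)
  run <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init = rep(kdc * v[1], nfilt - 1),
                              init.x = rep(v[1], nfilt - 1)))
  }
  ext <- c(2 * x[1] - x[(nfact + 1):2], x, 2 * x[n] - x[(n - 1):(n - nfact)])
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[(nfact + 1):(nfact + n)]
}

#' Low-pass filter marker trajectories
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass applied to
#' every marker coordinate, the standard 15 Hz trajectory smoothing for
#' optical motion capture at 120 Hz. Zero-phase application avoids the phase
#' lag that would shift the detected phase boundaries.
#'
#' @param marker_block a `frames x 3 x n_markers` array (mm), or a
#'   `grasp_trial` whose `marker_block` should be filtered.
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param rate_hz sampling rate (Hz); must exceed `2 * cutoff_hz`.
#' @return the filtered block, same shape (or the trial with the block
#'   replaced).
#' @export
lowpass_trajectories <- function(marker_block, cutoff_hz = 15, rate_hz = 120) {
  if (inherits(marker_block, "grasp_trial")) {
    trial <- marker_block
    trial$marker_block <- lowpass_trajectories(trial$marker_block, cutoff_hz,
                                               trial$kinematic_rate)
    return(trial)
  }
  if (rate_hz <= 2 * cutoff_hz)
    stop_graspid("graspid_config_error",
                 "sampling rate %g Hz must exceed twice the cutoff %g Hz",
                 rate_hz, cutoff_hz)
  filt <- signal::butter(4, cutoff_hz / (rate_hz / 2), "low")
  out <- marker_block
  for (m in seq_len(dim(marker_block)[3]))
    for (k in 1:3) out[, k, m] <- .zerophase(filt, marker_block[, k, m])
  out
}

#' Palm reference frame from the three palm markers
#'
#' @param palm_markers a 3 x 3 matrix, one palm marker per row (mm).
#' @return list with `centroid` (mm) and unit `normal`; the normal's sign is
#'   fixed by the marker labelling order (right-handed cross product of the
#'   first two palm edges).
#' @export
#' @examples
#' palm_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
palm_frame <- function(palm_markers) {
  if (!is.matrix(palm_markers) || any(dim(palm_markers) != c(3, 3)))
    stop_graspid("graspid_geometry_error", "palm_markers must be a 3 x 3 matrix")
  e1 <- palm_markers[2, ] - palm_markers[1, ]
  e2 <- palm_markers[3, ] - palm_markers[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  nn <- sqrt(sum(n^2))
  scale <- max(sqrt(sum(e1^2)), sqrt(sum(e2^2)))
  if (scale == 0 || nn < 1e-9 * scale^2)
    stop_graspid("graspid_geometry_error",
                 "palm markers are collinear or coincident; palm plane undefined")
  list(centroid = colMeans(palm_markers), normal = n / nn)
}

# numerically stable angle between two vectors, in degrees
.angle_deg <- function(u, v) {
  cu <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cu^2)), sum(u * v)) * 180 / pi
}

#' Proximal angle theta1 of one finger
#'
#' Angle (degrees, in `[0, 180]`) between the palm-plane normal and the line
#' from the palm-marker centroid to the finger's proximal-phalange marker
#' (for the thumb, its metacarpal marker).
#'
#' @param palm a palm frame from [palm_frame()].
#' @param proximal_marker length-3 coordinate vector (mm).
#' @return angle in degrees.
#' @export
proximal_angle_theta1 <- function(palm, proximal_marker) {
  d <- proximal_marker - palm$centroid
  if (sqrt(sum(d^2)) < 1e-9)
    stop_graspid("graspid_geometry_error",
                 "proximal marker coincides with the palm centroid")
  .angle_deg(palm$normal, d)
}

#' Flexion angle theta2 of one finger
#'
#' Angle (degrees) between the direction proximal -> middle and the
#' direction middle -> distal. A straight finger reads 0 degrees and flexion
#' increases the angle.
#'
#' @param proximal_marker,middle_marker,distal_marker length-3 coordinate
#'   vectors (mm) of consecutive markers along the finger.
#' @return angle in degrees.
#' @export
#' @examples
#' flexion_angle_theta2(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 90
flexion_angle_theta2 <- function(proximal_marker, middle_marker, distal_marker) {
  u <- middle_marker - proximal_marker
  v <- distal_marker - middle_marker
  if (sqrt(sum(u^2)) < 1e-9 || sqrt(sum(v^2)) < 1e-9)
    stop_graspid("graspid_geometry_error", "coincident consecutive finger markers")
  .angle_deg(u, v)
}

#' Extract the ten joint-angle series of a trial
#'
#' Validates marker completeness, optionally low-pass filters the
#' trajectories, and computes theta1/theta2 for every finger at every frame.
#'
#' @param trial a `grasp_trial` (or any list with a `frames x 3 x 20`
#'   `marker_block` with the package's marker naming).
#' @param filter_cutoff_hz low-pass cutoff (Hz); `NULL` disables filtering.
#' @return an object of class `grasp_angles`: list with `angles` (a
#'   `frames x 10` matrix, degrees, columns ordered thumb..pinky x
#'   theta1/theta2), `rate_hz`, and `wrist_speed` (mm/s, from the filtered
#'   wrist-marker midpoint, used later for phase segmentation).
#' @export
extract_joint_angles <- function(trial, filter_cutoff_hz = 15) {
  mb <- trial$marker_block
  rate <- trial$kinematic_rate %||% 120
  if (length(dim(mb)) != 3 || dim(mb)[3] != 20)
    stop_graspid("graspid_missing_data_error",
                 "expected 20 markers, got %s", paste(dim(mb), collapse = " x "))
  bad <- which(!apply(is.finite(mb), 3, all))
  if (length(bad)) {
    m1 <- bad[1]
    frames <- which(!apply(is.finite(mb[, , m1, drop = FALSE]), 1, all))
    stop_graspid("graspid_missing_data_error",
                 "marker '%s' has missing data at frames %d-%d",
                 dimnames(mb)[[3]][m1] %||% as.character(m1),
                 min(frames), max(frames))
  }
  if (!is.null(filter_cutoff_hz)) mb <- lowpass_trajectories(mb, filter_cutoff_hz, rate)

  T_k <- dim(mb)[1]
  nm <- dimnames(mb)[[3]] %||% marker_names()
  idx <- function(name) {
    i <- match(name, nm)
    if (is.na(i)) stop_graspid("graspid_missing_data_error", "marker '%s' absent", name)
    i
  }
  palm_i <- vapply(paste0("palm_", 1:3), idx, 0L)
  wrist_i <- vapply(paste0("wrist_", 1:2), idx, 0L)
  chain <- lapply(FINGERS, function(f) {
    segs <- if (f == "thumb") c("meta", "prox", "dist") else c("prox", "mid", "dist")
    vapply(paste0(f, "_", segs), idx, 0L)
  })

  angles <- matrix(NA_real_, T_k, 10, dimnames = list(NULL, angle_names()))
  for (t in seq_len(T_k)) {
    palm <- palm_frame(rbind(mb[t, , palm_i[1]], mb[t, , palm_i[2]],
                             mb[t, , palm_i[3]]))
    for (f in 1:5) {
      ci <- chain[[f]]
      angles[t, 2 * f - 1] <- proximal_angle_theta1(palm, mb[t, , ci[1]])
      angles[t, 2 * f] <- flexion_angle_theta2(mb[t, , ci[1]], mb[t, , ci[2]],
                                               mb[t, , ci[3]])
    }
  }

  wrist_mid <- (mb[, , wrist_i[1]] + mb[, , wrist_i[2]]) / 2
  vel <- apply(wrist_mid, 2, function(x) c(0, diff(x))) * rate
  speed <- sqrt(rowSums(vel^2))
  # light smoothing of the speed trace to suppress residual marker noise
  speed <- stats::filter(speed, rep(1 / 5, 5), sides = 2)
  speed[is.na(speed)] <- 0

  structure(list(angles = angles, rate_hz = rate,
                 wrist_speed = as.numeric(speed)),
            class = "grasp_angles")
}

#' @export
print.grasp_angles <- function(x, ...) {
  cat(sprintf("Joint-angle series: %d frames x %d angles at %g Hz\n",
              nrow(x$angles), ncol(x$angles), x$rate_hz))
  cat(sprintf("  range: %.1f to %.1f deg\n", min(x$angles), max(x$angles)))
  invisible(x)
}
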