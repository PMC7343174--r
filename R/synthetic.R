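# Synthetic multi-subject grasp recordings.
#
# The generator emulates the study design the analysis assumes: a panel of
# subjects, each grasping several objects repeatedly, recorded as 3-D hand
# marker trajectories (120 Hz) plus five fingertip force-sensor voltage
# channels (960 Hz), with a reach / grasp / release phase structure, stable
# per-subject movement templates, object-dependent grasp shapes, trial-to-
# trial variability, sensor noise and 50 Hz mains interference.

FINGERS <- c("thumb", "index", "middle", "ring", "pinky")

#' Names and order of the 15 trial features
#'
#' Fixed feature order used everywhere downstream: for each finger (thumb,
#' index, middle, ring, pinky) the proximal angle theta1, the flexion angle
#' theta2, and the fingertip normal force.
#'
#' @return character vector of length 15.
#' @export
feature_names <- function() {
  as.vector(t(outer(FINGERS, c("theta1", "theta2", "force"), paste, sep = "_")))
}

angle_names <- function() {
  as.vector(t(outer(FINGERS, c("theta1", "theta2"), paste, sep = "_")))
}

marker_names <- function() {
  finger_m <- as.vector(t(cbind(
    paste0(FINGERS, "_", c("meta", rep("prox", 4))),
    paste0(FINGERS, "_", c("prox", rep("mid", 4))),
    paste0(FINGERS, "_dist"))))
  c(finger_m, paste0("palm_", 1:3), paste0("wrist_", 1:2))
}

marker_roles <- function() {
  c(rep(c("phalange"), 15), rep("palm", 3), rep("wrist", 2))
}

# ---- configuration ----------------------------------------------------------

#' Configuration of the synthetic grasp-recording generator
#'
#' The defaults reproduce the study design the package targets: 31 subjects,
#' 5 objects, 7 trials per object (35 grasps per subject), markers at 120 Hz
#' and force channels at 960 Hz (ratio 8), and a 0.45 N/mm calibration
#' spring. Effect scales are the pointwise standard deviations of the smooth
#' template perturbations: `subject_effect_scale` and `object_effect_scale`
#' are in degrees for the angle templates (force templates use 0.05 N per
#' unit scale), `trial_noise_scale` likewise.
#'
#' @param n_subjects,n_objects,n_trials_per_object study-design counts.
#' @param subject_effect_scale pointwise SD (degrees) of between-subject
#'   angle-template differences.
#' @param trial_noise_scale pointwise SD (degrees) of within-subject
#'   trial-to-trial template deviation.
#' @param object_effect_scale pointwise SD (degrees) of object-dependent
#'   template differences.
#' @param mains_noise_amplitude amplitude (V) of the 50 Hz mains sinusoid on
#'   the force channels.
#' @param sensor_noise_sd SD (V) of white force-sensor noise.
#' @param marker_noise_sd SD (mm) of white marker-coordinate noise.
#' @param kinematic_rate,force_rate sampling rates (Hz); the force rate must
#'   be an integer multiple of the kinematic rate.
#' @param phase_duration_ranges list with elements `reach`, `grasp`,
#'   `release`, each a length-2 range (s) from which per-subject mean phase
#'   durations are drawn.
#' @param spring_constant calibration spring constant (N/mm).
#' @param hand_size_mean,hand_size_sd population distribution (mm) of hand
#'   size (wrist to middle-fingertip).
#' @param seed master seed; every subject/trial stream is derived from it.
#' @return an object of class `grasp_config`.
#' @export
#' @examples
#' cfg <- grasp_config(n_subjects = 2, n_objects = 1, n_trials_per_object = 2)
grasp_config <- function(n_subjects = 31, n_objects = 5,
                         n_trials_per_object = 7,
                         subject_effect_scale = 8,
                         trial_noise_scale = 1.5,
                         object_effect_scale = 8,
                         mains_noise_amplitude = 0.05,
                         sensor_noise_sd = 0.01,
                         marker_noise_sd = 0.1,
                         kinematic_rate = 120, force_rate = 960,
                         phase_duration_ranges = list(
                           reach = c(0.8, 1.2),
                           grasp = c(1.2, 1.8),
                           release = c(0.8, 1.2)),
                         spring_constant = 0.45,
                         hand_size_mean = 185, hand_size_sd = 12,
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_objects = as.integer(n_objects),
              n_trials_per_object = as.integer(n_trials_per_object),
              subject_effect_scale = subject_effect_scale,
              trial_noise_scale = trial_noise_scale,
              object_effect_scale = object_effect_scale,
              mains_noise_amplitude = mains_noise_amplitude,
              sensor_noise_sd = sensor_noise_sd,
              marker_noise_sd = marker_noise_sd,
              kinematic_rate = kinematic_rate, force_rate = force_rate,
              phase_duration_ranges = phase_duration_ranges,
              spring_constant = spring_constant,
              hand_size_mean = hand_size_mean, hand_size_sd = hand_size_sd,
              seed = as.integer(seed))
  counts <- c("n_subjects", "n_objects", "n_trials_per_object")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_graspid("graspid_config_error", "'%s' must be a count >= 1", f)
  scales <- c("subject_effect_scale", "trial_noise_scale",
              "object_effect_scale", "mains_noise_amplitude",
              "sensor_noise_sd", "marker_noise_sd")
  for (f in scales)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop_graspid("graspid_config_error", "'%s' must be >= 0", f)
  if (cfg$force_rate %% cfg$kinematic_rate != 0)
    stop_graspid("graspid_config_error",
                 "force_rate (%s) must be an integer multiple of kinematic_rate (%s)",
                 cfg$force_rate, cfg$kinematic_rate)
  if (cfg$spring_constant <= 0)
    stop_graspid("graspid_config_error", "spring_constant must be > 0")
  for (ph in c("reach", "grasp", "release")) {
    r <- cfg$phase_duration_ranges[[ph]]
    if (is.null(r) || length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop_graspid("graspid_config_error",
                   "phase_duration_ranges$%s must be a positive length-2 range", ph)
  }
  class(cfg) <- "grasp_config"
  cfg
}

#' @export
print.grasp_config <- function(x, ...) {
  cat("Synthetic grasp-recording configuration\n")
  cat(sprintf("  design: %d subjects x %d objects x %d trials (%d trials total)\n",
              x$n_subjects, x$n_objects, x$n_trials_per_object,
              x$n_subjects * x$n_objects * x$n_trials_per_object))
  cat(sprintf("  rates: %g Hz markers, %g Hz forces\n",
              x$kinematic_rate, x$force_rate))
  cat(sprintf("  effect scales (subject/object/trial): %g / %g / %g deg\n",
              x$subject_effect_scale, x$object_effect_scale, x$trial_noise_scale))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# ---- smooth template machinery ----------------------------------------------

# Population-mean angle curves on normalized movement time [0,1]. Fingers
# open slightly during reach, close onto the object just before canonical
# contact (t = 1/3), hold during grasp, and extend through release.
.angle_population <- function(t) {
  env <- smoothstep(t, 0.22, 0.36) * (1 - smoothstep(t, 0.66, 0.84))
  base1 <- c(55, 42, 40, 38, 36)   # theta1 baseline per finger, deg
  amp1  <- c(22, 28, 30, 28, 24)
  base2 <- c(8, 6, 6, 6, 6)        # theta2 (flexion) baseline, deg
  amp2  <- c(30, 42, 46, 44, 38)
  out <- matrix(0, length(t), 10)
  for (f in 1:5) {
    out[, 2 * f - 1] <- base1[f] + amp1[f] * env
    out[, 2 * f]     <- base2[f] + amp2[f] * env
  }
  colnames(out) <- angle_names()
  out
}

# Random smooth perturbations: fixed-amplitude sinusoids with random phases,
# sum over K harmonics. Pointwise variance is exactly scale^2 at every t,
# and the curves are band-limited far below the 15 Hz trajectory filter.
.draw_phases <- function(n_curves, K = 3) {
  matrix(runif(n_curves * K, 0, 2 * pi), n_curves, K)
}

.eval_smooth <- function(phases, scale, t) {
  K <- ncol(phases)
  out <- matrix(0, length(t), nrow(phases))
  if (scale == 0) return(out)
  for (k in seq_len(K)) {
    out <- out + sin(outer(2 * pi * k * t, phases[, k], "+"))
  }
  out * scale * sqrt(2 / K)
}

# Peak grasp force per finger (N) at the population level.
.force_population_peak <- c(4.5, 4.0, 3.5, 2.5, 1.8)

# Grasp-phase force envelope on tau in [0,1]: zero at both endpoints, quick
# raised ramps (10% of grasp duration) so contact is sharply detectable.
.force_envelope <- function(tau) {
  smoothstep(tau, 0, 0.1) * (1 - smoothstep(tau, 0.9, 1))
}

.object_phases <- function(config, object_id) {
  with_seed(derive_seed(config$seed, "object", object_id), list(
    angle = .draw_phases(10), force = .draw_phases(5)))
}

# ---- subject profiles -------------------------------------------------------

#' Generate one subject's movement profile
#'
#' Draws the subject's hand size, smooth angle/force template perturbations
#' (population mean plus a random smooth deviation with pointwise SD
#' `subject_effect_scale`), per-finger force-sensor response parameters, and
#' mean phase durations. Deterministic given `(config$seed, subject_index)`.
#'
#' @param config a [grasp_config()].
#' @param subject_index subject number in `1:n_subjects`.
#' @return an object of class `grasp_subject`.
#' @export
generate_subject_profile <- function(config, subject_index) {
  if (!inherits(config, "grasp_config"))
    stop_graspid("graspid_config_error", "config must be a grasp_config")
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop_graspid("graspid_config_error",
                 "subject_index %d outside 1:%d", subject_index, config$n_subjects)
  with_seed(derive_seed(config$seed, "subject", subject_index), {
    hand_size <- max(120, rnorm(1, config$hand_size_mean, config$hand_size_sd))
    angle_phases <- .draw_phases(10)
    force_phases <- .draw_phases(5)
    # force amplitude deviation per finger (N), tied to the subject scale
    force_amp_dev <- rnorm(5, 0, 0.08 * config$subject_effect_scale)
    # per-finger sensor response V = V0 + c1 F + c2 F^2 (monotone on 0-12 N)
    sensor <- list(v0 = rnorm(5, 0.5, 0.05),
                   c1 = pmax(0.2, rnorm(5, 0.35, 0.04)),
                   c2 = pmax(-0.012, pmin(0, rnorm(5, -0.006, 0.002))))
    phase_means <- vapply(config$phase_duration_ranges,
                          function(r) runif(1, r[1], r[2]), numeric(1))
    structure(list(subject_id = sprintf("S%02d", subject_index),
                   subject_index = subject_index,
                   hand_size = hand_size,
                   angle_phases = angle_phases,
                   force_phases = force_phases,
                   force_amp_dev = force_amp_dev,
                   sensor = sensor,
                   phase_duration_means = phase_means,
                   config = config),
              class = "grasp_subject")
  })
}

#' Evaluate a subject's angle templates on normalized movement time
#'
#' @param profile a `grasp_subject`.
#' @param t numeric vector in `[0, 1]` (normalized movement time).
#' @param object_id optional object label; when given, the object-dependent
#'   template deviation is included.
#' @return a `length(t) x 10` matrix of angles in degrees.
#' @export
angle_templates <- function(profile, t, object_id = NULL) {
  cfg <- profile$config
  out <- .angle_population(t) +
    .eval_smooth(profile$angle_phases, cfg$subject_effect_scale, t)
  if (!is.null(object_id)) {
    ph <- .object_phases(cfg, object_id)
    out <- out + .eval_smooth(ph$angle, cfg$object_effect_scale, t)
  }
  pmin(pmax(out, 1), 179)
}

#' Evaluate a subject's force templates on normalized grasp-phase time
#'
#' @inheritParams angle_templates
#' @param tau numeric vector in `[0, 1]` (normalized grasp-phase time).
#' @return a `length(tau) x 5` matrix of fingertip forces in newtons; zero at
#'   both endpoints.
#' @export
force_templates <- function(profile, tau, object_id = NULL) {
  cfg <- profile$config
  amp <- .force_population_peak + profile$force_amp_dev
  dev <- .eval_smooth(profile$force_phases, 0.05 * cfg$subject_effect_scale, tau)
  if (!is.null(object_id)) {
    ph <- .object_phases(cfg, object_id)
    dev <- dev + .eval_smooth(ph$force, 0.05 * cfg$object_effect_scale, tau)
  }
  env <- .force_envelope(tau)
  out <- sweep(dev, 2, amp, "+") * env
  pmax(out, 0)
}

#' @export
print.grasp_subject <- function(x, ...) {
  cat(sprintf("Grasp subject profile %s (hand size %.1f mm)\n",
              x$subject_id, x$hand_size))
  cat(sprintf("  mean phase durations (s): reach %.2f, grasp %.2f, release %.2f\n",
              x$phase_duration_means[["reach"]],
              x$phase_duration_means[["grasp"]],
              x$phase_duration_means[["release"]]))
  invisible(x)
}

# ---- hand geometry and forward kinematics -----------------------------------

# Hand-local geometry (mm at reference hand size 185): palm triangle in the
# z = 0 plane, wrist markers behind it, per-finger in-plane directions and
# segment lengths. The palm-plane normal is +z, so theta1/theta2 fully
# determine the per-finger marker chain (planar-per-finger approximation).
.hand_geometry <- function(hand_size) {
  s <- hand_size / 185
  list(palm = rbind(c(0, 0, 0), c(70, 0, 0), c(35, 55, 0)) * s,
       wrist = rbind(c(15, -45, 0), c(55, -45, 0)) * s,
       u_angles = c(160, 105, 90, 75, 60) * pi / 180,
       L1 = c(50, 85, 90, 85, 75) * s,
       L2 = c(35, 32, 34, 31, 26) * s,
       L3 = c(30, 24, 26, 24, 20) * s)
}

# Vectorized per-finger marker chain from angle series (degrees).
# Returns list of three T x 3 matrices (chain markers outward from palm).
.finger_chain <- function(geom, finger, th1_deg, th2_deg) {
  th1 <- th1_deg * pi / 180
  th2 <- th2_deg * pi / 180
  u <- c(cos(geom$u_angles[finger]), sin(geom$u_angles[finger]), 0)
  cen <- colMeans(geom$palm)
  # v = cos(th1) z + sin(th1) u ; rotation axis a = z x u (unit, a . v = 0)
  v <- cbind(sin(th1) * u[1], sin(th1) * u[2], cos(th1))
  a <- c(-u[2], u[1], 0)
  # w = v cos(th2) + (a x v) sin(th2)
  axv <- cbind(a[2] * v[, 3], -a[1] * v[, 3], a[1] * v[, 2] - a[2] * v[, 1])
  w <- v * cos(th2) + axv * sin(th2)
  m1 <- sweep(geom$L1[finger] * v, 2, cen, "+")
  m2 <- m1 + geom$L2[finger] * v
  m3 <- m2 + geom$L3[finger] * w
  list(m1, m2, m3)
}

# Minimum-jerk displacement profile on [0,1].
.minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# ---- trial generation -------------------------------------------------------

#' Generate one synthetic grasp trial
#'
#' Synthesizes the marker block by a forward kinematic chain driven by the
#' subject's (warped) angle templates, so that downstream angle extraction
#' recovers the templates, plus the whole-hand transport motion (minimum-jerk
#' reach and release, random rigid orientation). Force channels carry the
#' sensor baseline, white sensor noise and a random-phase 50 Hz mains
#' sinusoid throughout, plus the force template mapped through the subject's
#' nonlinear sensor response during the grasp phase.
#'
#' @param profile a `grasp_subject` from [generate_subject_profile()].
#' @param object_id object label (e.g. `"O1"`).
#' @param trial_index trial number.
#' @param config the [grasp_config()] used for the profile.
#' @return an object of class `grasp_trial` with elements `marker_block`
#'   (frames x 3 x 20 array, mm), `force_block` (samples x 5 matrix, V),
#'   `true_phase_bounds`, and generator-only ground truth `true_angles`
#'   (frames x 10, deg) and `true_forces` (frames x 5, N, kinematic rate).
#' @export
generate_trial <- function(profile, object_id, trial_index, config = profile$config) {
  rate <- config$kinematic_rate
  ratio <- config$force_rate / rate
  with_seed(derive_seed(config$seed, "trial", profile$subject_id,
                        object_id, trial_index), {
    durs <- profile$phase_duration_means * runif(3, 0.9, 1.1)
    n_idle <- round(0.3 * rate)
    n_ph <- pmax(2L, round(durs * rate))
    n_reach <- n_ph[[1]]; n_grasp <- n_ph[[2]]; n_release <- n_ph[[3]]
    T_k <- n_idle + n_reach + n_grasp + n_release + n_idle

    movement_onset <- n_idle + 1L
    contact_onset <- n_idle + n_reach + 1L
    release_onset <- n_idle + n_reach + n_grasp + 1L
    movement_end <- n_idle + n_reach + n_grasp + n_release

    # normalized template time with canonical phase thirds, warped so the
    # trial's actual phase boundaries land on 1/3 and 2/3
    tpl_t <- numeric(T_k)
    tpl_t[seq_len(n_idle)] <- 0
    tpl_t[movement_onset:(contact_onset - 1L)] <- seq_len(n_reach) / n_reach / 3
    tpl_t[contact_onset:(release_onset - 1L)] <- 1 / 3 + seq_len(n_grasp) / n_grasp / 3
    tpl_t[release_onset:movement_end] <- 2 / 3 + seq_len(n_release) / n_release / 3
    if (movement_end < T_k) tpl_t[(movement_end + 1L):T_k] <- 1

    trial_phases <- .draw_phases(10)
    angles <- angle_templates(profile, tpl_t, object_id) +
      .eval_smooth(trial_phases, config$trial_noise_scale, tpl_t)
    angles <- pmin(pmax(angles, 1), 179)

    # forces: template on grasp-normalized time, trial deviation, envelope
    trial_force_phases <- .draw_phases(5)
    force_at <- function(tau) {
      base <- force_templates(profile, tau, object_id)
      dev <- .eval_smooth(trial_force_phases, 0.05 * config$trial_noise_scale, tau)
      pmax(base + dev * .force_envelope(tau), 0)
    }
    # ground-truth forces at the kinematic rate (zero outside contact)
    true_forces <- matrix(0, T_k, 5, dimnames = list(NULL, FINGERS))
    g_frames <- contact_onset:(release_onset - 1L)
    true_forces[g_frames, ] <- force_at((seq_len(n_grasp) - 1) / n_grasp)

    # force-rate samples: sample s corresponds to time (s - 0.5) / force_rate
    T_f <- T_k * ratio
    s_time <- (seq_len(T_f) - 0.5) / config$force_rate
    g_start <- (contact_onset - 1) / rate
    g_end <- (release_onset - 1) / rate
    tau_f <- (s_time - g_start) / (g_end - g_start)
    in_grasp <- tau_f > 0 & tau_f < 1
    F_f <- matrix(0, T_f, 5)
    F_f[in_grasp, ] <- force_at(tau_f[in_grasp])

    sens <- profile$sensor
    mains_phi <- runif(5, 0, 2 * pi)
    volts <- matrix(0, T_f, 5, dimnames = list(NULL, FINGERS))
    for (i in 1:5) {
      volts[, i] <- sens$v0[i] + sens$c1[i] * F_f[, i] + sens$c2[i] * F_f[, i]^2 +
        config$mains_noise_amplitude * sin(2 * pi * 50 * s_time + mains_phi[i]) +
        rnorm(T_f, 0, config$sensor_noise_sd)
    }

    # marker trajectories: hand-local chain + whole-hand rigid transport
    geom <- .hand_geometry(profile$hand_size)
    local <- array(0, c(T_k, 3, 20), dimnames = list(NULL, c("x", "y", "z"),
                                                     marker_names()))
    for (f in 1:5) {
      ch <- .finger_chain(geom, f, angles[, 2 * f - 1], angles[, 2 * f])
      for (seg in 1:3) local[, , (f - 1) * 3 + seg] <- ch[[seg]]
    }
    for (p in 1:3) local[, , 15 + p] <- matrix(geom$palm[p, ], T_k, 3, byrow = TRUE)
    for (w in 1:2) local[, , 18 + w] <- matrix(geom$wrist[w, ], T_k, 3, byrow = TRUE)

    R <- .random_rotation()
    reach_vec <- c(280, 60, 40)
    prog <- numeric(T_k)
    prog[movement_onset:(contact_onset - 1L)] <- .minjerk(seq_len(n_reach) / n_reach)
    prog[contact_onset:(release_onset - 1L)] <- 1
    prog[release_onset:movement_end] <- 1 - .minjerk(seq_len(n_release) / n_release)
    trans <- outer(prog, reach_vec)

    markers <- array(0, dim(local), dimnames = dimnames(local))
    for (m in 1:20) {
      markers[, , m] <- local[, , m] %*% t(R) + trans +
        matrix(rnorm(T_k * 3, 0, config$marker_noise_sd), T_k, 3)
    }

    structure(list(subject_id = profile$subject_id,
                   object_id = object_id,
                   trial_index = trial_index,
                   marker_block = markers,
                   marker_roles = marker_roles(),
                   force_block = volts,
                   kinematic_rate = rate,
                   force_rate = config$force_rate,
                   true_phase_bounds = c(movement_onset = movement_onset,
                                         contact_onset = contact_onset,
                                         release_onset = release_onset,
                                         movement_end = movement_end),
                   true_angles = angles,
                   true_forces = true_forces),
              class = "grasp_trial")
  })
}

#' @export
print.grasp_trial <- function(x, ...) {
  cat(sprintf("Grasp trial: subject %s, object %s, trial %d\n",
              x$subject_id, x$object_id, x$trial_index))
  cat(sprintf("  markers: %d frames x 3 x %d at %g Hz; forces: %d samples x %d at %g Hz\n",
              dim(x$marker_block)[1], dim(x$marker_block)[3], x$kinematic_rate,
              nrow(x$force_block), ncol(x$force_block), x$force_rate))
  b <- x$true_phase_bounds
  cat(sprintf("  phase bounds (frames): onset %d, contact %d, release %d, end %d\n",
              b[1], b[2], b[3], b[4]))
  invisible(x)
}

# ---- calibration recordings -------------------------------------------------

#' Generate one subject's spring-platform calibration recordings
#'
#' Emulates the calibration procedure: the subject presses each fingertip
#' sensor down on a spring-loaded platform until the rail end, three times
#' per finger, while platform displacement is tracked. Force is
#' `spring_constant * displacement`; voltage follows the subject's sensor
#' response plus noise.
#'
#' @inheritParams generate_trial
#' @param max_displacement rail travel (mm).
#' @return a named list (one per finger) of `grasp_calibration_recording`
#'   objects, each with 3 repetition data frames (`voltage`, `displacement_mm`).
#' @export
generate_calibration <- function(profile, config = profile$config,
                                 max_displacement = 25) {
  rate <- config$kinematic_rate
  with_seed(derive_seed(config$seed, "calibration", profile$subject_id), {
    sens <- profile$sensor
    out <- lapply(1:5, function(i) {
      reps <- lapply(1:3, function(r) {
        tt <- seq(0, 3, by = 1 / rate)
        dx <- max_displacement * smoothstep(tt, 0.2, 2.8) * runif(1, 0.97, 1.0)
        FF <- config$spring_constant * dx
        v <- sens$v0[i] + sens$c1[i] * FF + sens$c2[i] * FF^2 +
          rnorm(length(FF), 0, config$sensor_noise_sd / 2)
        data.frame(sample = seq_along(tt), voltage = v, displacement_mm = dx)
      })
      structure(list(finger = FINGERS[i], repetitions = reps,
                     spring_constant = config$spring_constant),
                class = "grasp_calibration_recording")
    })
    names(out) <- FINGERS
    out
  })
}

# ---- full dataset -----------------------------------------------------------

#' Generate a full synthetic grasp dataset
#'
#' Produces `n_subjects * n_objects * n_trials_per_object` trials plus one
#' calibration recording set per subject, all deterministically derived from
#' `config$seed` with disjoint streams per subject/object/trial.
#'
#' @param config a [grasp_config()].
#' @param calibrations generate per-subject calibration recordings as well?
#' @return an object of class `grasp_recordings`: list with `trials`,
#'   `profiles`, `calibrations` and `config`.
#' @export
#' @examples
#' rec <- generate_dataset(grasp_config(n_subjects = 2, n_objects = 1,
#'                                      n_trials_per_object = 2))
#' length(rec$trials)
generate_dataset <- function(config, calibrations = TRUE) {
  if (!inherits(config, "grasp_config"))
    stop_graspid("graspid_config_error", "config must be a grasp_config")
  profiles <- lapply(seq_len(config$n_subjects),
                     function(i) generate_subject_profile(config, i))
  names(profiles) <- vapply(profiles, `[[`, "", "subject_id")
  objects <- sprintf("O%d", seq_len(config$n_objects))
  trials <- vector("list", config$n_subjects * config$n_objects *
                     config$n_trials_per_object)
  k <- 0L
  for (p in profiles) {
    for (obj in objects) {
      for (tr in seq_len(config$n_trials_per_object)) {
        k <- k + 1L
        trials[[k]] <- generate_trial(p, obj, tr, config)
      }
    }
  }
  calib <- if (calibrations) lapply(profiles, generate_calibration, config = config)
  structure(list(trials = trials, profiles = profiles,
                 calibrations = calib, config = config,
                 objects = objects),
            class = "grasp_recordings")
}

#' @export
print.grasp_recordings <- function(x, ...) {
  cat(sprintf("Synthetic grasp recordings: %d trials (%d subjects x %d objects x %d trials)\n",
              length(x$trials), x$config$n_subjects, x$config$n_objects,
              x$config$n_trials_per_object))
  invisible(x)
}

#' Hand sizes of the subjects in a recording set
#'
#' @param recordings a `grasp_recordings` object.
#' @return named numeric vector (mm), one entry per subject.
#' @export
hand_sizes <- function(recordings) {
  vapply(recordings$profiles, `[[`, numeric(1), "hand_size")
}
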