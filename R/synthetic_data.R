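# Seeded simulator of the laboratory activity protocol: ten standardised
# activities of daily living, four minutes each, with expired-gas sampling
# during the two final minutes of every activity. The signal model is
# additive -- gravity projection (static) + narrowband oscillation at the
# activity's dominant frequency (dynamic) + white sensor noise -- so its
# static/dynamic decomposition is analytically known.

#' Default activity profiles of the laboratory protocol
#'
#' One row per protocol activity: observed posture, the mean and SD of the
#' true MET cost across participants, the dominant movement frequency and
#' the unit gravity direction of the thigh-worn device during the activity
#' (x mediolateral, y vertical-when-standing, z anteroposterior). Shuffling
#' sideways straddles the 1.5-MET boundary on purpose: participants with a
#' low energy cost there are referenced as Standing while the motion still
#' registers on the accelerometer, the hardest edge case for posture-gated
#' cut-point models.
#'
#' @return Data frame with columns `activity_code`, `name`, `posture`,
#'   `met_mean`, `met_sd`, `dominant_freq_hz`, `grav_x`, `grav_y`,
#'   `grav_z`.
#' @export
default_activity_profiles <- function() {
  p <- data.frame(
    activity_code = 1:10,
    name = c("lying_supine", "sitting", "standing", "shuffling_sideways",
             "free_walking", "cycling", "treadmill_3.2kmh",
             "treadmill_preferred", "treadmill_weighted_vest",
             "brisk_treadmill"),
    posture = c("not_upright", "not_upright", "upright", "upright",
                "upright", "not_upright", "upright", "upright", "upright",
                "upright"),
    met_mean = c(1.00, 1.20, 1.30, 1.75, 3.40, 4.00, 3.20, 3.50, 4.20, 5.00),
    met_sd   = c(0.05, 0.08, 0.10, 0.25, 0.35, 0.60, 0.30, 0.40, 0.50, 0.60),
    dominant_freq_hz = c(0.8, 0.9, 1.0, 1.2, 1.8, 1.5, 1.6, 1.9, 1.9, 2.1),
    grav_x = c(0.00, 0.05, 0.05, 0.08, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    grav_y = c(0.02, 0.20, 0.98, 0.96, 0.96, 0.42, 0.96, 0.96, 0.96, 0.95),
    grav_z = c(1.00, 0.98, 0.17, 0.20, 0.25, 0.90, 0.25, 0.25, 0.25, 0.28))
  g <- sqrt(p$grav_x^2 + p$grav_y^2 + p$grav_z^2)
  p$grav_x <- p$grav_x / g
  p$grav_y <- p$grav_y / g
  p$grav_z <- p$grav_z / g
  p
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(x < lower)) x[x < lower] <- rnorm(sum(x < lower), mean, sd)
  x
}

#' Draw participant baseline characteristics
#'
#' Heterogeneous baselines for a healthy older-adult sample: age 73.5
#' (6.3) years truncated at 60, 50 percent female, body mass 72.2 (13.7)
#' kg, height 1.67 (0.10) m, fasting REE 2.82 (1.00) ml/kg/min, preferred
#' walking speed 3.7 (1.0) km/h, half fasted, half on cardiovascular
#' medication, a small share with prosthetic lower-limb joints, most at
#' low falls risk.
#'
#' @param n Number of participants.
#' @return Data frame of baseline characteristics, one row per
#'   participant (`participant_id` P01, P02, ...).
#' @export
sample_baselines <- function(n) {
  sex <- rep(c("female", "male"), length.out = n)[sample.int(n)]
  height <- round(rnorm_trunc(n, 1.67, 0.10, 1.40), 2)
  mass <- round(rnorm_trunc(n, 72.2, 13.7, 40), 1)
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    age = round(rnorm_trunc(n, 73.5, 6.3, 60), 1),
    sex = sex,
    body_mass = mass,
    body_height = height,
    bmi = round(mass / height^2, 1),
    prandial_state = rep(c("fasting", "non_fasting"),
                         length.out = n)[sample.int(n)],
    ree = round(rnorm_trunc(n, 2.82, 1.00, 1.2), 2),
    prosthetic_joints = rbinom(n, 1, 0.05) == 1,
    cv_medication = rbinom(n, 1, 0.5) == 1,
    fitness_level = sample(c("less_than_good", "good_or_better"), n,
                           replace = TRUE, prob = c(0.45, 0.55)),
    preferred_walking_speed = round(rnorm_trunc(n, 3.7, 1.0, 1.5), 1),
    falls_risk = sample(c("low", "medium_or_high"), n, replace = TRUE,
                        prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)
}

#' Simulate one participant's protocol session
#'
#' Generates the 60 Hz triaxial recording (ten 4-minute activities), the
#' per-minute calorimetry samples of the two gas-sampling minutes per
#' activity, and the per-minute ground truth. The dynamic amplitude scales
#' linearly with the activity's realised MET cost above rest
#' (`amp_per_met` g per MET) and with body height (+1 percent per cm above
#' the 1.67 m population mean, modelling the larger distance of the device
#' to the centre of rotation in taller people). Measured VO2 carries
#' multiplicative lognormal noise with the coefficient of variation of the
#' Douglas Bag method (`vo2_cv`, default 4.4 percent). Uses the current
#' RNG stream; seed at the dataset level.
#'
#' @param participant_id Identifier string.
#' @param baseline One-row baseline data frame (needs `ree`,
#'   `body_height`).
#' @param profiles Activity profile table, see
#'   [default_activity_profiles()].
#' @param sample_rate_hz Sampling rate (default 60).
#' @param amp_per_met Dynamic amplitude per MET above 1 (g, default 0.12).
#' @param vo2_cv Lognormal CV of measured VO2 (default 0.044).
#' @param noise_sd_base,noise_sd_rel White-noise SD: `base + rel * amp` (g,
#'   defaults 0.008 and 0.04).
#' @param height_gain_per_cm Amplitude gain per cm of height above 167 cm
#'   (default 0.01; set 0 to switch the height effect off).
#' @return List with `recording` (an `acc_recording`), `calorimetry`
#'   (data frame) and `truth` (per-minute data frame).
#' @export
simulate_participant <- function(participant_id, baseline,
                                 profiles = default_activity_profiles(),
                                 sample_rate_hz = 60,
                                 amp_per_met = 0.12,
                                 vo2_cv = 0.044,
                                 noise_sd_base = 0.008,
                                 noise_sd_rel = 0.04,
                                 height_gain_per_cm = 0.01) {
  if (nrow(profiles) < 1L || anyNA(profiles$met_mean) ||
      any(profiles$met_mean <= 0)) {
    stop("invalid activity profiles")
  }
  fs <- sample_rate_hz
  act_len <- 240L # seconds per activity
  n_act <- nrow(profiles)
  nsamp_act <- act_len * fs
  total <- n_act * nsamp_act
  xyz <- matrix(0, nrow = total, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  ann <- list()
  cal <- list()
  truth <- list()
  sdlog <- sqrt(log(1 + vo2_cv^2))
  hgain <- 1 + height_gain_per_cm * (baseline$body_height * 100 - 167)
  w <- c(0.30, 0.70, 0.65) # distribution of movement over the axes (unit norm)
  for (i in seq_len(n_act)) {
    pr <- profiles[i, ]
    met_i <- max(0.85, rnorm(1, pr$met_mean, pr$met_sd))
    amp <- amp_per_met * max(met_i - 1, 0.02) * hgain
    tt <- (seq_len(nsamp_act) - 1) / fs
    grav <- c(pr$grav_x, pr$grav_y, pr$grav_z)
    # small per-activity mounting jitter on the gravity direction
    grav <- grav + rnorm(3, 0, 0.01)
    grav <- grav / sqrt(sum(grav^2))
    # slow amplitude drift so repeated windows are not carbon copies
    drift <- 1 + 0.05 * sin(2 * pi * 0.015 * tt + runif(1, 0, 2 * pi))
    sel <- ((i - 1L) * nsamp_act + 1L):(i * nsamp_act)
    noise_sd <- noise_sd_base + noise_sd_rel * amp
    for (ax in 1:3) {
      phase <- runif(1, 0, 2 * pi)
      xyz[sel, ax] <- grav[ax] +
        w[ax] * amp * drift * sin(2 * pi * pr$dominant_freq_hz * tt + phase) +
        rnorm(nsamp_act, 0, noise_sd)
    }
    start <- (i - 1L) * act_len
    ann[[length(ann) + 1L]] <- data.frame(
      participant_id = participant_id, activity_code = pr$activity_code,
      start_s = start, end_s = start + act_len, gas_minute = 0L,
      observed_posture = pr$posture, stringsAsFactors = FALSE)
    for (gm in 1:2) {
      g0 <- start + 120 + (gm - 1L) * 60
      ann[[length(ann) + 1L]] <- data.frame(
        participant_id = participant_id, activity_code = pr$activity_code,
        start_s = g0, end_s = g0 + 60, gas_minute = gm,
        observed_posture = pr$posture, stringsAsFactors = FALSE)
      cal[[length(cal) + 1L]] <- data.frame(
        participant_id = participant_id, activity_code = pr$activity_code,
        minute_id = minute_id(pr$activity_code, gm),
        vo2 = met_i * baseline$ree * exp(rnorm(1, 0, sdlog)),
        observed_posture = pr$posture, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        participant_id = participant_id, activity_code = pr$activity_code,
        minute_id = minute_id(pr$activity_code, gm),
        true_met = met_i, posture = pr$posture, stringsAsFactors = FALSE)
    }
  }
  rec <- structure(list(participant_id = participant_id,
                        sample_rate_hz = fs,
                        samples = xyz,
                        time_s = (seq_len(total) - 1) / fs,
                        annotations = do.call(rbind, ann)),
                   class = "acc_recording")
  list(recording = rec,
       calorimetry = do.call(rbind, cal),
       truth = do.call(rbind, truth))
}

#' Simulate a full protocol dataset
#'
#' @param n_participants Number of participants (default 40, at least 2).
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param profiles Activity profile table.
#' @param ... Passed to [simulate_participant()] (noise and gain
#'   settings).
#' @return A `thighacc_dataset`: list with `recordings` (list of
#'   `acc_recording`), `calorimetry`, `baselines`, `truth` data frames and
#'   the `seed`.
#' @export
simulate_dataset <- function(n_participants = 40, seed = 1L,
                             profiles = default_activity_profiles(), ...) {
  if (n_participants < 2) stop("need at least 2 participants")
  set.seed(as.integer(seed))
  baselines <- sample_baselines(n_participants)
  recs <- vector("list", n_participants)
  cal <- list()
  truth <- list()
  for (i in seq_len(n_participants)) {
    sim <- simulate_participant(baselines$participant_id[i],
                                baselines[i, , drop = FALSE],
                                profiles = profiles, ...)
    recs[[i]] <- sim$recording
    cal[[i]] <- sim$calorimetry
    truth[[i]] <- sim$truth
  }
  structure(list(recordings = setNames(recs, baselines$participant_id),
                 calorimetry = do.call(rbind, cal),
                 baselines = baselines,
                 truth = do.call(rbind, truth),
                 seed = as.integer(seed)),
            class = "thighacc_dataset")
}

#' @export
print.thighacc_dataset <- function(x, ...) {
  cat("Synthetic protocol dataset:", length(x$recordings), "participants,",
      nrow(x$calorimetry), "gas-sampling minutes, seed", x$seed, "\n")
  invisible(x)
}

#' Write a dataset to CSV files
#'
#' Emits the declared plain-text formats: one `acc_<id>.csv`
#' (`time,x,y,z`) per participant, plus `annotations.csv`,
#' `calorimetry.csv`, `baselines.csv` and `truth.csv`. The files
#' round-trip losslessly through [read_dataset()].
#'
#' @param dataset A `thighacc_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "thighacc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- list()
  for (id in names(dataset$recordings)) {
    rec <- dataset$recordings[[id]]
    df <- data.frame(time = rec$time_s, rec$samples)
    write.csv(df, file.path(dir, paste0("acc_", id, ".csv")),
              row.names = FALSE)
    ann[[id]] <- rec$annotations
  }
  write.csv(do.call(rbind, ann), file.path(dir, "annotations.csv"),
            row.names = FALSE)
  write.csv(dataset$calorimetry, file.path(dir, "calorimetry.csv"),
            row.names = FALSE)
  write.csv(dataset$baselines, file.path(dir, "baselines.csv"),
            row.names = FALSE)
  write.csv(dataset$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
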