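# Reference intensity labelling: MET values from indirect calorimetry,
# classified with the posture-aware rule set used for thigh-worn devices.

#' Metabolic equivalent of a one-minute gas sample
#'
#' MET is defined against the participant's own measured resting oxygen
#' consumption rather than the 3.5 ml/kg/min convention:
#' `MET = VO2_minute / REE_participant`.
#'
#' @param vo2 Oxygen consumption during the minute (ml kg^-1 min^-1, STPD).
#' @param ree Participant resting energy expenditure on the same scale.
#' @return MET value (dimensionless), vectorised over `vo2`.
#' @examples
#' compute_met(8.46, 2.82) # 3 METs
#' @export
compute_met <- function(vo2, ree) {
  if (any(!is.finite(ree)) || any(ree <= 0)) stop("ree must be positive")
  if (any(!is.finite(vo2)) || any(vo2 <= 0)) stop("vo2 must be positive")
  vo2 / ree
}

#' Reference intensity class from MET and observed posture
#'
#' The rule set partitions every (MET, posture) pair:
#' MET <= 1.5 and not upright -> Sedentary; MET <= 1.5 and upright ->
#' Standing; 1.5 < MET < 3 -> LIPA; MET >= 3 -> MVPA. Posture only matters
#' at or below 1.5 MET. All six 10-s windows of a gas-sampling minute
#' inherit the minute's label.
#'
#' @param met MET value(s), positive.
#' @param posture Character vector, `"upright"` or `"not_upright"`.
#' @return Factor with levels `Sedentary, Standing, LIPA, MVPA`.
#' @export
classify_reference <- function(met, posture) {
  if (any(!is.finite(met)) || any(met <= 0)) stop("met must be positive")
  posture <- match.arg(posture, c("upright", "not_upright"),
                       several.ok = TRUE)
  if (length(posture) == 1L) posture <- rep(posture, length(met))
  stopifnot(length(posture) == length(met))
  cls <- ifelse(met >= 3, "MVPA",
         ifelse(met > 1.5, "LIPA",
         ifelse(posture == "upright", "Standing", "Sedentary")))
  factor(cls, levels = INTENSITY_LEVELS)
}

#' Resting energy expenditure from resting minutes
#'
#' Mean oxygen consumption over the supplied seated-rest minutes (the study
#' design uses the third and fourth minute of quiet sitting, fasted
#' participants only at dataset-build time).
#'
#' @param resting_vo2 Numeric vector of resting VO2 readings.
#' @return REE (ml kg^-1 min^-1).
#' @export
compute_ree <- function(resting_vo2) {
  if (any(!is.finite(resting_vo2)) || any(resting_vo2 <= 0)) {
    stop("resting vo2 readings must be positive")
  }
  mean(resting_vo2)
}

#' Per-minute reference labels for a calorimetry table
#'
#' @param calorimetry Data frame with columns `participant_id`,
#'   `activity_code`, `minute_id`, `vo2` and `observed_posture`.
#' @param baselines Data frame with columns `participant_id` and `ree`.
#' @return The calorimetry table with added `met` and `intensity_class`
#'   columns.
#' @export
reference_labels <- function(calorimetry, baselines) {
  need <- c("participant_id", "activity_code", "minute_id", "vo2",
            "observed_posture")
  if (!all(need %in% names(calorimetry))) {
    stop("calorimetry table must have columns: ",
         paste(setdiff(need, names(calorimetry)), collapse = ", "))
  }
  ree <- setNames(baselines$ree, baselines$participant_id)
  if (anyNA(ree[as.character(calorimetry$participant_id)])) {
    stop("baseline REE missing for some participants")
  }
  met <- compute_met(calorimetry$vo2,
                     unname(ree[as.character(calorimetry$participant_id)]))
  calorimetry$met <- met
  calorimetry$intensity_class <- classify_reference(
    met, calorimetry$observed_posture)
  calorimetry
}
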