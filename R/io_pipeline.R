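# Readers for the declared CSV formats, pipeline configuration, and the
# end-to-end orchestration (decompose -> features -> reference labels ->
# calibrate/train under LOSO -> performance report).

#' Read a raw recording and its annotations
#'
#' @param path CSV with header `time,x,y,z` (time in seconds, acceleration
#'   in g unless `input_units = "ms2"`).
#' @param annotations_path CSV with header
#'   `participant_id,activity_code,start_s,end_s,gas_minute,observed_posture`
#'   (0-based seconds, half-open intervals; `gas_minute` 0 marks a plain
#'   activity span, 1 or 2 a gas-sampling minute).
#' @param participant_id Participant to select from the annotation file;
#'   defaults to the single id present.
#' @param sample_rate_hz Expected sampling rate (default 60).
#' @param input_units `"g"` (default) or `"ms2"` (divided by 9.81 at
#'   ingest).
#' @return An `acc_recording`.
#' @export
read_recording <- function(path, annotations_path, participant_id = NULL,
                           sample_rate_hz = 60,
                           input_units = c("g", "ms2")) {
  input_units <- match.arg(input_units)
  df <- read.csv(path)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop(path, ": expected columns time,x,y,z")
  }
  bad <- which(!stats::complete.cases(df[need]) |
                 !apply(sapply(df[need], is.finite), 1, all))
  if (length(bad)) {
    stop(path, ": malformed/non-finite values at data line(s) ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (any(diff(df$time) <= 0)) {
    stop(path, ": timestamps not strictly increasing (first violation at ",
         "data line ", which(diff(df$time) <= 0)[1] + 1L, ")")
  }
  xyz <- as.matrix(df[c("x", "y", "z")])
  if (input_units == "ms2") xyz <- xyz / 9.81
  if (any(abs(xyz) > 8)) {
    stop(path, ": |acceleration| > 8 g exceeds the device range (+-8 g)")
  }
  ann <- read.csv(annotations_path, stringsAsFactors = FALSE)
  need_ann <- c("participant_id", "activity_code", "start_s", "end_s",
                "gas_minute", "observed_posture")
  if (!all(need_ann %in% names(ann))) {
    stop(annotations_path, ": expected columns ",
         paste(need_ann, collapse = ","))
  }
  if (is.null(participant_id)) {
    ids <- unique(ann$participant_id)
    if (length(ids) != 1L) {
      stop("annotation file holds several participants; pass participant_id")
    }
    participant_id <- ids
  }
  ann <- ann[ann$participant_id == participant_id, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("no annotation intervals for participant ", participant_id)
  }
  colnames(xyz) <- c("x", "y", "z")
  structure(list(participant_id = as.character(participant_id),
                 sample_rate_hz = sample_rate_hz,
                 samples = xyz,
                 time_s = df$time,
                 annotations = ann),
            class = "acc_recording")
}

#' Read a dataset directory written by [write_fixture()]
#'
#' @param dir Directory with `acc_<id>.csv`, `annotations.csv`,
#'   `calorimetry.csv`, `baselines.csv` (and optionally `truth.csv`).
#' @param sample_rate_hz Expected sampling rate (default 60).
#' @return A `thighacc_dataset` (with `truth = NULL` when absent).
#' @export
read_dataset <- function(dir, sample_rate_hz = 60) {
  baselines <- read.csv(file.path(dir, "baselines.csv"),
                        stringsAsFactors = FALSE)
  calorimetry <- read.csv(file.path(dir, "calorimetry.csv"),
                          stringsAsFactors = FALSE)
  annp <- file.path(dir, "annotations.csv")
  recs <- lapply(baselines$participant_id, function(id) {
    read_recording(file.path(dir, paste0("acc_", id, ".csv")), annp,
                   participant_id = id, sample_rate_hz = sample_rate_hz)
  })
  truth_path <- file.path(dir, "truth.csv")
  structure(list(recordings = setNames(recs, baselines$participant_id),
                 calorimetry = calorimetry,
                 baselines = baselines,
                 truth = if (file.exists(truth_path))
                   read.csv(truth_path, stringsAsFactors = FALSE) else NULL,
                 seed = NA_integer_),
            class = "thighacc_dataset")
}

#' Pipeline configuration
#'
#' Central list of every tunable of the pipeline with its default.
#' Unknown keys are rejected.
#'
#' @param ... Overrides, e.g. `pipeline_config(posture_threshold_g = 0.4)`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sample_rate_hz = 60,
    noise_cutoff_hz = 20,
    static_cutoff_hz = 0.5,
    filter_order = 4,
    input_units = "g",
    window_s = 10,
    posture_threshold_g = 0.5,
    ima_quadrature = "rectangle",
    r_threshold = 0.75,
    shadow_selection = TRUE,
    shadow_max_runs = 25,
    n_trees = 100,
    mtry = NULL,
    adjust_method = "bonferroni",
    acceptable_threshold = 80,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Windows, features and metrics for every participant of a dataset
#'
#' Runs decomposition, windowing, feature extraction and metric
#' computation, and joins the per-minute reference labels onto the
#' windows.
#'
#' @param dataset A `thighacc_dataset`.
#' @param config A [pipeline_config()].
#' @return Data frame: one row per window with metadata, the 109 feature
#'   columns, the window metrics (`svm`, `ima`, `tm`, `static_y_mean`) and
#'   the reference `met` and `intensity_class`.
#' @export
extract_windows <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "thighacc_dataset"))
  labels <- reference_labels(dataset$calorimetry, dataset$baselines)
  per_part <- lapply(dataset$recordings, function(rec) {
    dec <- decompose_recording(rec,
                               noise_cutoff_hz = config$noise_cutoff_hz,
                               static_cutoff_hz = config$static_cutoff_hz,
                               order = config$filter_order)
    wins <- segment_windows(dec, rec, window_s = config$window_s)
    feats <- build_feature_matrix(wins, config$sample_rate_hz)
    mets <- window_metrics(wins, config$sample_rate_hz)
    feats$svm <- mets$svm
    feats$ima <- mets$ima
    feats$tm <- mets$tm
    feats$static_y_mean <- mets$static_y_mean
    feats
  })
  win <- do.call(rbind, per_part)
  rownames(win) <- NULL
  key <- paste(win$participant_id, win$minute_id)
  lkey <- paste(labels$participant_id, labels$minute_id)
  idx <- match(key, lkey)
  if (anyNA(idx)) {
    stop("calorimetry sample missing for window minute(s): ",
         paste(head(unique(key[is.na(idx)]), 3), collapse = "; "))
  }
  win$met <- labels$met[idx]
  win$intensity_class <- labels$intensity_class[idx]
  win
}

loso_cutpoint <- function(win, metric_name, config) {
  folds <- loso_split(unique(win$participant_id))
  mats <- list()
  for (f in folds) {
    tr <- win[win$participant_id %in% f$train, ]
    te <- win[win$participant_id == f$test, ]
    model <- calibrate_cutpoints(tr[[metric_name]], tr$met,
                                 metric_name = metric_name,
                                 posture_threshold = config$posture_threshold_g)
    pred <- classify_cutpoint(te[[metric_name]], te$static_y_mean, model)
    mats[[f$test]] <- confusion(pred, te$intensity_class, f$test)
  }
  mats
}

loso_forest <- function(win, feature_cols, config) {
  folds <- loso_split(unique(win$participant_id))
  mats <- list()
  for (f in folds) {
    tr <- win[win$participant_id %in% f$train, ]
    te <- win[win$participant_id == f$test, ]
    model <- train_forest(tr[, feature_cols], tr$intensity_class,
                          n_trees = config$n_trees, seed = config$seed,
                          mtry = config$mtry)
    pred <- predict_forest(model, te[, feature_cols])
    mats[[f$test]] <- confusion(pred, te$intensity_class, f$test)
  }
  mats
}

#' Run the full classification pipeline with LOSO cross-validation
#'
#' Extracts windows and reference labels, then evaluates the three
#' posture-gated cut-off point algorithms (SVM, IMA, TM) and the Random
#' Forest under leave-one-subject-out cross-validation; also trains each
#' algorithm on the full data for the training-sample overfitting check,
#' benchmarks per-participant balanced accuracies against the
#' acceptability threshold, and (optionally) runs the robustness analysis
#' against the baseline characteristics.
#'
#' @param dataset A `thighacc_dataset`.
#' @param config A [pipeline_config()].
#' @param robustness_analysis Run per-characteristic robustness tests
#'   (default TRUE).
#' @param windows Optional precomputed window table from
#'   [extract_windows()] (skips re-extraction).
#' @return A `performance_report`: per algorithm, the per-participant and
#'   overall confusion matrices, overall and per-participant class
#'   performance, benchmark shares, training-sample performance; plus the
#'   feature selection, robustness tables and the effective config.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         robustness_analysis = TRUE, windows = NULL) {
  win <- if (is.null(windows)) extract_windows(dataset, config) else windows
  feat_cols <- feature_schema()$column
  sel_prune <- prune_correlated(win[, feat_cols], config$r_threshold)
  selected <- sel_prune$kept
  sel_shadow <- NULL
  if (isTRUE(config$shadow_selection)) {
    sel_shadow <- shadow_select(win[, selected], win$intensity_class,
                                seed = config$seed,
                                max_runs = config$shadow_max_runs)
    if (length(sel_shadow$confirmed) >= 2L) selected <- sel_shadow$confirmed
  }
  algorithms <- list()
  for (metric_name in c("svm", "ima", "tm")) {
    mats <- loso_cutpoint(win, metric_name, config)
    full_model <- calibrate_cutpoints(win[[metric_name]], win$met,
                                      metric_name = metric_name,
                                      posture_threshold = config$posture_threshold_g)
    train_pred <- classify_cutpoint(win[[metric_name]], win$static_y_mean,
                                    full_model)
    algorithms[[metric_name]] <- assemble_algorithm(
      mats, train_pred, win$intensity_class, config, model = full_model)
  }
  mats <- loso_forest(win, selected, config)
  full_forest <- train_forest(win[, selected], win$intensity_class,
                              n_trees = config$n_trees, seed = config$seed,
                              mtry = config$mtry)
  train_pred <- predict_forest(full_forest, win[, selected])
  algorithms[["random_forest"]] <- assemble_algorithm(
    mats, train_pred, win$intensity_class, config, model = full_forest)
  rob <- NULL
  if (robustness_analysis) {
    rob <- lapply(algorithms, function(alg) {
      per_cls <- lapply(INTENSITY_LEVELS, function(cl) {
        ba <- vapply(alg$per_participant_performance, function(pp) {
          v <- pp$balanced_accuracy[pp$class == cl]
          if (length(v)) v else NA_real_
        }, 0)
        ok <- is.finite(ba)
        if (sum(ok) < 3L) return(NULL)
        r <- robustness(ba[ok], dataset$baselines,
                        adjust = config$adjust_method)
        r$class <- cl
        r
      })
      do.call(rbind, Filter(Negate(is.null), per_cls))
    })
  }
  structure(list(algorithms = algorithms,
                 feature_selection = list(pruning = sel_prune,
                                          shadow = sel_shadow,
                                          selected = selected),
                 robustness = rob,
                 n_windows = nrow(win),
                 participants = unique(win$participant_id),
                 config = config),
            class = "performance_report")
}

assemble_algorithm <- function(per_participant_mats, train_pred,
                               train_ref, config, model = NULL) {
  overall <- sum_confusions(per_participant_mats)
  perf <- class_performance(overall,
                            acceptable_threshold = config$acceptable_threshold)
  pp_perf <- lapply(per_participant_mats, function(m) {
    # a held-out participant may lack windows of some class entirely;
    # those classes are skipped for that participant
    present <- INTENSITY_LEVELS[colSums(unclass(m)) > 0]
    class_performance(m, class = present,
                      acceptable_threshold = config$acceptable_threshold)
  })
  bench <- vapply(INTENSITY_LEVELS, function(cl) {
    ba <- unlist(lapply(pp_perf, function(pp) {
      pp$balanced_accuracy[pp$class == cl]
    }))
    benchmark(ba, config$acceptable_threshold)
  }, 0)
  list(per_participant = per_participant_mats,
       per_participant_performance = pp_perf,
       overall_confusion = overall,
       performance = perf,
       benchmark = bench,
       training_performance = training_sample_check(train_pred, train_ref),
       model = model)
}

#' @export
print.performance_report <- function(x, ...) {
  cat("LOSO performance report:", length(x$participants), "participants,",
      x$n_windows, "windows\n")
  for (nm in names(x$algorithms)) {
    alg <- x$algorithms[[nm]]
    cat("\n--", toupper(nm), "--\n")
    perf <- alg$performance
    for (i in seq_len(nrow(perf))) {
      cat(sprintf("  %-9s sens %5.1f  spec %5.1f  BA %5.1f  acceptable %5.1f%%  train BA %5.1f\n",
                  perf$class[i], perf$sensitivity[i], perf$specificity[i],
                  perf$balanced_accuracy[i], alg$benchmark[[as.character(perf$class[i])]],
                  alg$training_performance$balanced_accuracy[i]))
    }
  }
  invisible(x)
}

#' Write a performance report to JSON and CSV
#'
#' Emits `report.json` (full structure: confusion counts, performance,
#' benchmark, config) and `report.csv` (one row per algorithm x class x
#' participant plus "overall").
#'
#' @param report A `performance_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "performance_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (nm in names(report$algorithms)) {
    alg <- report$algorithms[[nm]]
    ov <- alg$performance
    ov$participant_id <- "overall"
    ov$algorithm <- nm
    rows[[length(rows) + 1L]] <- ov
    for (pid in names(alg$per_participant_performance)) {
      pp <- alg$per_participant_performance[[pid]]
      pp$participant_id <- pid
      pp$algorithm <- nm
      rows[[length(rows) + 1L]] <- pp
    }
  }
  csv <- do.call(rbind, rows)
  csv_path <- file.path(dir, "report.csv")
  write.csv(csv, csv_path, row.names = FALSE)
  json <- list(
    participants = report$participants,
    n_windows = report$n_windows,
    config = unclass(report$config),
    selected_features = report$feature_selection$selected,
    algorithms = lapply(report$algorithms, function(alg) {
      list(confusion = unclass(alg$overall_confusion),
           performance = alg$performance,
           benchmark = as.list(alg$benchmark),
           training_performance = alg$training_performance)
    }))
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(c(csv_path, json_path))
}
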