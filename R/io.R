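COHORT_COLUMNS <- c("patient_id", "time_months", "event", "art", "age",
                    "afs", "csge", "emt_mm", "image_dir")

#' Read a cohort CSV
#'
#' Schema (header required): `patient_id, time_months, event, art, age, afs,
#' csge, emt_mm, image_dir`; missing covariates may be empty. Validation
#' failures name the offending column and row. The ART censoring convention
#' is applied on read: under the default `"censor_at_art"`, patients who
#' started ART are right-censored at ART initiation for the
#' natural-conception model (their raw follow-up is kept in `time_raw` /
#' `event_raw`); `"keep_at_risk"` leaves follow-up untouched.
#'
#' @param path CSV file.
#' @param art_handling `"censor_at_art"` (default) or `"keep_at_risk"`.
#' @param art_start_month ART initiation time used by the censoring rule.
#' @param image_root optional directory against which `image_dir` entries are
#'   resolved and checked.
#' @return object of class `cohort_table`: `records` data frame plus an
#'   `image_index` (patient_id -> image paths) when `image_root` is given.
#' @export
read_cohort <- function(path, art_handling = c("censor_at_art", "keep_at_risk"),
                        art_start_month = 12, image_root = NULL) {
  art_handling <- match.arg(art_handling)
  if (!file.exists(path)) hs_error("missing-file", paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    hs_error("missing-column",
             paste0("cohort CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  df$patient_id <- as.character(df$patient_id)
  df$image_dir <- as.character(df$image_dir)
  df$image_dir[is.na(df$image_dir)] <- ""
  for (col in c("time_months", "event", "art")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      hs_error("non-numeric",
               paste0("column '", col, "' non-numeric at row(s) ",
                      paste(which(is.na(v)), collapse = ", ")))
    df[[col]] <- v
  }
  if (anyDuplicated(df$patient_id))
    hs_error("duplicate-id",
             paste0("duplicate patient_id: ",
                    paste(unique(df$patient_id[duplicated(df$patient_id)]),
                          collapse = ", ")))
  bad_t <- which(df$time_months <= 0)
  if (length(bad_t) > 0)
    hs_error("invalid-time", paste0("time_months <= 0 at row(s) ",
                                    paste(bad_t, collapse = ", ")))
  bad_e <- which(!df$event %in% c(0, 1))
  if (length(bad_e) > 0)
    hs_error("invalid-event", paste0("event not 0/1 at row(s) ",
                                     paste(bad_e, collapse = ", ")))
  bad_a <- which(!df$art %in% c(0, 1))
  if (length(bad_a) > 0)
    hs_error("invalid-art", paste0("art not 0/1 at row(s) ",
                                   paste(bad_a, collapse = ", ")))
  df$time_raw <- df$time_months
  df$event_raw <- df$event
  if (art_handling == "censor_at_art") {
    started <- df$art == 1 & df$time_months > art_start_month
    df$event[started] <- 0
    df$time_months[started] <- art_start_month
  }
  image_index <- NULL
  if (!is.null(image_root)) {
    image_index <- lapply(seq_len(nrow(df)), function(i) {
      d <- file.path(image_root, df$image_dir[i])
      if (df$image_dir[i] == "" || !dir.exists(d)) return(character(0))
      list.files(d, pattern = "\\.(png|PNG)$", full.names = TRUE)
    })
    names(image_index) <- df$patient_id
    orphans <- df$patient_id[vapply(image_index, length, numeric(1)) == 0]
    if (length(orphans) > 0)
      warning("patients without images: ", paste(orphans, collapse = ", "))
  }
  structure(list(records = df, image_index = image_index,
                 art_handling = art_handling,
                 art_start_month = art_start_month),
            class = "cohort_table")
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()] (round-trip identity on the raw columns).
#'
#' @param cohort a `cohort_table` or a records data frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  df <- if (inherits(cohort, "cohort_table")) cohort$records else cohort
  if ("time_raw" %in% names(df)) {
    df$time_months <- df$time_raw
    df$event <- df$event_raw
  }
  utils::write.csv(df[, COHORT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

REPORT_SCHEMA_VERSION <- 1L

#' Assemble an evaluation report
#'
#' Bundles c-index, time-AUC points, calibration tables and model
#' comparisons into one serializable report.
#'
#' @param model_id label of the evaluated model.
#' @param cindex a `concordance_result`.
#' @param auc a `time_auc_curve` (list of `time_auc_point`s).
#' @param calibration named list (by horizon) of `calibration_table`s.
#' @param comparisons list of lists `(vs, metric, p)`.
#' @param config_hash hash of the run configuration.
#' @export
evaluation_report <- function(model_id, cindex, auc = list(),
                              calibration = list(), comparisons = list(),
                              config_hash = "") {
  structure(list(model_id = model_id,
                 c_index = list(est = cindex$c_index, lo = cindex$ci_low,
                                hi = cindex$ci_high),
                 auc = lapply(auc, function(p)
                   list(horizon = p$horizon, est = p$auc, lo = p$ci_low,
                        hi = p$ci_high)),
                 calibration = lapply(names(calibration), function(h)
                   list(horizon = as.numeric(h),
                        bins = calibration[[h]])),
                 comparisons = comparisons,
                 config_hash = config_hash),
            class = "evaluation_report")
}

#' Write / read a JSON report
#'
#' Reports (`evaluation_report`, `stratum_table`, `complexity_report`) are
#' serialized with a schema version and the config hash of the producing
#' run; reading a file with an unknown schema version is an explicit error.
#'
#' @param report the report object.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  type <- class(report)[1]
  payload <- if (is.data.frame(report)) as.data.frame(report) else unclass(report)
  obj <- list(schema_version = REPORT_SCHEMA_VERSION, type = type,
              payload = payload)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != REPORT_SCHEMA_VERSION)
    hs_error("schema-version",
             paste0("unknown report schema version: ",
                    obj$schema_version %||% "absent"))
  obj
}

config_hash <- function(x) rlang::hash(x)

log_json_line <- function(path, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA, null = "null")
  cat(line, "\n", file = path, append = TRUE, sep = "")
}

# ---- command-line interface ------------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) hs_error("bad-flag", paste0("expected --flag, got ", a))
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      out[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  out
}

cli_num <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) return(default)
  as.numeric(v)
}

#' Command-line entry point
#'
#' Dispatches the pipeline commands `simulate`, `train`, `predict`,
#' `evaluate`, `gradcam`, `stratify`, `complexity`. Every command appends a
#' JSON-lines log record (command, options, config hash, seed, package
#' version) next to its output. Returns 0 on success and 1 on error (the
#' installed `inst/cli/hysterosurv` wrapper turns that into the process exit
#' code).
#'
#' @param args character vector, e.g.
#'   `c("simulate", "--n", "50", "--seed", "7", "--out", "dir")`.
#' @return integer exit status, invisibly.
#' @export
iua_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) hs_error("no-command", "usage: hysterosurv <command> [--flags]")
    cmd <- args[1]
    opts <- parse_cli_args(args[-1])
    switch(cmd,
      simulate = cli_simulate(opts),
      train = cli_train(opts),
      predict = cli_predict(opts),
      evaluate = cli_evaluate(opts),
      gradcam = cli_gradcam(opts),
      stratify = cli_stratify(opts),
      complexity = cli_complexity(opts),
      hs_error("unknown-command", paste0("unknown command: ", cmd)))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_log <- function(out_dir, cmd, opts, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_json_line(file.path(out_dir, "log.jsonl"),
                list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     command = cmd, options = opts,
                     config_hash = config_hash(opts), seed = seed,
                     version = as.character(utils::packageVersion("hysterosurv"))))
}

cli_simulate <- function(opts) {
  out <- opts$out %||% hs_error("missing-flag", "--out required")
  seed <- cli_num(opts, "seed") %||% hs_error("missing-flag", "--seed required")
  cfg <- generator_config(
    n_patients = cli_num(opts, "n", 100),
    images_per_patient = cli_num(opts, "images_per_patient", 3),
    image_size = cli_num(opts, "image_size", 48),
    beta_severity = cli_num(opts, "beta_severity", -1.2),
    seed = seed)
  generate_cohort(cfg, dir = out)
  cli_log(out, "simulate", opts, seed)
}

cli_load_images <- function(cohort, root, spec) {
  idx <- cohort$image_index
  lapply(idx, function(paths)
    lapply(paths, function(p) preprocess_image(png::readPNG(p), spec)))
}

cli_train <- function(opts) {
  cohort_csv <- opts$cohort %||% hs_error("missing-flag", "--cohort required")
  img_root <- opts$images %||% hs_error("missing-flag", "--images required")
  out <- opts$out %||% hs_error("missing-flag", "--out required")
  seed <- as.integer(cli_num(opts, "seed", 1))
  image_size <- as.integer(cli_num(opts, "image_size", 48))
  cohort <- read_cohort(cohort_csv, image_root = img_root)
  spec <- backbone_spec(opts$backbone %||% "tiny_test", input_size = image_size)
  imgs <- cli_load_images(cohort, img_root, spec)
  rec <- cohort$records
  flat <- unlist(imgs, recursive = FALSE)
  reps <- vapply(imgs, length, numeric(1))
  times <- rep(rec$time_months, reps)
  events <- rep(rec$event, reps)
  cfg <- train_config(
    learning_rate = cli_num(opts, "learning_rate", 0.01),
    epochs = as.integer(cli_num(opts, "epochs", 30)),
    batch_size = as.integer(cli_num(opts, "batch_size", 16)),
    seed = seed)
  model <- build_model(spec, seed = seed)
  model <- train_deepsurv(model, flat, times, events, cfg)
  # patient-level scores on the training cohort fix the baseline hazard
  scores <- vapply(imgs, function(im) predict_patient(model, im)$log_hazard,
                   numeric(1))
  model$baseline <- breslow_cumulative_hazard(scores, rec$time_months, rec$event)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(model, out)
  cli_log(dirname(out), "train", opts, seed)
}

cli_scores_for <- function(opts) {
  model <- load_checkpoint(opts$checkpoint %||% hs_error("missing-flag", "--checkpoint required"))
  img_root <- opts$images %||% hs_error("missing-flag", "--images required")
  cohort <- read_cohort(opts$cohort, image_root = img_root)
  imgs <- cli_load_images(cohort, img_root, model$backbone)
  empty <- names(imgs)[vapply(imgs, length, numeric(1)) == 0]
  if (length(empty) > 0)
    hs_error("no-images", paste0("patient(s) without images: ",
                                 paste(empty, collapse = ", ")))
  scores <- vapply(imgs, function(im) predict_patient(model, im)$log_hazard,
                   numeric(1))
  list(model = model, cohort = cohort, scores = scores)
}

cli_predict <- function(opts) {
  out <- opts$out %||% hs_error("missing-flag", "--out required")
  r <- cli_scores_for(opts)
  df <- data.frame(patient_id = r$cohort$records$patient_id,
                   log_hazard = unname(r$scores))
  if (!is.null(r$model$baseline)) {
    df$p_conception_12m <- predicted_event_probability(df$log_hazard,
                                                       r$model$baseline, 12)
    df$p_conception_24m <- predicted_event_probability(df$log_hazard,
                                                       r$model$baseline, 24)
  }
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, out, row.names = FALSE)
  cli_log(dirname(out), "predict", opts)
}

cli_evaluate <- function(opts) {
  out <- opts$out %||% hs_error("missing-flag", "--out required")
  seed <- as.integer(cli_num(opts, "seed", 1))
  B <- as.integer(cli_num(opts, "bootstrap", 200))
  horizons <- as.numeric(strsplit(opts$horizons %||% "12,24,48", ",")[[1]])
  r <- cli_scores_for(opts)
  rec <- r$cohort$records
  ci <- harrell_cindex(r$scores, rec$time_months, rec$event, B = B, seed = seed)
  auc <- suppressWarnings(
    time_auc_curve(r$scores, rec$time_months, rec$event, horizons,
                   B = B, seed = seed))
  calib <- list()
  if (!is.null(r$model$baseline)) {
    for (h in horizons) {
      p <- predicted_event_probability(r$scores, r$model$baseline, h)
      calib[[as.character(h)]] <-
        calibration_table(p, rec$time_months, rec$event, h)
    }
  }
  rep <- evaluation_report(r$model$backbone$name %||% "model", ci, auc, calib,
                           config_hash = config_hash(opts[setdiff(names(opts), "out")]))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_report(rep, out)
  cli_log(dirname(out), "evaluate", opts, seed)
}

cli_gradcam <- function(opts) {
  model <- load_checkpoint(opts$checkpoint %||% hs_error("missing-flag", "--checkpoint required"))
  img_path <- opts$image %||% hs_error("missing-flag", "--image required")
  out <- opts$out %||% hs_error("missing-flag", "--out required")
  sign <- opts$sign %||% "risk-of-subfertility"
  alpha <- cli_num(opts, "alpha", 0.4)
  raw <- png::readPNG(img_path)
  img <- preprocess_image(raw, model$backbone)
  hm <- grad_cam(model, img,
                 target_layer = if (!is.null(opts$layer)) as.integer(opts$layer),
                 sign = sign)
  disp <- (img - min(img)) / max(max(img) - min(img), 1e-12)
  ov <- overlay_heatmap(hm, disp, alpha = alpha)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(ov, out)
  cli_log(dirname(out), "gradcam", opts)
}

cli_stratify <- function(opts) {
  out <- opts$out %||% hs_error("missing-flag", "--out required")
  preds_csv <- opts$predictions %||% hs_error("missing-flag", "--predictions required")
  cohort <- read_cohort(opts$cohort %||% hs_error("missing-flag", "--cohort required"),
                        art_handling = "keep_at_risk")
  preds <- utils::read.csv(preds_csv, stringsAsFactors = FALSE)
  m <- match(cohort$records$patient_id, preds$patient_id)
  if (any(is.na(m))) hs_error("prediction-mismatch", "predictions missing for some patients")
  strats <- strsplit(opts$stratifiers %||% "model,afs,csge,emt", ",")[[1]]
  tab <- stratification_table(cohort$records, preds$p_conception_12m[m],
                              threshold = cli_num(opts, "threshold", 0.5),
                              stratifiers = strats,
                              time_dependent = isTRUE(opts$time_dependent == "true"))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_report(tab, out)
  utils::write.csv(tab, sub("\\.json$", ".csv", out), row.names = FALSE)
  cli_log(dirname(out), "stratify", opts)
}

cli_complexity <- function(opts) {
  out <- opts$out %||% hs_error("missing-flag", "--out required")
  name <- opts$backbone %||% hs_error("missing-flag", "--backbone required")
  rep <- complexity_report(name,
                           input_size = cli_num(opts, "input_size"),
                           measure_time = isTRUE(opts$measure_time == "true"))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  write_report(rep, out)
  cli_log(dirname(out), "complexity", opts)
}
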