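#' Pipeline configuration
#'
#' A fully serializable description of an end-to-end run: input locations,
#' segmentation and feature parameters, model family and protocol
#' parameters, and the master seed. A run's config plus seed reproduces its
#' outputs byte for byte.
#'
#' @param cohort_table path to a delimited cohort table with columns `id`,
#'   `age`, `gender`, `sfbbs_item1..sfbbs_item7`, `recording_path`.
#' @param out_dir output directory for run artifacts.
#' @param still_window calibration window, s.
#' @param seg,feat parameter lists from [seg_params()] /
#'   [feature_config()].
#' @param model `"enet"` (tuned elastic net), `"ridge"`, `"lasso"` or
#'   `"tree"`.
#' @param n_iter,test_frac,inner_folds protocol parameters, see
#'   [run_rsscv()].
#' @param tasks SFBBS item numbers to classify (default 3, 6, 7 — the
#'   reaching, feet-in-line and single-leg items).
#' @param seed master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_table, out_dir, still_window = c(0, 1),
                            seg = seg_params(), feat = feature_config(),
                            model = c("enet", "ridge", "lasso", "tree"),
                            n_iter = 100, test_frac = 0.2, inner_folds = 10,
                            tasks = c(3, 6, 7), seed = 1) {
  model <- match.arg(model)
  structure(list(cohort_table = cohort_table, out_dir = out_dir,
                 still_window = still_window, seg = seg, feat = feat,
                 model = model, n_iter = n_iter, test_frac = test_frac,
                 inner_folds = inner_folds, tasks = tasks, seed = seed),
            class = "pipeline_config")
}

# FNV-1a 32-bit over the serialized config (no hashing package available)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # multiply by the FNV prime mod 2^32 in two pieces to stay exact
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- ((hi16 * 16777619) %% 65536 * 65536 + lo16 * 16777619) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format in two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a cohort table and its recordings
#'
#' @param path delimited cohort table (see [pipeline_config()]); relative
#'   `recording_path`s are resolved against the table's directory.
#' @param dialect recording file dialect, see [recording_dialect()].
#' @return List of [participant_record()]s.
#' @export
read_cohort <- function(path, dialect = recording_dialect()) {
  if (!file.exists(path)) abort_argument(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "gender", paste0("sfbbs_item", 1:7),
            "recording_path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(paste("cohort table missing columns:",
                       paste(miss, collapse = ", ")))
  lapply(seq_len(nrow(df)), function(i) {
    rp <- df$recording_path[i]
    if (!file.exists(rp)) rp <- file.path(dirname(path), rp)
    items <- as.numeric(df[i, paste0("sfbbs_item", 1:7)])
    participant_record(df$id[i], df$age[i], df$gender[i],
                       read_recording(rp, dialect), sfbbs_record(items))
  })
}

#' Write a simulated cohort to disk
#'
#' Writes one recording file per participant, the cohort table, and a
#' ground-truth JSON — the layout [read_cohort()] and [run_pipeline()]
#' consume.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tug_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "recordings"), showWarnings = FALSE)
  paths <- character()
  for (p in cohort$participants) {
    rp <- file.path("recordings", paste0(p$id, ".csv"))
    write_recording(p$recording, file.path(dir, rp))
    paths <- c(paths, rp)
  }
  tab <- data.frame(id = vapply(cohort$participants, `[[`, "", "id"),
                    age = vapply(cohort$participants, `[[`, 0, "age"),
                    gender = vapply(cohort$participants, `[[`, 0, "gender"))
  for (j in 1:7)
    tab[[paste0("sfbbs_item", j)]] <-
      vapply(cohort$participants, function(p) p$sfbbs$items[j], 0)
  tab$recording_path <- paths
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Run the full balance-assessment pipeline
#'
#' Executes calibrate, segment, extract, train (and per-item classify) and
#' writes every artifact — feature table, regression metrics, importance
#' table, per-task classification reports and ROC points — into the run
#' directory, each stamped with the config hash so a mismatched resume is
#' refused. Per-participant stage failures are recorded and skipped; the
#' pipeline aborts only if more than 20% of records fail.
#'
#' @param config a [pipeline_config()].
#' @param overwrite allow writing into a run directory created under a
#'   different config.
#' @return Invisibly, a list with the feature table, the regression
#'   `rsscv` result, the importance report and per-task `subtask_rsscv`
#'   results.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$cohort_table))
    abort_argument(paste("no such cohort table:", config$cohort_table))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "run_config.json")
  if (file.exists(cfg_path) && !overwrite) {
    old <- jsonlite::read_json(cfg_path)
    if (!identical(old$config_hash, hash))
      abort_argument("run directory holds a different config; refusing resume")
  }
  jsonlite::write_json(c(list(config_hash = hash),
                         unclass(config)[setdiff(names(config), "out_dir")]),
                       cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  participants <- read_cohort(config$cohort_table)
  features <- extract_cohort_features(participants, config$still_window,
                                      config$seg, config$feat)
  fails <- attr(features, "failures")
  if (length(fails) > 0.2 * length(participants))
    abort_data(sprintf("%d of %d records failed processing",
                       length(fails), length(participants)))
  write_stamped_csv(features, file.path(config$out_dir, "features.csv"),
                    hash)

  reg <- feature_registry()
  X <- as.matrix(features[, reg$name])
  y <- features$sfbbs_total
  alpha_fix <- switch(config$model, ridge = 0, lasso = 1, NULL)

  out <- list(features = features)
  if (config$model == "tree") {
    Xi <- impute_cols(X, colMeans(X, na.rm = TRUE))
    out$model <- fit_regression_tree(Xi, y)
    m <- evaluate(y, predict(out$model, Xi))
    jsonlite::write_json(list(config_hash = hash, model = "tree",
                              train_mae = m$mae, train_rmse = m$rmse),
                         file.path(config$out_dir, "regression_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    res <- run_rsscv(X, y, family = "gaussian", n_iter = config$n_iter,
                     test_frac = config$test_frac,
                     inner_folds = config$inner_folds, alpha = alpha_fix,
                     seed = config$seed)
    out$regression <- res
    it <- res$iterations[res$iterations$valid, ]
    jsonlite::write_json(
      list(config_hash = hash, model = config$model, seed = config$seed,
           mean_mae = mean(it$mae), sd_mae = stats::sd(it$mae),
           mean_rmse = mean(it$rmse), sd_rmse = stats::sd(it$rmse),
           iterations = it),
      file.path(config$out_dir, "regression_metrics.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    imp <- relative_importance(res)
    out$importance <- imp
    write_stamped_csv(as.data.frame(imp),
                      file.path(config$out_dir, "importance.csv"), hash)

    out$subtasks <- list()
    for (task in config$tasks) {
      scores <- features[[paste0("sfbbs_item", task)]]
      sub <- tryCatch(
        run_subtask_rsscv(X, scores, task = task, n_iter = config$n_iter,
                          test_frac = config$test_frac,
                          inner_folds = config$inner_folds,
                          seed = config$seed),
        tug_error = function(e) e)
      if (inherits(sub, "error")) {
        message(sprintf("task %s skipped: %s", task, conditionMessage(sub)))
        next
      }
      out$subtasks[[as.character(task)]] <- sub
      jsonlite::write_json(
        list(config_hash = hash, task = task,
             per_iteration_mean = sub$metrics_mean,
             pooled = unclass(sub$metrics_pooled),
             pooled_auc = sub$pooled_auc),
        file.path(config$out_dir,
                  sprintf("subtask_%s_metrics.json", task)),
        auto_unbox = TRUE, digits = NA)
      write_stamped_csv(sub$roc$points,
                        file.path(config$out_dir,
                                  sprintf("subtask_%s_roc.csv", task)),
                        hash)
    }
  }
  invisible(out)
}

# CSV with the config hash embedded as a leading comment line
write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a hash-stamped CSV written by the pipeline
#'
#' @param path file path.
#' @return data.frame; the embedded hash is in attribute `config_hash`.
#' @export
read_stamped_csv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "config_hash") <- sub("^# config_hash=", "", first)
  df
}
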