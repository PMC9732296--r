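#' Seed-deterministic random train/test split
#'
#' @param records Data frame of measurement records.
#' @param n_test Number of records held out for testing.
#' @param seed Integer seed; the split is a pure function of
#'   `(nrow(records), n_test, seed)`.
#' @return List with data frames `train` and `test` and the integer
#'   hold-out indices `test_index`. The two parts are disjoint and
#'   exhaust the input.
#' @export
split_train_test <- function(records, n_test = 32L, seed = 1L) {
  n <- nrow(records)
  if (n_test < 1L || n_test >= n) {
    stop("'n_test' must be in [1, nrow(records) - 1]", call. = FALSE)
  }
  set.seed(seed)
  test_index <- sort(sample.int(n, n_test))
  list(train = records[-test_index, , drop = FALSE],
       test = records[test_index, , drop = FALSE],
       test_index = test_index)
}

#' Configuration for an end-to-end calibration run
#'
#' @param generator A [titration_config()] describing the synthetic
#'   experiment. The pipeline default raises the basal glucose to
#'   80 mg/dl (a realistic pre-titration level, which also keeps every
#'   reference reading strictly positive for the relative-difference
#'   statistics).
#' @param input Optional path to a measurements CSV
#'   ([read_measurements()]); when given, generation is skipped.
#' @param kernel,control Passed to [rvm()].
#' @param n_test Hold-out size for the random split.
#' @param seed Master seed: generation uses `seed`, the split `seed + 1`.
#' @param parkes_type Diabetes type for the consensus grid.
#' @param seg_grid Risk lattice for the surveillance grid; the surrogate
#'   surface by default.
#' @param scope Evaluate error grids and agreement over `"all"` records
#'   (predictions from the fitted model on every batch) or `"test"` only.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = titration_config(basal_glucose = 80),
                            input = NULL,
                            kernel = rvm_kernel(),
                            control = rvm_control(),
                            n_test = 32L,
                            seed = 1L,
                            parkes_type = c("type2", "type1"),
                            seg_grid = NULL,
                            scope = c("all", "test")) {
  stopifnot(inherits(generator, "titration_config"))
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input, call. = FALSE)
  }
  structure(list(
    generator = generator, input = input, kernel = kernel, control = control,
    n_test = as.integer(n_test), seed = as.integer(seed),
    parkes_type = match.arg(parkes_type),
    seg_grid = if (is.null(seg_grid)) seg_surrogate_grid() else seg_grid,
    scope = match.arg(scope)
  ), class = "pipeline_config")
}

#' Run the calibration and evaluation pipeline
#'
#' Generates (or loads) a titration measurement table, splits it into
#' training and hold-out sets, fits the relevance vector machine mapping
#' `(g_add, v_u)` to the reference meter reading, predicts glucose over
#' the evaluation scope, and evaluates the predicted-vs-reference pairs
#' with the Clarke, Parkes and surveillance error grids and the full
#' agreement report. Fully reproducible: every number in the result is a
#' deterministic function of the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, `measurements.csv`,
#'   `model.json` and `report.json` are written there.
#' @return Object of class `"glucose_run"`: the configuration, the
#'   measurement table, the split, the fitted `"rvm"` model, the
#'   evaluation pairs (`ref`, `pred`), the `"agreement_report"`, the zone
#'   summaries (`clarke`, `parkes`, `seg`), and a file `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(pipeline_config(
#'   generator = titration_config(n_batches = 40, basal_glucose = 80),
#'   n_test = 10, seed = 42))
#' run
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  if (is.null(config$input)) {
    gen <- config$generator
    gen$seed <- config$seed
    measurements <- generate_titration(gen)
  } else {
    measurements <- read_measurements(config$input)
  }

  split <- split_train_test(measurements, config$n_test, config$seed + 1L)
  model <- rvm(cbgm ~ g_add + v_u, data = split$train,
               kernel = config$kernel, control = config$control)

  eval_data <- if (config$scope == "all") measurements else split$test
  pred <- pmax(predict(model, eval_data), 0)
  ref <- eval_data$cbgm
  if (any(ref <= 0)) {
    stop(paste("non-positive reference readings in the evaluation scope;",
               "raise 'basal_glucose' or 'glucose_start'"), call. = FALSE)
  }

  states <- unique(eval_data$state)
  report <- agreement_report(ref, pred,
                             state = if (all(states %in% c("fasting", "postmeal")))
                               eval_data$state else NULL)
  zones <- list(
    clarke = summarize_zones(ref, pred, "clarke"),
    parkes = summarize_zones(ref, pred,
                             if (config$parkes_type == "type1") "parkes_t1"
                             else "parkes_t2"),
    seg = summarize_zones(ref, pred, "seg", seg_grid = config$seg_grid)
  )

  manifest <- character(0)
  run <- structure(list(
    config = config, measurements = measurements, split = split,
    model = model, ref = ref, pred = pred,
    report = report, zones = zones,
    manifest = manifest,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "glucose_run")

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    paths <- c(
      measurements = file.path(output_dir, "measurements.csv"),
      model = file.path(output_dir, "model.json"),
      report = file.path(output_dir, "report.json")
    )
    write_measurements(measurements, paths[["measurements"]])
    write_rvm(model, paths[["model"]])
    jsonlite::write_json(run_report(run), paths[["report"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    run$manifest <- paths
  }
  run
}

# flat, serializable view of a run: provenance + every reported number
run_report <- function(run) {
  zones_as_list <- function(z) {
    list(n_total = attr(z, "n_total"),
         zone = z$zone, n = z$n, pct = z$pct)
  }
  list(
    provenance = list(
      seed = run$config$seed,
      timestamp = run$timestamp,
      scope = run$config$scope,
      parkes_type = run$config$parkes_type,
      seg_provenance = run$config$seg_grid$provenance,
      n_records = nrow(run$measurements),
      n_test = run$config$n_test
    ),
    model = list(
      kernel = run$model$kernel$kind,
      kernel_width = run$model$kernel$width,
      n_relevance_vectors = length(run$model$relevance_index),
      sigma2 = run$model$sigma2,
      converged = run$model$converged,
      iterations = run$model$iterations
    ),
    agreement = list(
      n = run$report$n,
      ncc = run$report$ncc,
      bias_pct = run$report$bias_pct,
      mard_pct = run$report$mard_pct,
      sd_rel_pct = run$report$sd_rel_pct,
      ba_bias = run$report$bland_altman$bias,
      ba_limits = as.numeric(run$report$bland_altman$limits),
      p_value = run$report$p_value
    ),
    zones = lapply(run$zones, zones_as_list)
  )
}

#' @export
print.glucose_run <- function(x, ...) {
  cat("Glucose calibration run\n")
  cat(sprintf("  %d records (%s), %d train / %d test, scope: %s\n",
              nrow(x$measurements),
              if (is.null(x$config$input)) "generated" else "loaded",
              nrow(x$split$train), nrow(x$split$test), x$config$scope))
  cat(sprintf("  model: %s kernel, %d relevance vectors, noise SD %.3g mg/dl\n",
              x$model$kernel$kind, length(x$model$relevance_index),
              sqrt(x$model$sigma2)))
  cat(sprintf("  NCC %.4f | bias %.2f%% | MARD %.2f%% | SD %.2f%% | p = %.3g\n",
              x$report$ncc, x$report$bias_pct, x$report$mard_pct,
              x$report$sd_rel_pct, x$report$p_value))
  a_pct <- function(z) { i <- match("A", z$zone); if (is.na(i)) 0 else z$pct[i] }
  green <- x$zones$seg
  g_pct <- { i <- match("none", green$zone); if (is.na(i)) 0 else green$pct[i] }
  cat(sprintf("  Clarke A: %.1f%% | Parkes(%s) A: %.1f%% | SEG no-risk: %.1f%% (%s surface)\n",
              a_pct(x$zones$clarke), x$config$parkes_type, a_pct(x$zones$parkes),
              g_pct, attr(green, "provenance")))
  invisible(x)
}
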