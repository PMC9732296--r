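#' Configuration for the synthetic glucose titration generator
#'
#' Describes one in-vitro titration run: glucose is added to a fixed blood
#' sample in equal increments, the ultrasonic receiver voltage is read after
#' each addition, and a commercial reference meter reads the same sample.
#' The generator reproduces the statistical structure of that experiment:
#' an equally spaced latent glucose grid, a strictly monotone voltage
#' response around a water-calibration baseline, additive Gaussian sensor
#' noise, and multiplicative (constant-CV) reference-meter error.
#'
#' @param n_batches Number of titration batches. If `NULL`, derived from
#'   `glucose_start`, `glucose_step` and `glucose_max` as the number of
#'   steps that fit in the range.
#' @param glucose_step Glucose added per batch, mg/dl.
#' @param glucose_start Added glucose in the first batch, mg/dl.
#' @param glucose_max Upper end of the added-glucose range, mg/dl. Only used
#'   to derive `n_batches` when that is `NULL`.
#' @param basal_glucose Glucose already present in the sample before any
#'   addition, mg/dl. Latent glucose is `basal_glucose + added glucose`.
#' @param baseline_voltage Receiver voltage at zero glucose, mV (the
#'   distilled-water calibration reading).
#' @param response Functional form of the voltage response: `"linear"`
#'   (baseline + slope * glucose) or `"logistic"` (saturating).
#' @param slope Voltage change per unit glucose for the linear form,
#'   mV per mg/dl. Negative by default: voltage falls as glucose rises.
#' @param logistic_amplitude Total voltage swing of the logistic form, mV
#'   (sign sets the direction).
#' @param logistic_midpoint Glucose at the logistic inflection, mg/dl.
#' @param logistic_scale Logistic width parameter, mg/dl.
#' @param sensor_noise_sd SD of additive Gaussian noise on the receiver
#'   voltage, mV.
#' @param meter_cv Coefficient of variation of the reference meter
#'   (multiplicative relative error), dimensionless, in `[0, 1)`.
#' @param seed Integer seed making generation deterministic; `NULL` leaves
#'   the RNG state alone.
#'
#' @return An object of class `"titration_config"`.
#' @seealso [generate_titration()], [sensor_response()]
#' @export
#' @examples
#' cfg <- titration_config(n_batches = 5, sensor_noise_sd = 0, meter_cv = 0, seed = 1)
#' generate_titration(cfg)
titration_config <- function(n_batches = 125,
                             glucose_step = 4,
                             glucose_start = 0,
                             glucose_max = 450,
                             basal_glucose = 0,
                             baseline_voltage = 19,
                             response = c("linear", "logistic"),
                             slope = -0.01,
                             logistic_amplitude = -5,
                             logistic_midpoint = 225,
                             logistic_scale = 75,
                             sensor_noise_sd = 0.25,
                             meter_cv = 0.03,
                             seed = NULL) {
  response <- match.arg(response)
  if (glucose_step <= 0) stop("'glucose_step' must be positive", call. = FALSE)
  if (glucose_start < 0) stop("'glucose_start' must be non-negative", call. = FALSE)
  if (basal_glucose < 0) stop("'basal_glucose' must be non-negative", call. = FALSE)
  if (sensor_noise_sd < 0) stop("'sensor_noise_sd' must be non-negative", call. = FALSE)
  if (meter_cv < 0 || meter_cv >= 1) stop("'meter_cv' must be in [0, 1)", call. = FALSE)
  if (is.null(n_batches)) {
    if (glucose_max <= glucose_start) {
      stop("'glucose_max' must exceed 'glucose_start' when 'n_batches' is NULL",
           call. = FALSE)
    }
    n_batches <- floor((glucose_max - glucose_start) / glucose_step) + 1L
  }
  n_batches <- as.integer(n_batches)
  if (n_batches < 1L) stop("'n_batches' must be at least 1", call. = FALSE)
  if (response == "linear" && slope == 0) {
    stop("linear response requires a nonzero 'slope'", call. = FALSE)
  }
  if (response == "logistic" && (logistic_amplitude == 0 || logistic_scale <= 0)) {
    stop("logistic response requires nonzero amplitude and positive scale",
         call. = FALSE)
  }
  structure(list(
    n_batches = n_batches, glucose_step = glucose_step,
    glucose_start = glucose_start, glucose_max = glucose_max,
    basal_glucose = basal_glucose, baseline_voltage = baseline_voltage,
    response = response, slope = slope,
    logistic_amplitude = logistic_amplitude,
    logistic_midpoint = logistic_midpoint, logistic_scale = logistic_scale,
    sensor_noise_sd = sensor_noise_sd, meter_cv = meter_cv, seed = seed
  ), class = "titration_config")
}

#' @export
print.titration_config <- function(x, ...) {
  cat("Titration generator configuration\n")
  cat(sprintf("  batches: %d, added glucose %g to %g mg/dl in %g mg/dl steps\n",
              x$n_batches, x$glucose_start,
              x$glucose_start + (x$n_batches - 1L) * x$glucose_step,
              x$glucose_step))
  cat(sprintf("  basal glucose: %g mg/dl\n", x$basal_glucose))
  cat(sprintf("  response: %s, baseline %g mV\n", x$response, x$baseline_voltage))
  cat(sprintf("  sensor noise SD: %g mV, meter CV: %g\n",
              x$sensor_noise_sd, x$meter_cv))
  invisible(x)
}

#' Noise-free sensor response curve
#'
#' Maps latent glucose concentration to the expected ultrasonic receiver
#' voltage under the configured response form. Strictly monotone in glucose;
#' the linear form passes through `baseline_voltage` at zero glucose.
#'
#' @param glucose Glucose concentration(s), mg/dl; must be non-negative.
#' @param config A [titration_config()].
#' @return Voltage(s), mV.
#' @export
sensor_response <- function(glucose, config) {
  stopifnot(inherits(config, "titration_config"))
  if (any(glucose < 0)) stop("glucose must be non-negative", call. = FALSE)
  switch(config$response,
    linear = config$baseline_voltage + config$slope * glucose,
    logistic = config$baseline_voltage + config$logistic_amplitude /
      (1 + exp(-(glucose - config$logistic_midpoint) / config$logistic_scale))
  )
}

#' Generate a synthetic titration series
#'
#' Produces one measurement record per batch. Batch `k` (zero-based) has
#' latent glucose `basal_glucose + glucose_start + k * glucose_step`;
#' the receiver voltage is the sensor response plus Gaussian noise; the
#' reference meter reads the latent glucose times `1 + N(0, meter_cv)`
#' (clamped at zero). Deterministic given `config$seed`.
#'
#' @param config A [titration_config()].
#' @return A data frame with columns `g_add` (added glucose, mg/dl), `v_u`
#'   (receiver voltage, mV), `cbgm` (reference meter glucose, mg/dl),
#'   `true_glucose` (latent glucose, mg/dl) and `state`
#'   (`"fasting"`, `"postmeal"` or `"unknown"`).
#' @export
generate_titration <- function(config) {
  stopifnot(inherits(config, "titration_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- seq_len(config$n_batches) - 1L
  g_add <- config$glucose_start + k * config$glucose_step
  true_glucose <- config$basal_glucose + g_add
  v_u <- sensor_response(true_glucose, config) +
    stats::rnorm(length(k), 0, config$sensor_noise_sd)
  cbgm <- pmax(true_glucose * (1 + stats::rnorm(length(k), 0, config$meter_cv)), 0)
  data.frame(g_add = g_add, v_u = v_u, cbgm = cbgm,
             true_glucose = true_glucose,
             state = rep("unknown", length(k)),
             stringsAsFactors = FALSE)
}

# glycemic class intervals keyed by meal state; closed on the right, so a
# fasting value of exactly 125 mg/dl is prediabetes, 125.1 diabetes
glycemic_intervals <- function() {
  data.frame(
    state = rep(c("fasting", "postmeal"), each = 3L),
    class = rep(c("normal", "prediabetes", "diabetes"), 2L),
    lower = c(70, 100, 125, 70, 140, 200),
    upper = c(100, 125, Inf, 140, 200, Inf),
    stringsAsFactors = FALSE
  )
}

#' Generate a classified cohort of measurements
#'
#' Draws measurement records stratified by meal state and glycemic class,
#' emulating a cohort summarised by per-class counts. Latent glucose is
#' uniform within each class interval (diabetes-class draws are capped at
#' `cap` mg/dl, the device's sensing range); voltages and reference
#' readings follow the same noise model as [generate_titration()].
#'
#' @param counts Data frame with columns `state` (`"fasting"`/`"postmeal"`),
#'   `class` (`"normal"`/`"prediabetes"`/`"diabetes"`) and `n` (counts
#'   >= 0). Defaults to the six-stratum design of the reference experiment
#'   (17/16/95 fasting, 39/14/71 post-meal).
#' @param config A [titration_config()]; supplies the response and noise
#'   model plus the seed.
#' @param cap Upper draw limit for the open-ended diabetes classes, mg/dl.
#' @return A data frame as in [generate_titration()], with `state` set.
#' @export
generate_cohort <- function(counts = cohort_counts(), config = titration_config(),
                            cap = 450) {
  stopifnot(inherits(config, "titration_config"))
  need <- c("state", "class", "n")
  if (!all(need %in% names(counts))) {
    stop("'counts' needs columns state, class, n", call. = FALSE)
  }
  if (any(counts$n < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts$n) == 0) stop("cohort is empty: all counts are zero", call. = FALSE)
  iv <- glycemic_intervals()
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    n <- counts$n[i]
    if (n == 0) next
    row <- iv[iv$state == counts$state[i] & iv$class == counts$class[i], ]
    if (nrow(row) != 1L) {
      stop(sprintf("unknown stratum: %s/%s", counts$state[i], counts$class[i]),
           call. = FALSE)
    }
    hi <- min(row$upper, cap)
    if (hi <= row$lower) stop("'cap' below the class interval", call. = FALSE)
    true_glucose <- stats::runif(n, row$lower, hi)
    v_u <- sensor_response(true_glucose, config) +
      stats::rnorm(n, 0, config$sensor_noise_sd)
    cbgm <- pmax(true_glucose * (1 + stats::rnorm(n, 0, config$meter_cv)), 0)
    out[[i]] <- data.frame(
      g_add = pmax(true_glucose - config$basal_glucose, 0),
      v_u = v_u, cbgm = cbgm, true_glucose = true_glucose,
      state = rep(counts$state[i], n), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Six-stratum cohort design of the reference experiment
#'
#' @return Data frame with columns `state`, `class`, `n`.
#' @export
cohort_counts <- function() {
  data.frame(
    state = rep(c("fasting", "postmeal"), each = 3L),
    class = rep(c("normal", "prediabetes", "diabetes"), 2L),
    n = c(17L, 16L, 95L, 39L, 14L, 71L),
    stringsAsFactors = FALSE
  )
}

#' Read and write measurement tables
#'
#' Measurements are persisted as comma-separated UTF-8 text with a header
#' row and dot decimals: columns `g_add`, `v_u`, `cbgm`, and optionally
#' `true_glucose` and `state`. On read, a missing `state` column is filled
#' with `"unknown"`; unknown extra columns are ignored with a message;
#' missing required columns or non-numeric entries are errors naming the
#' offending rows.
#'
#' @param measurements Data frame as produced by [generate_titration()].
#' @param path File path.
#' @return `write_measurements()` returns `path` invisibly;
#'   `read_measurements()` returns the measurement data frame.
#' @export
write_measurements <- function(measurements, path) {
  need <- c("g_add", "v_u", "cbgm")
  if (!all(need %in% names(measurements))) {
    stop("measurements need columns g_add, v_u, cbgm", call. = FALSE)
  }
  keep <- intersect(c("g_add", "v_u", "cbgm", "true_glucose", "state"),
                    names(measurements))
  utils::write.csv(measurements[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("g_add", "v_u", "cbgm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("measurement file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  known <- c("g_add", "v_u", "cbgm", "true_glucose", "state")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    message("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  numeric_cols <- intersect(c("g_add", "v_u", "cbgm", "true_glucose"), names(raw))
  for (cl in numeric_cols) {
    vals <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(vals) & !is.na(raw[[cl]]))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' at data row(s) %s in %s",
                   cl, paste(utils::head(bad, 5L), collapse = ", "), path),
           call. = FALSE)
    }
    if (anyNA(vals)) {
      stop(sprintf("missing '%s' at data row(s) %s in %s",
                   cl, paste(utils::head(which(is.na(vals)), 5L), collapse = ", "),
                   path), call. = FALSE)
    }
    raw[[cl]] <- vals
  }
  if (!"state" %in% names(raw)) raw$state <- "unknown"
  raw[intersect(known, names(raw))]
}
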