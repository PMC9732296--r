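#' Normalized correlation coefficient of two series
#'
#' Zero-lag normalized cross-correlation,
#' `sum(x * y) / sqrt(sum(x^2) * sum(y^2))`. On strictly positive,
#' non-mean-centred glucose series this is the similarity index that sits
#' near 1 for well-agreeing meters; the mean-centred Pearson coefficient
#' is available via `method = "pearson"`.
#'
#' @param x,y Numeric series of equal length >= 2.
#' @param method `"ncc"` (default) or `"pearson"`.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' ncc(c(3, 4), c(4, 3))  # 24/25
ncc <- function(x, y, method = c("ncc", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 paired values", call. = FALSE)
  if (method == "pearson") return(stats::cor(x, y))
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) stop("zero-norm input series", call. = FALSE)
  sum(x * y) / sqrt(nx * ny)
}

#' Relative-difference statistics between device and reference
#'
#' Per-pair relative differences are `d_i = 100 (pred_i - ref_i) / ref_i`
#' (percent). Bias is their mean, MARD the mean of their absolute values,
#' and the spread the sample standard deviation (n - 1 denominator).
#' `MARD >= |bias|` always.
#'
#' @param ref Reference glucose, mg/dl; strictly positive.
#' @param pred Device glucose, mg/dl.
#' @return List with `bias_pct`, `mard_pct`, `sd_rel_pct` and the
#'   per-pair differences `rel_diff_pct`.
#' @export
relative_difference_stats <- function(ref, pred) {
  if (length(ref) != length(pred)) stop("series lengths differ", call. = FALSE)
  if (any(ref <= 0)) stop("reference values must be positive", call. = FALSE)
  d <- 100 * (pred - ref) / ref
  list(bias_pct = mean(d), mard_pct = mean(abs(d)),
       sd_rel_pct = stats::sd(d), rel_diff_pct = d)
}

#' Modified Bland-Altman (Tukey mean-difference) analysis
#'
#' Plots device minus reference against their average; the limits of
#' agreement are the mean difference plus/minus 1.96 sample SDs.
#'
#' @param ref,pred Paired series of equal length >= 2, mg/dl.
#' @return Object of class `"bland_altman"`: data frame `points`
#'   (`average`, `difference`), `bias` (mean difference), `sd_diff`, and
#'   `limits` (lower, upper).
#' @export
bland_altman <- function(ref, pred) {
  if (length(ref) != length(pred)) stop("series lengths differ", call. = FALSE)
  if (length(ref) < 2L) stop("need at least 2 paired values", call. = FALSE)
  d <- pred - ref
  m <- (ref + pred) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    points = data.frame(average = m, difference = d),
    bias = bias, sd_diff = s,
    limits = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Modified Bland-Altman analysis\n")
  cat(sprintf("  n = %d pairs\n", nrow(x$points)))
  cat(sprintf("  mean difference (device - reference): %.3f mg/dl\n", x$bias))
  cat(sprintf("  limits of agreement: [%.3f, %.3f] mg/dl\n",
              x$limits[1], x$limits[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$points$average, x$points$difference,
                 xlab = "average of meters (mg/dl)",
                 ylab = "device - reference (mg/dl)",
                 main = "Modified Bland-Altman", ...)
  graphics::abline(h = x$bias, col = "blue")
  graphics::abline(h = x$limits, col = "red3", lty = 2)
  invisible(x)
}

#' Glycemic classification of a glucose value
#'
#' Classifies by the measured level and meal state. Fasting: 70-100
#' normal, (100, 125] prediabetes, above 125 diabetes. Post-meal: 70-140
#' normal, (140, 200] prediabetes, above 200 diabetes. Intervals are
#' closed on the right, so a fasting 125 mg/dl is prediabetes. Values
#' below 70 mg/dl fall outside the classification bands and are flagged
#' `hypo`.
#'
#' @param value Glucose, mg/dl (> 0).
#' @param state `"fasting"` or `"postmeal"` (recycled).
#' @return Factor with levels `hypo`, `normal`, `prediabetes`, `diabetes`.
#' @export
classify_glucose <- function(value, state) {
  if (any(value <= 0)) stop("glucose must be positive", call. = FALSE)
  n <- max(length(value), length(state))
  value <- rep_len(value, n); state <- rep_len(as.character(state), n)
  bad <- !state %in% c("fasting", "postmeal")
  if (any(bad)) {
    stop("unknown meal state: ", paste(unique(state[bad]), collapse = ", "),
         call. = FALSE)
  }
  cls <- character(n)
  for (s in c("fasting", "postmeal")) {
    idx <- state == s
    if (!any(idx)) next
    br <- if (s == "fasting") c(0, 70, 100, 125, Inf) else c(0, 70, 140, 200, Inf)
    # (0,70) hypo, then right-closed bands
    cls[idx] <- as.character(cut(value[idx], breaks = br,
                                 labels = c("hypo", "normal", "prediabetes",
                                            "diabetes"),
                                 right = TRUE, include.lowest = FALSE))
    cls[idx & value == 70] <- "normal"  # 70 opens the normal band
  }
  factor(cls, levels = c("hypo", "normal", "prediabetes", "diabetes"))
}

#' Per-class summary of paired meter readings
#'
#' Groups paired readings by meal state and the glycemic class of the
#' *reference* reading, and reports per stratum the count, mean and SD of
#' each meter, and the within-stratum normalized correlation.
#'
#' @param ref,pred Paired readings, mg/dl.
#' @param state Meal state per pair (`"fasting"`/`"postmeal"`).
#' @return Data frame with one row per state/class stratum: `state`,
#'   `class`, `n`, `ref_mean`, `ref_sd`, `pred_mean`, `pred_sd`, `ncc`.
#'   Strata with no members have `n = 0` and `NA` statistics; `hypo`
#'   strata appear only when populated.
#' @export
classification_summary <- function(ref, pred, state) {
  n <- length(ref)
  if (length(pred) != n || length(state) != n) {
    stop("ref, pred and state lengths differ", call. = FALSE)
  }
  cls <- classify_glucose(ref, state)
  design <- expand.grid(class = c("normal", "prediabetes", "diabetes"),
                        state = c("fasting", "postmeal"),
                        stringsAsFactors = FALSE)[, c("state", "class")]
  if (any(cls == "hypo")) {
    design <- rbind(design,
                    expand.grid(state = unique(as.character(state[cls == "hypo"])),
                                class = "hypo", stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(design)), function(i) {
    idx <- as.character(state) == design$state[i] &
      as.character(cls) == design$class[i]
    k <- sum(idx)
    data.frame(
      state = design$state[i], class = design$class[i], n = k,
      ref_mean = if (k) mean(ref[idx]) else NA_real_,
      ref_sd = if (k > 1) stats::sd(ref[idx]) else if (k == 1) 0 else NA_real_,
      pred_mean = if (k) mean(pred[idx]) else NA_real_,
      pred_sd = if (k > 1) stats::sd(pred[idx]) else if (k == 1) 0 else NA_real_,
      ncc = if (k > 1) ncc(ref[idx], pred[idx]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test for a mean difference between the two meters
#'
#' Two-sided Welch two-sample t-test by default (the location comparison
#' behind a "no statistically significant difference, p > 0.05" claim);
#' Mann-Whitney available. Two degenerate zero-variance series with equal
#' means give p = 1.
#'
#' @param ref,pred Series of length >= 3.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return The two-sided p-value.
#' @export
mean_difference_test <- function(ref, pred, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(ref) < 3L || length(pred) < 3L) {
    stop("need at least 3 values per series", call. = FALSE)
  }
  if (stats::sd(ref) == 0 && stats::sd(pred) == 0) {
    return(if (mean(ref) == mean(pred)) 1 else 0)
  }
  if (method == "welch") {
    stats::t.test(ref, pred)$p.value
  } else {
    stats::wilcox.test(ref, pred, exact = FALSE)$p.value
  }
}

#' Full agreement report between reference and device series
#'
#' Bundles every agreement statistic of the evaluation protocol:
#' normalized correlation, relative-difference statistics (bias, MARD,
#' SD), modified Bland-Altman limits, the Welch location test, and — when
#' meal states are supplied — the per-class summary table.
#'
#' @param ref,pred Paired series, mg/dl (`ref > 0`).
#' @param state Optional meal state per pair for the classification table.
#' @return Object of class `"agreement_report"` with components `n`,
#'   `ncc`, `bias_pct`, `mard_pct`, `sd_rel_pct`, `bland_altman`,
#'   `p_value`, and `per_class` (or `NULL`).
#' @export
agreement_report <- function(ref, pred, state = NULL) {
  rd <- relative_difference_stats(ref, pred)
  structure(list(
    n = length(ref),
    ncc = ncc(ref, pred),
    bias_pct = rd$bias_pct,
    mard_pct = rd$mard_pct,
    sd_rel_pct = rd$sd_rel_pct,
    bland_altman = bland_altman(ref, pred),
    p_value = mean_difference_test(ref, pred),
    per_class = if (is.null(state)) NULL else
      classification_summary(ref, pred, state)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 4, ...) {
  cat("Meter agreement report\n")
  cat(sprintf("  n pairs:        %d\n", x$n))
  cat(sprintf("  NCC:            %.*f\n", digits, x$ncc))
  cat(sprintf("  bias:           %.*f %%\n", digits, x$bias_pct))
  cat(sprintf("  MARD:           %.*f %%\n", digits, x$mard_pct))
  cat(sprintf("  SD(rel diff):   %.*f %%\n", digits, x$sd_rel_pct))
  cat(sprintf("  BA limits:      [%.3f, %.3f] mg/dl\n",
              x$bland_altman$limits[1], x$bland_altman$limits[2]))
  cat(sprintf("  Welch p-value:  %.4g\n", x$p_value))
  if (!is.null(x$per_class)) {
    cat("  Per-class summary (classes keyed on the reference meter):\n")
    print(x$per_class, row.names = FALSE, digits = digits)
  }
  invisible(x)
}
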