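#' Clarke error grid zone assignment
#'
#' Assigns each (reference, device) glucose pair to one of the five Clarke
#' zones: A clinically correct, B uncritical, C overcorrection, D missed
#' correction ("clinically dangerous failure to detect"), E wrong
#' correction. The canonical 1987 operationalization is used, applied in
#' the order A, E, C, D, else B, so every pair receives exactly one zone:
#' \itemize{
#'   \item A: `ref <= 70 & pred <= 70`, or `|pred - ref| <= 0.2 ref`
#'   \item E: `ref <= 70 & pred >= 180`, or `ref >= 180 & pred <= 70`
#'   \item C: `70 <= ref <= 290 & pred >= ref + 110`, or
#'     `130 <= ref <= 180 & pred <= (7/5) ref - 182`
#'   \item D: `ref >= 240 & 70 <= pred <= 180`, or
#'     `ref <= 175/3 & 70 <= pred <= 180`, or
#'     `175/3 <= ref <= 70 & pred >= (6/5) ref`
#'   \item B: everything else
#' }
#' Minor boundary dialects of this grid exist in the literature; this is
#' the most widely used one. The first axis is always the reference
#' (comparator) meter, the second the device under evaluation.
#'
#' @param ref Reference glucose, mg/dl (> 0).
#' @param pred Device glucose, mg/dl (>= 0).
#' @return Factor with levels `A`-`E`, one element per pair.
#' @export
#' @examples
#' clarke_zone(120, 123)  # the worked coordinate: zone A
clarke_zone <- function(ref, pred) {
  if (any(ref <= 0)) stop("reference glucose must be positive", call. = FALSE)
  if (any(pred < 0)) stop("device glucose must be non-negative", call. = FALSE)
  n <- max(length(ref), length(pred))
  ref <- rep_len(ref, n); pred <- rep_len(pred, n)
  zone <- rep("B", n)
  d <- rep(FALSE, n)
  d <- (ref >= 240 & pred >= 70 & pred <= 180) |
       (ref <= 175 / 3 & pred >= 70 & pred <= 180) |
       (ref >= 175 / 3 & ref <= 70 & pred >= (6 / 5) * ref)
  zone[d] <- "D"
  cc <- (ref >= 70 & ref <= 290 & pred >= ref + 110) |
        (ref >= 130 & ref <= 180 & pred <= (7 / 5) * ref - 182)
  zone[cc] <- "C"
  e <- (ref <= 70 & pred >= 180) | (ref >= 180 & pred <= 70)
  zone[e] <- "E"
  a <- (ref <= 70 & pred <= 70) | (abs(pred - ref) <= 0.2 * ref)
  zone[a] <- "A"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Parkes (consensus) error grid boundary polylines
#'
#' Vertex tables of the consensus error grid, separately for type 1 and
#' type 2 diabetes, as polylines in the (reference, device) plane over
#' 0-550 mg/dl. Each boundary is the limit between a zone and the
#' next-lower-risk zone on the same side of the identity line; under this
#' package's contract the type 2 grid carries zones A-D only (its most
#' extreme upper region is reported as D).
#'
#' @param type `"type1"` or `"type2"`.
#' @return Named list of boundaries; each element has `x` (reference) and
#'   `y` (device) vertex vectors. Upper boundaries are named `B_upper`,
#'   `C_upper`, `D_upper` (and `E_upper` for type 1); lower boundaries
#'   `B_lower`, `C_lower`, `D_lower`.
#' @export
parkes_boundaries <- function(type = c("type2", "type1")) {
  type <- match.arg(type)
  if (type == "type1") {
    list(
      B_upper = list(x = c(0, 30, 140, 280, 430), y = c(50, 50, 170, 380, 550)),
      C_upper = list(x = c(0, 30, 50, 70, 260), y = c(60, 60, 80, 110, 550)),
      D_upper = list(x = c(0, 25, 50, 80, 125), y = c(100, 100, 125, 215, 550)),
      E_upper = list(x = c(0, 35, 50), y = c(150, 155, 550)),
      B_lower = list(x = c(50, 50, 170, 385, 550), y = c(0, 30, 145, 300, 450)),
      C_lower = list(x = c(120, 120, 260, 550), y = c(0, 30, 130, 250)),
      D_lower = list(x = c(250, 250, 550), y = c(0, 40, 150))
    )
  } else {
    list(
      B_upper = list(x = c(0, 30, 230, 440), y = c(50, 50, 330, 550)),
      C_upper = list(x = c(0, 30, 280), y = c(60, 60, 550)),
      D_upper = list(x = c(0, 25, 35, 125), y = c(80, 80, 90, 550)),
      B_lower = list(x = c(50, 50, 90, 330, 550), y = c(0, 30, 80, 230, 450)),
      C_lower = list(x = c(90, 260, 550), y = c(0, 130, 250)),
      D_lower = list(x = c(250, 250, 410, 550), y = c(0, 40, 110, 160))
    )
  }
}

# boundary height at x: vertical segments collapse to their later vertex,
# flat extension beyond the last vertex (upper regions end at the grid top)
polyline_y <- function(b, x) {
  keep <- !duplicated(b$x, fromLast = TRUE)
  stats::approx(b$x[keep], b$y[keep], x, rule = 2)$y
}

#' Parkes (consensus) error grid zone assignment
#'
#' Assigns (reference, device) pairs to consensus-grid zones by comparing
#' the device reading against the embedded boundary polylines
#' ([parkes_boundaries()]) at the reference value. Points on a boundary
#' are assigned to the lower-risk zone. The grid domain is 0-550 mg/dl;
#' values above 550 are clipped with a warning. Per this package's
#' contract the type 2 grid returns zones A-D only.
#'
#' @param ref Reference glucose, mg/dl (>= 0).
#' @param pred Device glucose, mg/dl (>= 0).
#' @param type Diabetes type of the grid: `"type2"` (default) or
#'   `"type1"`.
#' @return Factor with levels `A`-`E`.
#' @export
parkes_zone <- function(ref, pred, type = c("type2", "type1")) {
  type <- match.arg(type)
  if (any(ref < 0) || any(pred < 0)) {
    stop("glucose values must be non-negative", call. = FALSE)
  }
  n <- max(length(ref), length(pred))
  ref <- rep_len(ref, n); pred <- rep_len(pred, n)
  if (any(ref > 550) || any(pred > 550)) {
    warning("values above 550 mg/dl clipped to the consensus grid domain",
            call. = FALSE)
    ref <- pmin(ref, 550); pred <- pmin(pred, 550)
  }
  b <- parkes_boundaries(type)
  zone <- rep("A", n)
  upper <- c("B_upper", "C_upper", "D_upper",
             if (type == "type1") "E_upper")
  lower <- c("B_lower", "C_lower", "D_lower")
  for (i in seq_along(upper)) {
    beyond <- pred > polyline_y(b[[upper[i]]], ref)
    zone[beyond] <- substr(upper[i], 1, 1)
  }
  for (i in seq_along(lower)) {
    bd <- b[[lower[i]]]
    beyond <- ref > min(bd$x) & pred < polyline_y(bd, ref)
    zone[beyond] <- substr(lower[i], 1, 1)
  }
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Surveillance error grid risk surfaces
#'
#' The surveillance error grid (SEG) scores each (reference, device) pair
#' with a continuous clinical-risk value on a 0-600 mg/dl lattice, binned
#' into colour-coded categories. The official surface is an empirically
#' derived clinician-survey lookup table; this package evaluates any
#' user-supplied lattice ([read_seg_grid()]) and ships a synthetic
#' *surrogate* surface for exercising the machinery:
#' `risk = 4 * min(1, |pred - ref| / max(ref, 30))`, zero on the identity
#' line and saturating at 4. Results on the surrogate surface exercise the
#' interpolation and binning code paths; they are not the official SEG
#' risk scores.
#'
#' @param step Lattice spacing in mg/dl.
#' @return An object of class `"seg_grid"`: lattice coordinates `ref` and
#'   `pred`, a risk matrix (rows = reference), and a `provenance` tag
#'   (`"surrogate"` or `"official"`).
#' @export
seg_surrogate_grid <- function(step = 5) {
  r <- seq(0, 600, by = step)
  p <- seq(0, 600, by = step)
  risk <- outer(r, p, function(ref, pred) {
    4 * pmin(1, abs(pred - ref) / pmax(ref, 30))
  })
  structure(list(ref = r, pred = p, risk = risk, provenance = "surrogate"),
            class = "seg_grid")
}

#' @export
print.seg_grid <- function(x, ...) {
  cat(sprintf("SEG risk lattice (%s): %d x %d nodes, ref 0-%g, pred 0-%g mg/dl\n",
              x$provenance, length(x$ref), length(x$pred),
              max(x$ref), max(x$pred)))
  invisible(x)
}

#' Read and write SEG risk lattices
#'
#' Lattice CSV format: a header row `ref,<pred_1>,...,<pred_k>` giving the
#' device-axis lattice values, then one row per reference lattice value
#' with the risk at each node.
#'
#' @param grid A `"seg_grid"` object.
#' @param path File path.
#' @param provenance Tag recorded on the grid read back (use
#'   `"official"` for the published surveillance surface).
#' @return `write_seg_grid()` returns `path` invisibly; `read_seg_grid()`
#'   a `"seg_grid"`.
#' @export
write_seg_grid <- function(grid, path) {
  stopifnot(inherits(grid, "seg_grid"))
  df <- data.frame(ref = grid$ref, grid$risk, check.names = FALSE)
  names(df) <- c("ref", grid$pred)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_seg_grid
#' @export
read_seg_grid <- function(path, provenance = "official") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "ref") stop("first lattice column must be 'ref'", call. = FALSE)
  pred <- as.numeric(names(df)[-1])
  if (anyNA(pred)) stop("device-axis header values must be numeric", call. = FALSE)
  risk <- as.matrix(df[, -1, drop = FALSE])
  if (any(risk < 0)) stop("risk values must be non-negative", call. = FALSE)
  structure(list(ref = df$ref, pred = pred, risk = unname(risk),
                 provenance = provenance),
            class = "seg_grid")
}

#' Surveillance error grid risk score
#'
#' Bilinear interpolation of the risk lattice at each (reference, device)
#' pair. Values outside the lattice are clamped to its edge with a
#' warning.
#'
#' @param ref,pred Glucose pair(s), mg/dl.
#' @param grid A `"seg_grid"`; the surrogate surface by default.
#' @return Numeric risk score(s).
#' @export
seg_risk <- function(ref, pred, grid = seg_surrogate_grid()) {
  stopifnot(inherits(grid, "seg_grid"))
  n <- max(length(ref), length(pred))
  ref <- rep_len(as.numeric(ref), n); pred <- rep_len(as.numeric(pred), n)
  rlim <- range(grid$ref); plim <- range(grid$pred)
  if (any(ref < rlim[1] | ref > rlim[2] | pred < plim[1] | pred > plim[2])) {
    warning("values outside the risk lattice clamped to its edge", call. = FALSE)
    ref <- pmin(pmax(ref, rlim[1]), rlim[2])
    pred <- pmin(pmax(pred, plim[1]), plim[2])
  }
  i <- pmin(findInterval(ref, grid$ref), length(grid$ref) - 1L)
  j <- pmin(findInterval(pred, grid$pred), length(grid$pred) - 1L)
  x0 <- grid$ref[i]; x1 <- grid$ref[i + 1L]
  y0 <- grid$pred[j]; y1 <- grid$pred[j + 1L]
  tx <- (ref - x0) / (x1 - x0)
  ty <- (pred - y0) / (y1 - y0)
  (1 - tx) * (1 - ty) * grid$risk[cbind(i, j)] +
    tx * (1 - ty) * grid$risk[cbind(i + 1L, j)] +
    (1 - tx) * ty * grid$risk[cbind(i, j + 1L)] +
    tx * ty * grid$risk[cbind(i + 1L, j + 1L)]
}

seg_category_levels <- c("none", "slight_lower", "slight_higher",
                         "moderate_lower", "moderate_higher",
                         "great_lower", "great_higher", "extreme")

#' Surveillance error grid risk category
#'
#' Bins a risk score into the standard SEG categories. The no-risk
#' ("green") bin is the closed interval `[0, 0.5]`; subsequent bins are
#' half-open on the left in steps of 0.5 up to `extreme` above 3.5.
#'
#' @param risk Non-negative risk score(s).
#' @return Factor with levels `none`, `slight_lower`, `slight_higher`,
#'   `moderate_lower`, `moderate_higher`, `great_lower`, `great_higher`,
#'   `extreme`.
#' @export
seg_category <- function(risk) {
  if (any(risk < 0)) stop("risk must be non-negative", call. = FALSE)
  cut(risk, breaks = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, Inf),
      labels = seg_category_levels, include.lowest = TRUE, right = TRUE)
}

#' Summarize error-grid zone occupancy
#'
#' Counts and percentages per zone (Clarke or Parkes) or per risk category
#' (SEG) over a set of paired readings.
#'
#' @param ref,pred Paired reference and device glucose, mg/dl.
#' @param grid One of `"clarke"`, `"parkes_t1"`, `"parkes_t2"`, `"seg"`.
#' @param seg_grid Risk lattice for `grid = "seg"`; surrogate by default.
#' @return An object of class `"zone_summary"`: a data frame with columns
#'   `zone`, `n`, `pct`, with attributes `grid`, `n_total`, and for SEG
#'   the lattice `provenance`.
#' @export
summarize_zones <- function(ref, pred,
                            grid = c("clarke", "parkes_t1", "parkes_t2", "seg"),
                            seg_grid = NULL) {
  grid <- match.arg(grid)
  if (length(ref) < 1L) stop("need at least one paired reading", call. = FALSE)
  if (length(ref) != length(pred)) stop("ref and pred lengths differ", call. = FALSE)
  provenance <- NULL
  zones <- switch(grid,
    clarke = clarke_zone(ref, pred),
    parkes_t1 = parkes_zone(ref, pred, "type1"),
    parkes_t2 = parkes_zone(ref, pred, "type2"),
    seg = {
      if (is.null(seg_grid)) seg_grid <- seg_surrogate_grid()
      provenance <- seg_grid$provenance
      seg_category(seg_risk(ref, pred, seg_grid))
    })
  tab <- table(zones)
  out <- data.frame(zone = names(tab), n = as.integer(tab),
                    pct = 100 * as.integer(tab) / length(zones),
                    stringsAsFactors = FALSE)
  structure(out, class = c("zone_summary", "data.frame"),
            grid = grid, n_total = length(zones), provenance = provenance)
}

#' @export
print.zone_summary <- function(x, ...) {
  cat(sprintf("Error grid summary: %s, n = %d\n",
              attr(x, "grid"), attr(x, "n_total")))
  if (!is.null(attr(x, "provenance"))) {
    cat(sprintf("  SEG risk surface: %s\n", attr(x, "provenance")))
  }
  df <- as.data.frame(x)
  df$pct <- sprintf("%.1f%%", df$pct)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Scatter plot of paired readings on an error grid
#'
#' @param ref,pred Paired readings, mg/dl.
#' @param grid `"clarke"`, `"parkes_t1"` or `"parkes_t2"`.
#' @param ... Passed to [graphics::plot()].
#' @return The zone factor, invisibly.
#' @export
plot_error_grid <- function(ref, pred, grid = c("clarke", "parkes_t1", "parkes_t2"),
                            ...) {
  grid <- match.arg(grid)
  zones <- switch(grid,
    clarke = clarke_zone(ref, pred),
    parkes_t1 = parkes_zone(ref, pred, "type1"),
    parkes_t2 = parkes_zone(ref, pred, "type2"))
  lim <- if (grid == "clarke") c(0, 400) else c(0, 550)
  cols <- c(A = "forestgreen", B = "olivedrab3", C = "gold",
            D = "darkorange", E = "red3")
  graphics::plot(ref, pred, col = cols[as.character(zones)], pch = 19,
                 xlim = lim, ylim = lim,
                 xlab = "reference glucose (mg/dl)",
                 ylab = "device glucose (mg/dl)",
                 main = paste(grid, "error grid"), ...)
  graphics::abline(0, 1, lty = 3)
  if (grid != "clarke") {
    b <- parkes_boundaries(if (grid == "parkes_t1") "type1" else "type2")
    for (bd in b) graphics::lines(bd$x, bd$y, col = "grey40")
  }
  graphics::legend("topleft", legend = levels(droplevels(zones)),
                   col = cols[levels(droplevels(zones))], pch = 19, bty = "n")
  invisible(zones)
}
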