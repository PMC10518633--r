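#' Phagocytosis index from cell counts
#'
#' The fraction of cells phagocytosing, as a percentage of total cells
#' per field (the MetaXpress-style readout).
#'
#' @param cells_phagocytosing,cells_total Non-negative counts;
#'   `cells_total` must be > 0.
#' @return Percentage (0..100).
#' @export
index_cell_fraction <- function(cells_phagocytosing, cells_total) {
  if (any(cells_total <= 0))
    stop("cells_total must be > 0", call. = FALSE)
  if (any(cells_phagocytosing < 0) || any(cells_phagocytosing > cells_total))
    stop("cells_phagocytosing must lie in [0, cells_total]", call. = FALSE)
  100 * cells_phagocytosing / cells_total
}

#' Phagocytosis index from pHrodo area
#'
#' pHrodo-red signal normalized to the well's phase confluency at time 0
#' (the IncuCyte-style readout).
#'
#' @param red_area Non-negative pHrodo-red area.
#' @param phase_confluency_t0 Starting confluency; must be > 0.
#' @return Index (arbitrary units).
#' @export
index_area <- function(red_area, phase_confluency_t0) {
  if (any(phase_confluency_t0 <= 0))
    stop("phase_confluency_t0 must be > 0", call. = FALSE)
  if (any(red_area < 0)) stop("red_area must be >= 0", call. = FALSE)
  red_area / phase_confluency_t0
}

#' Add the phagocytosis index to a measurement table
#'
#' Dispatches on the table's `mode` column: `cell_count` rows get
#' `index = 100 * cells_phagocytosing / cells_total`, `red_area` rows get
#' `index = red_area / phase_confluency_t0`.
#'
#' @param df Long measurement table as emitted by [generate_timeseries()].
#' @return `df` with an `index` column.
#' @export
phago_index <- function(df) {
  if (!"mode" %in% names(df)) stop("table needs a 'mode' column", call. = FALSE)
  idx <- numeric(nrow(df))
  cc <- df$mode == "cell_count"
  if (any(cc))
    idx[cc] <- index_cell_fraction(df$cells_phagocytosing[cc],
                                   df$cells_total[cc])
  if (any(!cc))
    idx[!cc] <- index_area(df$red_area[!cc], df$phase_confluency_t0[!cc])
  df$index <- idx
  df
}

#' Normalize curves to the within-experiment control at the last timepoint
#'
#' Within each replicate (the "within experiment" grouping), every
#' curve is divided by the mean control-condition index at the final
#' timepoint and expressed in percent, so the control condition's mean
#' final value maps to 100%.
#'
#' @param df Table with an `index` column (see [phago_index()]).
#' @param replicate_col,time_col Column names for the grouping and time.
#' @param is_control Logical vector marking control wells; by default
#'   rows with `disease == "control"` and, when a `treatment` column
#'   exists, `treatment == "none"`.
#' @return `df` with an `index_pct` column.
#' @export
normalize_to_final_control <- function(df, replicate_col = "replicate_id",
                                       time_col = "time_h",
                                       is_control = NULL) {
  if (!"index" %in% names(df))
    stop("run phago_index() first (no 'index' column)", call. = FALSE)
  if (is.null(is_control)) {
    is_control <- df$disease == "control"
    if ("treatment" %in% names(df))
      is_control <- is_control & df$treatment == "none"
  }
  df$index_pct <- NA_real_
  for (rep_id in unique(df[[replicate_col]])) {
    in_rep <- df[[replicate_col]] == rep_id
    t_final <- max(df[[time_col]][in_rep])
    ctrl <- in_rep & is_control & df[[time_col]] == t_final
    if (!any(ctrl))
      stop("replicate '", rep_id, "' has no control well at the final ",
           "timepoint", call. = FALSE)
    denom <- mean(df$index[ctrl])
    if (denom <= 0)
      stop("control final value is not positive in replicate '", rep_id,
           "'", call. = FALSE)
    df$index_pct[in_rep] <- 100 * df$index[in_rep] / denom
  }
  df
}

#' Area under an uptake curve
#'
#' Trapezoidal integral of an uptake curve over the hour axis. Interior
#' missing values are linearly interpolated; leading or trailing missing
#' values truncate the integration range (recorded in the
#' `"time_range"` attribute).
#'
#' @param time_h Strictly increasing times, hours.
#' @param value Curve values (e.g. `index_pct`).
#' @return AUC in value-units x hours, with attribute `time_range`.
#' @export
curve_auc <- function(time_h, value) {
  if (length(time_h) < 2L)
    stop("need at least 2 timepoints", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("time_h must be strictly increasing", call. = FALSE)
  ok <- !is.na(value)
  if (sum(ok) < 2L) stop("fewer than 2 non-missing values", call. = FALSE)
  lo <- which(ok)[1L]
  hi <- which(ok)[sum(ok)]
  t <- time_h[lo:hi]
  v <- value[lo:hi]
  if (anyNA(v)) v <- stats::approx(t[!is.na(v)], v[!is.na(v)], xout = t)$y
  auc <- sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  attr(auc, "time_range") <- c(t[1L], t[length(t)])
  auc
}

#' Per-well AUC table
#'
#' @param df Table with normalized curves (see
#'   [normalize_to_final_control()]).
#' @param value_col Which value to integrate (default `index_pct`).
#' @return One row per well: ids, condition columns, `auc`.
#' @export
auc_table <- function(df, value_col = "index_pct") {
  wells <- unique(df$well_id)
  rows <- lapply(wells, function(w) {
    d <- df[df$well_id == w, ]
    d <- d[order(d$time_h), ]
    keep <- intersect(c("well_id", "replicate_id", "condition", "disease",
                        "treatment", "mode"), names(d))
    out <- d[1L, keep, drop = FALSE]
    out$auc <- as.numeric(curve_auc(d$time_h, d[[value_col]]))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Degradation metrics around a wash
#'
#' For a degradation assay (uptake, wash, continued imaging): the peak
#' value over the pre-wash interval, the final value, and the fraction
#' of the peak remaining at the end.
#'
#' @param time_h,value One well's curve.
#' @param wash_time_h Wash time; must lie within the time range.
#' @return List `peak`, `final`, `fraction_remaining`.
#' @export
degradation_metrics <- function(time_h, value, wash_time_h) {
  if (wash_time_h < min(time_h) || wash_time_h > max(time_h))
    stop("wash_time_h outside the time range", call. = FALSE)
  pre <- time_h <= wash_time_h
  peak <- max(value[pre])
  if (peak <= 0) stop("no uptake before the wash (peak is 0)", call. = FALSE)
  final <- value[which.max(time_h)]
  list(peak = peak, final = final, fraction_remaining = final / peak)
}
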