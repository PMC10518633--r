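#' One condition of a phagocytosis kinetics design
#'
#' @param label Condition label (e.g. `"AD"`, `"control"`, `"AD+CytD"`).
#' @param plateau Asymptotic uptake level. In `cell_count` mode this is the
#'   asymptotic fraction of cells phagocytosing (0..1); in `red_area` mode
#'   an arbitrary-unit pHrodo plateau.
#' @param rate Logistic rate constant, per hour.
#' @param half_time_h Time of half-maximal uptake, hours.
#' @param disease Disease status of the synaptoneurosome donor
#'   (`"control"` or `"AD"`).
#' @param treatment One of `"none"`, `"CytD"`, `"antiMFGE8"`, `"IgG1"`,
#'   `"anti_a5b5"`, `"K777"`. Cytochalasin D abolishes phagocytosis, so
#'   `"CytD"` forces the plateau to 0.
#' @return One-row data frame.
#' @export
kinetics_condition <- function(label, plateau, rate, half_time_h,
                               disease = c("control", "AD"),
                               treatment = c("none", "CytD", "antiMFGE8",
                                             "IgG1", "anti_a5b5", "K777")) {
  disease <- match.arg(disease)
  treatment <- match.arg(treatment)
  if (plateau < 0) stop("plateau must be >= 0", call. = FALSE)
  if (treatment == "CytD") plateau <- 0
  data.frame(label = label, disease = disease, treatment = treatment,
             plateau = plateau, rate = rate, half_time_h = half_time_h)
}

#' Design of a simulated live-imaging phagocytosis assay
#'
#' Noiseless uptake follows a logistic in time,
#' `v(t) = plateau / (1 + exp(-rate * (t - half_time_h)))`.
#' After an optional wash at `wash_time_h`, the retained signal decays
#' exponentially at `decay_rate_post_wash` - except under cathepsin
#' blockade (`treatment = "K777"`), where degradation is prevented and
#' the signal holds. Well-level noise is multiplicative lognormal with
#' coefficient of variation `well_noise_cv` (0 gives the closed form
#' exactly).
#'
#' @param conditions Data frame of [kinetics_condition()] rows.
#' @param timepoints_h Strictly increasing imaging times, hours
#'   (e.g. every 10 min for 3 h for microglia, every 2 h for 48 h for
#'   astrocytes).
#' @param wells_per_condition Wells per condition per replicate.
#' @param n_replicates Independent culture replicates / donors; the
#'   grouping within which control normalization happens.
#' @param well_noise_cv Multiplicative noise CV per measurement.
#' @param mode `"cell_count"` (MetaXpress-style: cells phagocytosing /
#'   total cells) or `"red_area"` (IncuCyte-style: pHrodo area /
#'   starting confluency).
#' @param wash_time_h Optional wash time for degradation assays.
#' @param decay_rate_post_wash Exponential decay rate after wash, per
#'   hour.
#' @param cells_total Cells per field in `cell_count` mode (reported as
#'   the per-field average, so fractional values are kept).
#' @param confluency_mean Mean phase confluency at t = 0 in `red_area`
#'   mode.
#' @return Object of class `KineticsDesign`.
#' @export
kinetics_design <- function(conditions, timepoints_h,
                            wells_per_condition = 3L, n_replicates = 1L,
                            well_noise_cv = 0.05,
                            mode = c("cell_count", "red_area"),
                            wash_time_h = NULL,
                            decay_rate_post_wash = 0.1,
                            cells_total = 200,
                            confluency_mean = 40) {
  mode <- match.arg(mode)
  if (length(timepoints_h) == 0L)
    stop("timepoints_h must be non-empty", call. = FALSE)
  if (any(diff(timepoints_h) <= 0))
    stop("timepoints_h must be strictly increasing", call. = FALSE)
  conditions <- as.data.frame(conditions)
  if (any(conditions$plateau < 0))
    stop("plateau must be >= 0", call. = FALSE)
  conditions$plateau[conditions$treatment == "CytD"] <- 0
  if (!is.null(wash_time_h) &&
      (wash_time_h <= min(timepoints_h) || wash_time_h >= max(timepoints_h)))
    stop("wash_time_h must lie inside the time range", call. = FALSE)
  structure(list(conditions = conditions, timepoints_h = timepoints_h,
                 wells_per_condition = as.integer(wells_per_condition),
                 n_replicates = as.integer(n_replicates),
                 well_noise_cv = well_noise_cv, mode = mode,
                 wash_time_h = wash_time_h,
                 decay_rate_post_wash = decay_rate_post_wash,
                 cells_total = cells_total,
                 confluency_mean = confluency_mean),
            class = "KineticsDesign")
}

#' Noiseless uptake curve of a kinetics condition
#'
#' The logistic (and optional post-wash decay) closed form used by the
#' simulator; exported so analysis results can be checked against it.
#'
#' @param t Times, hours.
#' @param plateau,rate,half_time_h Logistic parameters.
#' @param wash_time_h,decay_rate Optional wash time and post-wash decay.
#' @return Numeric vector of uptake values.
#' @export
logistic_uptake <- function(t, plateau, rate, half_time_h,
                            wash_time_h = NULL, decay_rate = 0) {
  v <- plateau / (1 + exp(-rate * (t - half_time_h)))
  if (!is.null(wash_time_h)) {
    vw <- plateau / (1 + exp(-rate * (wash_time_h - half_time_h)))
    post <- t > wash_time_h
    v[post] <- vw * exp(-decay_rate * (t[post] - wash_time_h))
  }
  v
}

#' Simulate phagocytosis time series
#'
#' Emits one long-format measurement table with one row per well and
#' timepoint, matching what live-imaging instruments export: in
#' `cell_count` mode columns `cells_total` and `cells_phagocytosing`, in
#' `red_area` mode columns `red_area` and `phase_confluency_t0`.
#'
#' @param design A [kinetics_design()].
#' @param seed Integer seed; fully determines the table.
#' @return Data frame with columns `well_id`, `replicate_id`, `condition`,
#'   `disease`, `treatment`, `mode`, `time_h` plus the mode's measurement
#'   columns.
#' @export
generate_timeseries <- function(design, seed) {
  stopifnot(inherits(design, "KineticsDesign"))
  withr::with_seed(as.integer(seed), {
    sdlog <- if (design$well_noise_cv > 0)
      sqrt(log(1 + design$well_noise_cv^2)) else 0
    rows <- list()
    for (r in seq_len(design$n_replicates)) {
      for (ci in seq_len(nrow(design$conditions))) {
        cond <- design$conditions[ci, ]
        decay <- if (cond$treatment == "K777") 0 else design$decay_rate_post_wash
        for (w in seq_len(design$wells_per_condition)) {
          t <- design$timepoints_h
          v <- logistic_uptake(t, cond$plateau, cond$rate, cond$half_time_h,
                               design$wash_time_h, decay)
          if (sdlog > 0)
            v <- v * stats::rlnorm(length(v), -sdlog^2 / 2, sdlog)
          well <- sprintf("rep%d_%s_w%d", r, cond$label, w)
          df <- data.frame(well_id = well,
                           replicate_id = sprintf("rep%d", r),
                           condition = cond$label, disease = cond$disease,
                           treatment = cond$treatment, mode = design$mode,
                           time_h = t)
          if (design$mode == "cell_count") {
            df$cells_total <- design$cells_total
            df$cells_phagocytosing <- pmin(v, 1) * design$cells_total
          } else {
            conf <- design$confluency_mean *
              (if (sdlog > 0) stats::rlnorm(1, -sdlog^2 / 2, sdlog) else 1)
            df$phase_confluency_t0 <- conf
            df$red_area <- v * conf
          }
          rows[[length(rows) + 1L]] <- df
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Kinetics design presets
#'
#' * `"astro-ad-vs-control"`: IncuCyte-style astrocyte assay, imaging
#'   every 2 h for 48 h; AD synaptoneurosomes reach a 2x higher plateau,
#'   faster, than control; a CytD well row is the negative control.
#' * `"microglia-ad-vs-control"`: fast microglial assay, every 10 min
#'   for 3 h.
#' * `"degradation"`: 2 h uptake, wash, then 48 h of post-wash imaging;
#'   conditions with and without cathepsin blockade (K777).
#'
#' @param name Preset name.
#' @return A `KineticsDesign`.
#' @export
kinetics_preset <- function(name) {
  switch(
    name,
    "astro-ad-vs-control" = kinetics_design(
      rbind(kinetics_condition("control", 0.30, 0.18, 20, "control"),
            kinetics_condition("AD", 0.60, 0.26, 14, "AD"),
            kinetics_condition("AD+CytD", 0.60, 0.26, 14, "AD", "CytD")),
      timepoints_h = seq(0, 48, by = 2), wells_per_condition = 3L,
      n_replicates = 5L, well_noise_cv = 0.08, mode = "red_area"),
    "microglia-ad-vs-control" = kinetics_design(
      rbind(kinetics_condition("control", 0.35, 4.5, 0.8, "control"),
            kinetics_condition("AD", 0.70, 6.0, 0.6, "AD"),
            kinetics_condition("AD+CytD", 0.70, 6.0, 0.6, "AD", "CytD")),
      timepoints_h = seq(0, 3, by = 1 / 6), wells_per_condition = 3L,
      n_replicates = 8L, well_noise_cv = 0.08, mode = "cell_count"),
    "degradation" = kinetics_design(
      rbind(kinetics_condition("untreated", 0.5, 3.0, 1.0, "control"),
            kinetics_condition("K777", 0.5, 3.0, 1.0, "control", "K777")),
      timepoints_h = c(seq(0, 2, by = 0.25), seq(4, 50, by = 2)),
      wells_per_condition = 3L, n_replicates = 3L, well_noise_cv = 0.05,
      mode = "red_area", wash_time_h = 2, decay_rate_post_wash = 0.12),
    stop("unknown kinetics preset '", name, "'", call. = FALSE))
}
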