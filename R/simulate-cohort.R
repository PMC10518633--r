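#' Cohort design for simulated stacks
#'
#' A cohort is a set of groups (e.g. disease cohorts), each with
#' `n_cases_per_group` cases contributing `n_stacks_per_case` stacks.
#' Group effects are planted as multipliers on the engulfed fraction
#' and/or the glial volume fraction of the base stack parameters; on top
#' of the group effect every case draws one lognormal multiplier with
#' unit mean and coefficient of variation `case_cv`, shared by all of
#' that case's stacks (the between-case biological variability that the
#' random-intercept model later absorbs).
#'
#' @param groups Data frame with columns `name`, `engulf_mult`,
#'   `glia_mult` (multipliers > 0), one row per group.
#' @param n_cases_per_group,n_stacks_per_case Counts (>= 1).
#' @param case_cv Coefficient of variation of the per-case multiplier
#'   (>= 0; 0 disables case variability).
#' @param base A [stack_sim_params()] object.
#' @param preset_name Optional name recorded when built by
#'   [cohort_preset()].
#' @return An object of class `CohortDesign`.
#' @export
cohort_design <- function(groups, n_cases_per_group, n_stacks_per_case,
                          case_cv = 0.2, base = stack_sim_params(),
                          preset_name = NA_character_) {
  groups <- as.data.frame(groups)
  if (!all(c("name", "engulf_mult", "glia_mult") %in% names(groups)))
    stop("groups needs columns name, engulf_mult, glia_mult", call. = FALSE)
  if (any(groups$engulf_mult <= 0) || any(groups$glia_mult <= 0))
    stop("group multipliers must be > 0", call. = FALSE)
  if (n_cases_per_group < 1L || n_stacks_per_case < 1L)
    stop("counts must be >= 1", call. = FALSE)
  if (case_cv < 0) stop("case_cv must be >= 0", call. = FALSE)
  stopifnot(inherits(base, "StackSimParams"))
  structure(list(groups = groups,
                 n_cases_per_group = as.integer(n_cases_per_group),
                 n_stacks_per_case = as.integer(n_stacks_per_case),
                 case_cv = case_cv, base = base, preset_name = preset_name),
            class = "CohortDesign")
}

#' Named cohort presets encoding the planted effect sizes
#'
#' Ready-made [cohort_design()]s whose planted group effects match the
#' effect sizes the quantification pipeline is expected to recover:
#'
#' * `"fig1-astro-ad"` - astrocyte (filamentous, GFAP-like) engulfment,
#'   AD vs aged control, planted engulfed-volume ratio 2.1.
#' * `"fig1-astro-aging"` - aged control vs midlife control, planted
#'   ratio 2.7.
#' * `"fig2-cd68-burden"` - phago-lysosomal (blobby, CD68-like) stain
#'   burden, AD vs control, planted glial-volume ratio 1.9.
#' * `"fig3-astro-triple"` - one AD group with a neurite channel; the
#'   planted ratio of pairwise (syn-in-glia) to triple
#'   (syn+neurite-in-glia) volume is 10.
#' * `"fig3-microglia-triple"` - as above with planted pair:triple
#'   ratio 44 and a denser synaptic channel to stabilise the
#'   small-volume ratio.
#' * `"smoke"` - tiny two-group design for fast end-to-end checks.
#'
#' All full presets use 12 cases per group, 4 stacks per case,
#' 32 x 128 x 128 voxel stacks at the default voxel size, and a
#' between-case CV of 0.2.
#'
#' @param name Preset name.
#' @return A `CohortDesign`.
#' @export
cohort_preset <- function(name) {
  mk_groups <- function(nm, eng = c(1, 1), gli = c(1, 1))
    data.frame(name = nm, engulf_mult = eng, glia_mult = gli)
  d <- switch(
    name,
    "fig1-astro-ad" = cohort_design(
      mk_groups(c("aged_control", "AD"), eng = c(1, 2.1)),
      n_cases_per_group = 12L, n_stacks_per_case = 4L, case_cv = 0.2,
      base = stack_sim_params(glial_morphology = "filamentous",
                              engulfed_fraction = 0.10)),
    "fig1-astro-aging" = cohort_design(
      mk_groups(c("midlife_control", "aged_control"), eng = c(1, 2.7)),
      n_cases_per_group = 12L, n_stacks_per_case = 4L, case_cv = 0.2,
      base = stack_sim_params(glial_morphology = "filamentous",
                              engulfed_fraction = 0.10)),
    "fig2-cd68-burden" = cohort_design(
      mk_groups(c("control", "AD"), gli = c(1, 1.9)),
      n_cases_per_group = 12L, n_stacks_per_case = 4L, case_cv = 0.2,
      base = stack_sim_params(glial_morphology = "blobby",
                              glial_volume_fraction = 0.04,
                              punctum_density = 0,
                              amplitudes = c(glia = 400, syn = 4200,
                                             neurite = 130, plaque = 170))),
    "fig3-astro-triple" = cohort_design(
      data.frame(name = "AD", engulf_mult = 1, glia_mult = 1),
      n_cases_per_group = 12L, n_stacks_per_case = 4L, case_cv = 0.2,
      base = stack_sim_params(glial_morphology = "filamentous",
                              engulfed_fraction = 0.15,
                              neurite_density = 60,
                              neurite_engulfed_volume_ratio = 1 / 10)),
    "fig3-microglia-triple" = cohort_design(
      data.frame(name = "AD", engulf_mult = 1, glia_mult = 1),
      n_cases_per_group = 12L, n_stacks_per_case = 4L, case_cv = 0.2,
      base = stack_sim_params(glial_morphology = "filamentous",
                              engulfed_fraction = 0.15,
                              punctum_density = 1.5,
                              neurite_density = 60,
                              neurite_engulfed_volume_ratio = 1 / 44)),
    "smoke" = cohort_design(
      mk_groups(c("control", "AD"), eng = c(1, 2)),
      n_cases_per_group = 2L, n_stacks_per_case = 1L, case_cv = 0,
      base = stack_sim_params(shape_zyx = c(16L, 64L, 64L),
                              engulfed_fraction = 0.15,
                              punctum_density = 0.9)),
    stop("unknown preset name '", name, "'", call. = FALSE))
  d$preset_name <- name
  d
}

#' Generate a simulated cohort
#'
#' Draws the cohort layout deterministically from one seed: case metadata
#' (cohort label, region, APOE4 status, sex, age), one lognormal
#' multiplier per case, and one sub-seed per stack. Stacks themselves are
#' materialised lazily by [realize_stack()] so arbitrarily large cohorts
#' need constant memory.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; the same `(design, seed)` gives an identical
#'   cohort, metadata table included.
#' @return An object of class `GlialCohort` with `stacks` (one row per
#'   stack: ids, group, case multiplier, sub-seed) and `metadata` (one
#'   row per case).
#' @export
generate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "CohortDesign"))
  withr::with_seed(as.integer(seed), {
    g <- design$groups
    n_cases <- nrow(g) * design$n_cases_per_group
    case_id <- sprintf("%s_case%02d",
                       rep(g$name, each = design$n_cases_per_group),
                       rep(seq_len(design$n_cases_per_group), nrow(g)))
    sdlog <- sqrt(log(1 + design$case_cv^2))
    case_mult <- if (design$case_cv > 0)
      stats::rlnorm(n_cases, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    else rep(1, n_cases)
    metadata <- data.frame(
      case_id = case_id,
      cohort = rep(g$name, each = design$n_cases_per_group),
      region = "synthetic",
      apoe4 = stats::runif(n_cases) < 0.35,
      sex = sample(c("F", "M"), n_cases, replace = TRUE),
      age = round(stats::runif(n_cases, 62, 95)),
      plaque_present = design$base$plaque_count > 0L,
      case_mult = case_mult)

    n_stacks <- n_cases * design$n_stacks_per_case
    stacks <- data.frame(
      stack_id = sprintf("%s_s%d", rep(case_id, each = design$n_stacks_per_case),
                         rep(seq_len(design$n_stacks_per_case), n_cases)),
      case_id = rep(case_id, each = design$n_stacks_per_case),
      group = rep(metadata$cohort, each = design$n_stacks_per_case),
      case_mult = rep(case_mult, each = design$n_stacks_per_case),
      engulf_mult = rep(rep(g$engulf_mult, each = design$n_cases_per_group),
                        each = design$n_stacks_per_case),
      glia_mult = rep(rep(g$glia_mult, each = design$n_cases_per_group),
                      each = design$n_stacks_per_case),
      stack_seed = sample.int(2147483646L, n_stacks))
    structure(list(design = design, seed = as.integer(seed),
                   metadata = metadata, stacks = stacks),
              class = "GlialCohort")
  })
}

#' @export
print.GlialCohort <- function(x, ...) {
  cat(sprintf(
    "GlialCohort (%s, seed %d): %d groups x %d cases x %d stacks = %d stacks\n",
    ifelse(is.na(x$design$preset_name), "custom", x$design$preset_name),
    x$seed, nrow(x$design$groups), x$design$n_cases_per_group,
    x$design$n_stacks_per_case, nrow(x$stacks)))
  invisible(x)
}

#' Materialise one stack of a cohort
#'
#' Regenerates stack `i` of a [generate_cohort()] result from its stored
#' sub-seed, applying the group and case multipliers to the base
#' parameters (engulfed fraction and glial volume fraction, both capped
#' at 0.97).
#'
#' @param cohort A `GlialCohort`.
#' @param i Stack row index (or a `stack_id`).
#' @param render Passed to [generate_stack()]; `FALSE` gives ground truth
#'   only.
#' @return As [generate_stack()].
#' @export
realize_stack <- function(cohort, i, render = TRUE) {
  stopifnot(inherits(cohort, "GlialCohort"))
  if (is.character(i)) i <- match(i, cohort$stacks$stack_id)
  row <- cohort$stacks[i, ]
  p <- cohort$design$base
  p$engulfed_fraction <- min(0.97, p$engulfed_fraction * row$engulf_mult *
                               row$case_mult)
  p$glial_volume_fraction <- min(0.97, p$glial_volume_fraction *
                                   row$glia_mult * row$case_mult)
  generate_stack(p, seed = row$stack_seed, stack_id = row$stack_id,
                 case_id = row$case_id, render = render)
}

#' Ground-truth tally of a cohort
#'
#' Per-stack planted quantities, computed directly from the simulator's
#' ground truth (no segmentation): punctum counts, engulfed counts and
#' volumes, planted glial volume fraction. This is the oracle against
#' which pipeline recovery is judged.
#'
#' @param cohort A `GlialCohort`.
#' @return Data frame, one row per stack.
#' @export
cohort_truth_table <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort$stacks)), function(i) {
    tr <- realize_stack(cohort, i, render = FALSE)$truth
    p <- tr$puncta
    data.frame(stack_id = tr$stack_id, case_id = tr$case_id,
               group = cohort$stacks$group[i],
               n_puncta = nrow(p), n_engulfed = sum(p$engulfed),
               engulfed_volume_um3 = sum(p$volume_um3[p$engulfed]),
               glia_volume_frac = mean(tr$labels$glia > 0L))
  })
  do.call(rbind, rows)
}

default_cohort_presets <- function(design) {
  glia_preset <- if (design$base$glial_morphology == "blobby") "CD68" else "GFAP"
  pr <- list(glia = glia_preset)
  if (design$base$punctum_density > 0) pr$syn <- "Syn1"
  if (design$base$neurite_density > 0 ||
      design$base$neurite_engulfed_volume_ratio > 0) pr$neurite <- "MAP2"
  if (design$base$plaque_count > 0L) pr$plaque <- "plaque"
  pr
}

#' Segment and score every stack of a cohort
#'
#' Runs the full per-stack pipeline (simulate, segment with the marker
#' presets, colocalize, [compute_stack_metrics()]) over a cohort and
#' returns the per-stack metrics table with group and case columns.
#'
#' @param cohort A `GlialCohort`.
#' @param presets Channel presets, default chosen from the design
#'   (GFAP-settings for filamentous glia, CD68-settings for blobby).
#' @param params [coloc_params()].
#' @param progress Emit a progress message every few stacks.
#' @return Data frame, one row per stack.
#' @export
cohort_metrics <- function(cohort, presets = NULL,
                           params = coloc_params(), progress = FALSE) {
  stopifnot(inherits(cohort, "GlialCohort"))
  design <- cohort$design
  if (is.null(presets)) presets <- default_cohort_presets(design)
  has_syn <- "syn" %in% names(presets)
  has_neurite <- "neurite" %in% names(presets)
  has_plaque <- "plaque" %in% names(presets)
  n <- nrow(cohort$stacks)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- realize_stack(cohort, i)$stack
    segs <- segment_stack(st, presets)
    if (has_syn) {
      rows[[i]] <- compute_stack_metrics(
        st, segs, pair = c("syn", "glia"),
        triple_channel = if (has_neurite) "neurite",
        plaque_channel = if (has_plaque) "plaque", params = params)
    } else {
      # burden-only readout (no synaptic channel simulated)
      vox <- prod(dim(st))
      rows[[i]] <- data.frame(
        stack_id = st$stack_id, case_id = st$case_id,
        stack_volume_um3 = vox * voxel_volume_um3(st$voxel_size_zyx),
        burden_frac_glia = sum(segs$glia$objects$voxel_count) / vox)
    }
    rows[[i]]$group <- cohort$stacks$group[i]
    if (progress && i %% 8L == 0L)
      message(sprintf("  stack %d/%d", i, n))
  }
  do.call(rbind, rows)
}

#' Recover the planted effect of a cohort preset
#'
#' Generates a [cohort_preset()] cohort, runs the full
#' segmentation-and-colocalization pipeline on every stack, and computes
#' the preset's headline quantity exactly as a cohort would be scored:
#'
#' * engulfment presets (`fig1-*`): ratio of group means of case-level
#'   mean object-rule colocalized volume (second group over first);
#' * burden preset (`fig2-cd68-burden`): ratio of group means of
#'   case-level mean stained volume fraction;
#' * triple presets (`fig3-*`): ratio of the mean pairwise (syn & glia)
#'   to mean triple (syn & neurite & glia) intersection volume.
#'
#' @param name Preset name.
#' @param seed Integer seed for the whole cohort.
#' @param progress Progress messages.
#' @return List with `value` (the recovered ratio), `n` (number of
#'   stacks), and `metrics` (the per-stack table).
#' @export
recover_preset_ratio <- function(name, seed = 1L, progress = FALSE) {
  cohort <- generate_cohort(cohort_preset(name), seed)
  met <- cohort_metrics(cohort, progress = progress)
  case_mean <- function(col) {
    cm <- stats::aggregate(met[[col]],
                           by = list(case_id = met$case_id,
                                     group = met$group), FUN = mean)
    names(cm)[3] <- "value"
    cm
  }
  groups <- cohort$design$groups$name
  value <- if (name %in% c("fig1-astro-ad", "fig1-astro-aging")) {
    cm <- case_mean("coloc_volume_um3")
    mean(cm$value[cm$group == groups[2]]) /
      mean(cm$value[cm$group == groups[1]])
  } else if (name == "fig2-cd68-burden") {
    cm <- case_mean("burden_frac_glia")
    mean(cm$value[cm$group == groups[2]]) /
      mean(cm$value[cm$group == groups[1]])
  } else if (name %in% c("fig3-astro-triple", "fig3-microglia-triple")) {
    cm_pair <- case_mean("and_volume_um3")
    cm_tri <- case_mean("triple_volume_um3")
    mean(cm_pair$value) / mean(cm_tri$value)
  } else {
    stop("no recovery rule for preset '", name, "'", call. = FALSE)
  }
  list(value = value, n = nrow(cohort$stacks), metrics = met)
}
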