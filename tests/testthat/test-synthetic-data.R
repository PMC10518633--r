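test_that("one seed fully determines stacks and ground truth", {
  p <- tiny_sim_params(punctum_density = 0.9)
  a <- generate_stack(p, seed = 7)
  b <- generate_stack(p, seed = 7)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$puncta, b$truth$puncta)
  expect_identical(a$truth$labels, b$truth$labels)
  c <- generate_stack(p, seed = 8)
  expect_false(identical(a$stack$channels$syn, c$stack$channels$syn))
})

test_that("zero punctum density leaves a noise-only synaptic channel", {
  g <- generate_stack(tiny_sim_params(punctum_density = 0), seed = 3)
  expect_equal(nrow(g$truth$puncta), 0L)
  expect_true("syn" %in% names(g$stack$channels))
  # nothing but (sub-quantization) noise in the channel
  expect_lt(mean(g$stack$channels$syn), 0.5)
})

test_that("engulfed tally follows the planted binomial fraction", {
  # ~500 expected puncta at engulfed_fraction 0.3
  p <- stack_sim_params(punctum_density = 500 / 5096, engulfed_fraction = 0.3)
  tr <- generate_stack(p, seed = 7, render = FALSE)$truth
  n_eng <- sum(tr$puncta$engulfed)
  expect_lt(abs(n_eng - 150), 3 * sqrt(500 * 0.3 * 0.7))
  # conservation: every punctum is either engulfed or not
  expect_equal(sum(tr$puncta$engulfed) + sum(!tr$puncta$engulfed),
               nrow(tr$puncta))
  # engulfed centroids lie inside a glial ground-truth object
  eng <- tr$puncta[tr$puncta$engulfed, ]
  expect_true(all(!is.na(eng$host_glia_id) & eng$host_glia_id > 0))
})

test_that("increasing engulfed_fraction does not decrease engulfed volume", {
  vols <- vapply(c(0.05, 0.15, 0.3), function(f) {
    tr <- generate_stack(tiny_sim_params(engulfed_fraction = f),
                         seed = 11, render = FALSE)$truth
    sum(tr$puncta$volume_um3[tr$puncta$engulfed])
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("label volumes share the stack shape and punctum table matches", {
  g <- generate_stack(tiny_sim_params(neurite_density = 10,
                                      neurite_engulfed_volume_ratio = 0.1,
                                      plaque_count = 2L), seed = 5)
  for (lab in g$truth$labels)
    expect_identical(dim(lab), dim(g$stack$channels[[1L]]))
  expect_setequal(names(g$stack$channels),
                  c("glia", "syn", "neurite", "plaque"))
})

test_that("cohort layout, determinism and planted group ratio", {
  design <- cohort_design(
    data.frame(name = c("a", "b"), engulf_mult = c(1, 2), glia_mult = 1),
    n_cases_per_group = 3L, n_stacks_per_case = 2L, case_cv = 0,
    base = tiny_sim_params())
  co <- generate_cohort(design, 5)
  expect_equal(nrow(co$stacks), 12L)
  expect_equal(length(unique(co$stacks$case_id)), 6L)
  expect_identical(co$metadata, generate_cohort(design, 5)$metadata)

  # planted ratio recovered from the emitted ground truth alone
  design2 <- cohort_design(
    data.frame(name = c("a", "b"), engulf_mult = c(1, 2), glia_mult = 1),
    n_cases_per_group = 3L, n_stacks_per_case = 4L, case_cv = 0,
    base = stack_sim_params(shape_zyx = c(16L, 64L, 64L),
                            engulfed_fraction = 0.2))
  tt <- cohort_truth_table(generate_cohort(design2, 5))
  agg <- tapply(tt$engulfed_volume_um3, tt$group, mean)
  expect_lt(abs(agg[["b"]] / agg[["a"]] - 2), 0.1)
})

test_that("unknown cohort preset is rejected, known presets build", {
  expect_error(cohort_preset("no-such-preset"), "unknown preset")
  for (nm in c("fig1-astro-ad", "fig1-astro-aging", "fig2-cd68-burden",
               "fig3-astro-triple", "fig3-microglia-triple", "smoke"))
    expect_s3_class(cohort_preset(nm), "CohortDesign")
})

test_that("kinetics: CytD is flat, noiseless wells follow the closed form", {
  des <- kinetics_design(
    rbind(kinetics_condition("ctrl", 0.4, 0.3, 10, "control"),
          kinetics_condition("AD", 0.8, 0.3, 10, "AD"),
          kinetics_condition("cytd", 0.8, 0.3, 10, "AD", "CytD")),
    timepoints_h = seq(0, 48, by = 4), wells_per_condition = 2L,
    well_noise_cv = 0, mode = "cell_count")
  ts <- generate_timeseries(des, 9)
  cytd <- ts[ts$treatment == "CytD", ]
  expect_true(all(cytd$cells_phagocytosing == 0))

  ctrl <- ts[ts$condition == "ctrl" & ts$well_id == "rep1_ctrl_w1", ]
  expect_equal(ctrl$cells_phagocytosing / ctrl$cells_total,
               logistic_uptake(ctrl$time_h, 0.4, 0.3, 10))

  # planted 2x plateau shows up exactly at the final timepoint
  fin <- ts[ts$time_h == 48, ]
  expect_equal(mean(fin$cells_phagocytosing[fin$condition == "AD"]) /
                 mean(fin$cells_phagocytosing[fin$condition == "ctrl"]), 2)

  expect_identical(ts, generate_timeseries(des, 9))
})

test_that("kinetics design validation", {
  cond <- kinetics_condition("c", 0.5, 0.3, 10)
  expect_error(kinetics_design(cond, timepoints_h = numeric(0)), "non-empty")
  expect_error(kinetics_design(cond, timepoints_h = c(0, 2, 2)),
               "strictly increasing")
  expect_error(kinetics_design(cond, timepoints_h = 0:10, wash_time_h = 12),
               "inside the time range")
  # CytD forces a zero plateau
  expect_equal(kinetics_condition("x", 0.7, 1, 1, "AD", "CytD")$plateau, 0)
})

test_that("degenerate stack shapes are rejected", {
  expect_error(stack_sim_params(shape_zyx = c(4L, 64L, 64L)), ">= 8")
  expect_error(stack_sim_params(engulfed_fraction = 1.4), "fraction")
  expect_error(stack_sim_params(glial_volume_fraction = -0.1), "fraction")
})
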