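test_that("cell-count index is the percentage of cells phagocytosing", {
  expect_equal(index_cell_fraction(25, 100), 25)
  expect_equal(index_cell_fraction(0, 100), 0)
  expect_error(index_cell_fraction(5, 0), "> 0")
  expect_error(index_cell_fraction(120, 100), "\\[0, cells_total\\]")
})

test_that("area index divides pHrodo signal by starting confluency", {
  expect_equal(index_area(200, 50), 4)
  expect_equal(index_area(200, 100), 2)       # doubling confluency halves it
  expect_error(index_area(200, 0), "> 0")
  expect_error(index_area(-1, 10), ">= 0")
})

test_that("control normalization fixes the control final mean at 100%", {
  des <- kinetics_design(
    rbind(kinetics_condition("control", 0.40, 0.25, 12, "control"),
          kinetics_condition("AD", 0.80, 0.25, 12, "AD")),
    timepoints_h = seq(0, 48, 2), wells_per_condition = 3L,
    n_replicates = 4L, well_noise_cv = 0.1, mode = "red_area")
  curves <- normalize_to_final_control(phago_index(generate_timeseries(des, 4)))
  fin <- curves[curves$time_h == 48, ]
  for (r in unique(fin$replicate_id))
    expect_equal(mean(fin$index_pct[fin$replicate_id == r &
                                      fin$disease == "control"]), 100)
  # noiseless 2x plateau maps the AD final mean to 200%
  des0 <- des; des0$well_noise_cv <- 0
  cv0 <- normalize_to_final_control(phago_index(generate_timeseries(des0, 4)))
  fin0 <- cv0[cv0$time_h == 48, ]
  expect_equal(mean(fin0$index_pct[fin0$disease == "AD"]), 200)

  # normalization is idempotent
  again <- cv0
  again$index <- again$index_pct
  again <- normalize_to_final_control(again)
  expect_equal(again$index_pct, cv0$index_pct)
})

test_that("normalization fails without a positive final control", {
  df <- data.frame(well_id = "w1", replicate_id = "r1", disease = "AD",
                   treatment = "none", time_h = c(0, 1), index = c(0, 5))
  expect_error(normalize_to_final_control(df), "no control well")
  df2 <- data.frame(well_id = "w1", replicate_id = "r1", disease = "control",
                    treatment = "none", time_h = c(0, 1), index = c(1, 0))
  expect_error(normalize_to_final_control(df2), "not positive")
})

test_that("trapezoidal AUC matches closed forms and is linear", {
  a <- curve_auc(c(0, 1, 2), c(0, 50, 100))
  expect_equal(as.numeric(a), 100)
  expect_equal(as.numeric(curve_auc(c(0, 48), c(100, 100))), 4800)
  expect_error(curve_auc(5, 10), "at least 2")
  # linearity
  t <- 0:10; v <- runif(11, 0, 50); w <- runif(11, 0, 50)
  expect_equal(as.numeric(curve_auc(t, 3 * v)),
               3 * as.numeric(curve_auc(t, v)))
  expect_equal(as.numeric(curve_auc(t, v + w)),
               as.numeric(curve_auc(t, v)) + as.numeric(curve_auc(t, w)))
  # interior gaps interpolate; leading/trailing gaps truncate the range
  vv <- c(0, NA, 20, 30, NA)
  a2 <- curve_auc(0:4, vv)
  expect_equal(as.numeric(a2), as.numeric(curve_auc(0:3, c(0, 10, 20, 30))))
  expect_equal(attr(a2, "time_range"), c(0, 3))
})

test_that("noiseless AUC ratio matches numerical integration of the model", {
  des <- kinetics_design(
    rbind(kinetics_condition("control", 0.30, 0.2, 16, "control"),
          kinetics_condition("AD", 0.60, 0.2, 16, "AD")),
    timepoints_h = seq(0, 48, 2), wells_per_condition = 1L,
    well_noise_cv = 0, mode = "red_area")
  curves <- normalize_to_final_control(phago_index(generate_timeseries(des, 1)))
  aucs <- auc_table(curves)
  ratio <- aucs$auc[aucs$condition == "AD"] /
    aucs$auc[aucs$condition == "control"]
  num <- function(pl) stats::integrate(function(t)
    logistic_uptake(t, pl, 0.2, 16), 0, 48, subdivisions = 2000L)$value
  expect_equal(ratio, num(0.60) / num(0.30), tolerance = 1e-3)
})

test_that("degradation metrics: decay, retention, cathepsin blockade", {
  expect_equal(degradation_metrics(0:10, c(0, 5, 10, rep(0, 8)), 2)$fraction_remaining, 0)
  expect_equal(degradation_metrics(0:10, c(0, 5, rep(10, 9)), 2)$fraction_remaining, 1)
  expect_error(degradation_metrics(0:10, rep(0, 11), 2), "peak is 0")
  expect_error(degradation_metrics(0:10, rep(1, 11), 20), "outside")

  curves <- normalize_to_final_control(
    phago_index(generate_timeseries(kinetics_preset("degradation"), 2)))
  frac <- vapply(split(curves, curves$well_id), function(d) {
    d <- d[order(d$time_h), ]
    degradation_metrics(d$time_h, d$index_pct, 2)$fraction_remaining
  }, numeric(1))
  cond <- vapply(split(curves, curves$well_id),
                 function(d) d$treatment[1], character(1))
  expect_gt(min(frac[cond == "K777"]), 0.8)      # blockade holds the signal
  expect_lt(max(frac[cond == "none"]), 0.2)      # untreated wells degrade
})
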