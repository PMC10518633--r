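test_that("the 25% overlap rule decides the worked object pair", {
  pr <- make_overlap_pair(100L, 40L, 10L)       # overlap = 25% of smaller
  rec <- colocalize_pair(pr$seg_a, pr$seg_b)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$fraction_of_b, 0.25)
  expect_true(rec$colocalized)

  rec9 <- with(make_overlap_pair(100L, 40L, 9L),
               colocalize_pair(seg_a, seg_b))
  expect_equal(rec9$fraction_of_b, 0.225)
  expect_false(rec9$colocalized)

  # identical objects: both fractions 1, colocalized
  lab <- array(0L, c(4, 8, 8)); lab[1:2, 1:3, 1:3] <- 1L
  self <- colocalize_pair(seg_from_labels(lab), seg_from_labels(lab))
  expect_equal(c(self$fraction_of_a, self$fraction_of_b), c(1, 1))
  expect_true(self$colocalized)
})

test_that("alternative denominator rules anchor the fraction differently", {
  pr <- make_overlap_pair(100L, 40L, 10L)
  rec_a <- colocalize_pair(pr$seg_a, pr$seg_b,
                           coloc_params(denominator_rule = "object_a"))
  expect_false(rec_a$colocalized)               # 10/100 < 25%
  rec_b <- colocalize_pair(pr$seg_a, pr$seg_b,
                           coloc_params(denominator_rule = "object_b"))
  expect_true(rec_b$colocalized)                # 10/40 >= 25%
  expect_error(coloc_params(min_overlap_fraction = 0), "in \\(0, 1\\]")
})

test_that("min_object verdicts are symmetric and overlaps bounded", {
  set.seed(3)
  for (rep in 1:3) {
    ma <- array(runif(4 * 20 * 20) < 0.15, c(4, 20, 20))
    mb <- array(runif(4 * 20 * 20) < 0.15, c(4, 20, 20))
    sa <- label_components(ma, channel = "a")
    sb <- label_components(mb, channel = "b")
    ab <- colocalize_pair(sa, sb)
    ba <- colocalize_pair(sb, sa)
    key_ab <- paste(ab$object_a, ab$object_b, ab$colocalized)
    key_ba <- paste(ba$object_b, ba$object_a, ba$colocalized)
    expect_setequal(key_ab, key_ba)
    expect_true(all(ab$fraction_of_a >= 0 & ab$fraction_of_a <= 1))
    expect_true(all(ab$fraction_of_b >= 0 & ab$fraction_of_b <= 1))
    expect_true(all(ab$overlap_voxels <=
                      pmin(sa$objects$voxel_count[ab$object_a],
                           sb$objects$voxel_count[ab$object_b])))
    # voxel-level AND equals the sum of all pair overlaps
    expect_equal(sum(ab$overlap_voxels), sum(ma & mb))
  }
})

test_that("shape mismatches are rejected", {
  sa <- label_components(array(TRUE, c(4, 8, 8)))
  sb <- label_components(array(TRUE, c(4, 8, 9)))
  expect_error(colocalize_pair(sa, sb), "different stack shapes")
  expect_error(colocalized_volume(array(TRUE, c(2, 2, 2)),
                                  array(TRUE, c(2, 2, 3))), "differ")
})

test_that("voxel-level colocalized volumes match the AND oracle", {
  expect_equal(colocalized_volume(array(c(TRUE, FALSE), c(2, 4, 4)),
                                  array(c(FALSE, TRUE), c(2, 4, 4))), 0)
  # a 20-voxel punctum fully inside glia at the standard voxel size
  syn <- array(FALSE, c(6, 10, 10)); syn[2:3, 2:3, 2:6] <- TRUE
  glia <- array(TRUE, c(6, 10, 10))
  expect_equal(colocalized_volume(syn, glia), 20 * 0.18 * 0.18 * 0.3)
  expect_equal(colocalized_volume(syn, glia), 0.1944)

  set.seed(5)
  for (rep in 1:3) {
    a <- array(runif(240) < 0.4, c(4, 6, 10))
    b <- array(runif(240) < 0.4, c(4, 6, 10))
    g <- array(runif(240) < 0.5, c(4, 6, 10))
    expect_equal(colocalized_volume(a, b, c(1, 1, 1)), sum(a & b))
    expect_equal(triple_colocalized_volume(a, b, g, c(1, 1, 1)),
                 sum(a & b & g))
  }
})

test_that("triple colocalization degenerate cases", {
  m <- array(runif(4 * 6 * 6) < 0.5, c(4, 6, 6))
  none <- array(FALSE, c(4, 6, 6))
  expect_equal(triple_colocalized_volume(m, none, m), 0)
  expect_equal(triple_colocalized_volume(m, m, m, c(1, 1, 1)), sum(m))
})

test_that("stack metrics normalize as specified and flag zero glia", {
  # glial volume 1000 um^3, colocalized 50 um^3 -> normalized 0.05
  vox <- c(1, 1, 1)
  d <- c(10L, 10L, 10L)
  lab_syn <- array(0L, d); lab_syn[1:100] <- 1L
  lab_glia <- array(0L, d); lab_glia[51:150] <- 1L   # overlap 50 voxels
  st <- image_stack(list(syn = array(0, d), glia = array(0, d)),
                    voxel_size_zyx = vox)
  segs <- list(syn = seg_from_labels(lab_syn, vox, "syn"),
               glia = seg_from_labels(lab_glia, vox, "glia"))
  met <- compute_stack_metrics(st, segs)
  expect_equal(met$coloc_volume_um3, 50)
  expect_equal(met$glia_volume_um3, 100)
  expect_equal(met$coloc_per_glia_volume, 0.5)
  expect_equal(met$coloc_per_stack_volume, 50 / 1000)
  expect_equal(met$burden_frac_glia, 0.1)

  # zero glial volume: normalized metric flagged missing, others intact
  segs0 <- list(syn = seg_from_labels(lab_syn, vox, "syn"),
                glia = seg_from_labels(array(0L, d), vox, "glia"))
  met0 <- compute_stack_metrics(st, segs0)
  expect_true(is.na(met0$coloc_per_glia_volume))
  expect_equal(met0$coloc_volume_um3, 0)
  expect_equal(met0$burden_frac_syn, 0.1)
})

test_that("plaque proximity stratifies objects by physical distance", {
  d <- c(8L, 20L, 20L)
  plaque <- array(FALSE, d); plaque[3:5, 2:5, 2:5] <- TRUE
  lab <- array(0L, d)
  lab[4, 3, 3] <- 1L          # inside the plaque -> distance 0
  lab[4, 3, 12] <- 2L         # 7 voxels away in y: 1.26 um -> near at 10 um
  lab[4, 3, 20] <- 3L         # 15 voxels: 2.7 um -> far at 2 um threshold
  seg <- seg_from_labels(lab)
  strat10 <- plaque_stratify(seg, plaque, distance_um = 10)
  expect_equal(strat10$stratum, c("near", "near", "near"))
  expect_equal(strat10$min_distance_um[1], 0)
  strat2 <- plaque_stratify(seg, plaque, distance_um = 2)
  expect_equal(strat2$stratum, c("near", "near", "far"))
  # brute-force distance for object 3
  pts <- which(plaque, arr.ind = TRUE)
  dmin <- sqrt(min(((pts[, 1] - 4) * 0.3)^2 + ((pts[, 2] - 3) * 0.18)^2 +
                     ((pts[, 3] - 20) * 0.18)^2))
  expect_equal(strat2$min_distance_um[3], dmin)

  # empty plaque mask: stack is plaque-free, objects unlabelled
  strat0 <- plaque_stratify(seg, array(FALSE, d))
  expect_true(strat0$plaque_free)
  expect_true(all(is.na(strat0$stratum)))
})

test_that("near and far colocalized volumes partition the total", {
  g <- generate_stack(tiny_sim_params(plaque_count = 1L,
                                      engulfed_fraction = 0.2), seed = 21)
  segs <- segment_stack(g$stack)
  met <- compute_stack_metrics(g$stack, segs, plaque_channel = "plaque")
  expect_false(met$plaque_free)
  expect_equal(met$coloc_volume_near_um3 + met$coloc_volume_far_um3,
               met$coloc_volume_um3)
})

test_that("measured colocalized volume rises with the planted plant", {
  fs <- seq(0.04, 0.32, length.out = 6)
  vals <- t(vapply(seq_along(fs), function(i) {
    g <- generate_stack(stack_sim_params(shape_zyx = c(16L, 64L, 64L),
                                         engulfed_fraction = fs[i]),
                        seed = 200 + i)
    segs <- segment_stack(g$stack)
    rec <- colocalize_pair(segs$syn, segs$glia)
    c(planted = sum(g$truth$puncta$volume_um3[g$truth$puncta$engulfed]),
      measured = sum(rec$overlap_volume_um3[rec$colocalized]))
  }, numeric(2)))
  expect_gt(cor(vals[, "planted"], vals[, "measured"], method = "spearman"),
            0.8)
})
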