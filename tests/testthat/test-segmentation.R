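test_that("flat input is the documented degenerate case of mean - C", {
  x <- array(42, c(4, 16, 16))
  expect_true(all(local_mean_threshold(x, seg_params(5L, 0.5))))
  expect_false(any(local_mean_threshold(x, seg_params(5L, -0.5))))
})

test_that("local mean threshold equals the brute-force window oracle", {
  set.seed(42)
  x <- array(runif(4 * 16 * 16, 0, 255), c(4, 16, 16))
  for (w in c(5L, 4L, 10L)) {     # odd, even, larger-than-typical windows
    m_oracle <- oracle_local_mean(x, w)
    for (c_off in c(3, -2)) {
      mask <- local_mean_threshold(x, seg_params(w, c_off))
      expect_identical(mask, x > (m_oracle - c_off))
    }
  }
})

test_that("thresholding is invariant to a constant intensity shift", {
  set.seed(1)
  x <- array(runif(4 * 16 * 16, 0, 200), c(4, 16, 16))
  p <- seg_params(7L, 1.5)
  expect_identical(local_mean_threshold(x, p),
                   local_mean_threshold(x + 17, p))
})

test_that("non-finite intensities are rejected", {
  x <- array(1, c(4, 8, 8)); x[2, 3, 4] <- NA
  expect_error(local_mean_threshold(x, seg_params(3L, 1)), "non-finite")
})

test_that("component labelling matches a flood-fill oracle", {
  set.seed(7)
  for (rep in 1:3) {
    mask <- array(runif(4 * 16 * 16) < 0.22, c(4, 16, 16))
    for (conn in c(6L, 18L, 26L)) {
      seg <- label_components(mask, connectivity = conn)
      fl <- oracle_flood_fill(mask, conn)
      expect_true(same_partition(seg$labels, fl))
      expect_equal(sort(seg$objects$voxel_count),
                   sort(as.integer(table(fl[fl > 0L]))))
    }
  }
})

test_that("corner-touching voxels split by connectivity", {
  mask <- array(FALSE, c(3, 4, 4))
  mask[1, 1, 1] <- TRUE
  mask[2, 2, 2] <- TRUE                 # shares only a corner
  expect_equal(nrow(label_components(mask, 26L)$objects), 1L)
  expect_equal(nrow(label_components(mask, 6L)$objects), 2L)
  expect_equal(nrow(label_components(array(FALSE, c(3, 4, 4)))$objects), 0L)
})

test_that("object voxel counts partition the mask; min_size filters", {
  set.seed(11)
  mask <- array(runif(6 * 20 * 20) < 0.15, c(6, 20, 20))
  seg <- label_components(mask)
  expect_equal(sum(seg$objects$voxel_count), sum(mask))
  expect_equal(seg$objects$volume_um3,
               seg$objects$voxel_count * prod(default_voxel_size()))

  seg2 <- label_components(mask, min_size = 3L)
  dropped <- sum(seg$objects$voxel_count[seg$objects$voxel_count < 3L])
  expect_equal(sum(seg2$objects$voxel_count) + dropped, sum(mask))
  expect_true(all(seg2$objects$voxel_count >= 3L))
  expect_equal(sort(unique(as.vector(seg2$labels[seg2$labels > 0]))),
               seg2$objects$id)
})

test_that("built-in marker presets expose the printed window/C pairs", {
  pr <- segmentation_presets()
  expect_equal(c(pr$CD68$window_size, pr$CD68$c_offset), c(70, 0.2))
  expect_equal(c(pr$Syn1$window_size, pr$Syn1$c_offset), c(10, 1))
  expect_equal(c(pr$GFAP$window_size, pr$GFAP$c_offset), c(70, 0.15))
  expect_null(pr$CD68$min_size)
  expect_identical(pr$CD68$method, "mean")
})

test_that("segment_stack requires present channels and applies presets", {
  g <- generate_stack(tiny_sim_params(), seed = 2)
  expect_error(segment_stack(g$stack, presets = list(nope = "Syn1")),
               "not present")
  segs <- segment_stack(g$stack)
  expect_setequal(names(segs), c("glia", "syn"))
  expect_s3_class(segs$syn, "ChannelSegmentation")
})

test_that("paper presets recover planted puncta and engulfed fraction", {
  p <- stack_sim_params(shape_zyx = c(24L, 96L, 96L), engulfed_fraction = 0.1)
  g <- generate_stack(p, seed = 101)
  segs <- segment_stack(g$stack)
  rec <- colocalize_pair(segs$syn, segs$glia)
  pc <- g$truth$puncta
  d <- dim(g$stack)
  lin <- round(pc$z_um / 0.3) + 1 +
    d[1] * (round(pc$y_um / 0.18) + d[2] * round(pc$x_um / 0.18))
  obj_at <- segs$syn$labels[lin]
  # nearly every planted punctum is hit by a segmented object
  expect_gte(mean(obj_at > 0), 0.9)
  # a punctum reads as ingested when it lies in the glial foreground and
  # its object passes the overlap rule; that fraction tracks the plant
  in_glia <- segs$glia$labels[lin] > 0
  coloc_objs <- unique(rec$object_a[rec$colocalized])
  recovered <- mean(obj_at %in% coloc_objs & in_glia)
  expect_lt(abs(recovered - 0.1), 0.05)
})
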