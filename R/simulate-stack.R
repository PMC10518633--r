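#' Parameters for simulating a multi-channel 3D stack
#'
#' Describes one synthetic cortical-tissue stack: a glial channel
#' (filamentous, GFAP-like, or blobby, CD68-like morphology), a synaptic
#' channel of diffraction-limited puncta of which a planted fraction sits
#' inside the glial ground-truth volume, an optional neurite channel
#' (MAP2-like tubes) and an optional amyloid-plaque channel. Rendering
#' follows the standard fluorescence forward model: signal, Gaussian PSF
#' blur, Poisson shot noise, additive Gaussian read noise, quantization.
#'
#' @param shape_zyx Voxel counts (z, y, x); every axis must have at least
#'   8 voxels.
#' @param voxel_size_zyx Micrometres per voxel (z, y, x).
#' @param glial_morphology `"filamentous"` (dilated branching random walks)
#'   or `"blobby"` (union of random ellipsoids).
#' @param n_glial_cells Number of glial structures placed before the
#'   volume-fraction target takes over; more are added until the target
#'   is reached.
#' @param glial_volume_fraction Target fraction of the stack volume occupied
#'   by glial ground truth.
#' @param punctum_density Synaptic puncta per um^3 (0 disables puncta; the
#'   synaptic channel then contains only background and noise).
#' @param punctum_radius Gaussian sigma of a punctum, micrometres.
#' @param engulfed_fraction Fraction of puncta planted inside the glial
#'   ground truth (centroid inside a glial object).
#' @param neurite_density Background neurite tubes per stack (0 disables the
#'   neurite channel unless `neurite_engulfed_volume_ratio > 0`).
#' @param neurite_engulfed_volume_ratio Target ratio of triple
#'   (syn & neurite & glia) to pairwise (syn & glia) ground-truth volume:
#'   this fraction of engulfed puncta receives a co-engulfed neurite
#'   fragment through it.
#' @param plaque_count Amyloid-plaque blobs per stack (0 disables).
#' @param psf_sigma_zyx Gaussian PSF sigma in voxels (z, y, x).
#' @param background_level Constant background, digital numbers.
#' @param read_noise_sd Gaussian read noise sd, digital numbers.
#' @param photon_scale Photons per digital number for the Poisson shot-noise
#'   stage; larger values mean less shot noise.
#' @param bit_depth Output quantization (8 gives 0..255).
#' @param amplitudes Named peak signal amplitudes (digital numbers) for
#'   channels `glia`, `syn`, `neurite`, `plaque`.
#' @return An object of class `StackSimParams`.
#' @export
stack_sim_params <- function(shape_zyx = c(32L, 128L, 128L),
                             voxel_size_zyx = default_voxel_size(),
                             glial_morphology = c("filamentous", "blobby"),
                             n_glial_cells = 6L,
                             glial_volume_fraction = 0.08,
                             punctum_density = 1.2,
                             punctum_radius = 0.05,
                             engulfed_fraction = 0.1,
                             neurite_density = 0,
                             neurite_engulfed_volume_ratio = 0,
                             plaque_count = 0L,
                             psf_sigma_zyx = c(0.8, 0.6, 0.6),
                             background_level = 0,
                             read_noise_sd = 0.15,
                             photon_scale = 50,
                             bit_depth = 8L,
                             amplitudes = c(glia = 150, syn = 4200,
                                            neurite = 130, plaque = 170)) {
  glial_morphology <- match.arg(glial_morphology)
  shape_zyx <- as.integer(shape_zyx)
  if (length(shape_zyx) != 3L || any(shape_zyx < 8L))
    stop("shape_zyx must be 3 voxel counts, each >= 8", call. = FALSE)
  voxel_size_zyx <- as.numeric(voxel_size_zyx)
  if (length(voxel_size_zyx) != 3L || any(voxel_size_zyx <= 0))
    stop("voxel_size_zyx must be 3 positive sizes (um)", call. = FALSE)
  for (nm in c("glial_volume_fraction", "engulfed_fraction",
               "neurite_engulfed_volume_ratio")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(nm, " must be a fraction in [0, 1]", call. = FALSE)
  }
  if (punctum_density < 0 || punctum_radius <= 0)
    stop("punctum_density must be >= 0 and punctum_radius > 0", call. = FALSE)
  if (neurite_density < 0 || plaque_count < 0)
    stop("neurite_density and plaque_count must be >= 0", call. = FALSE)
  if (any(psf_sigma_zyx < 0) || read_noise_sd < 0 || photon_scale <= 0 ||
      background_level < 0)
    stop("invalid noise model parameters", call. = FALSE)
  structure(list(
    shape_zyx = shape_zyx, voxel_size_zyx = voxel_size_zyx,
    glial_morphology = glial_morphology, n_glial_cells = as.integer(n_glial_cells),
    glial_volume_fraction = glial_volume_fraction,
    punctum_density = punctum_density, punctum_radius = punctum_radius,
    engulfed_fraction = engulfed_fraction, neurite_density = neurite_density,
    neurite_engulfed_volume_ratio = neurite_engulfed_volume_ratio,
    plaque_count = as.integer(plaque_count), psf_sigma_zyx = psf_sigma_zyx,
    background_level = background_level, read_noise_sd = read_noise_sd,
    photon_scale = photon_scale, bit_depth = as.integer(bit_depth),
    amplitudes = amplitudes), class = "StackSimParams")
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k / sum(k)
}

empty_mask <- function(shape) array(FALSE, dim = shape)

# one filamentous glial cell: compact soma plus branching persistent random
# walks stamped as capsules with tapering radius (star-shaped astrocyte)
filament_cell_segments <- function(extent_um, step_um = 0.7,
                                   n_branches = 4L, steps_per_branch = 20L,
                                   radius_um = 0.5) {
  soma <- runif(3, 0.1, 0.9) * extent_um
  segs <- list()
  queue <- list()
  for (b in seq_len(n_branches)) {
    u <- rnorm(3)
    queue[[length(queue) + 1L]] <-
      list(p = soma, dir = u / sqrt(sum(u^2)), left = steps_per_branch,
           r = radius_um)
  }
  while (length(queue) > 0L) {
    st <- queue[[1L]]; queue[[1L]] <- NULL
    p <- st$p; dir <- st$dir
    for (i in seq_len(st$left)) {
      dir <- dir + 0.45 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      q <- p + step_um * dir
      q <- pmin(pmax(q, 0), extent_um)          # stay inside the stack
      r <- st$r * (1 - 0.4 * i / st$left)       # taper towards the tip
      segs[[length(segs) + 1L]] <- list(p0 = p, p1 = q, r = r)
      p <- q
      if (runif(1) < 0.08 && st$left - i > 4L) {
        u <- dir + rnorm(3)
        queue[[length(queue) + 1L]] <-
          list(p = p, dir = u / sqrt(sum(u^2)), left = st$left - i, r = r)
      }
    }
  }
  segs
}

# grow glial ground truth until the volume-fraction target is met on the
# imaged (cropped) region
simulate_glia_mask <- function(params, margin = c(0L, 0L, 0L)) {
  shape <- params$shape_zyx
  vs <- params$voxel_size_zyx
  extent <- (shape - 1) * vs
  mask <- empty_mask(shape)
  target <- params$glial_volume_fraction
  if (target <= 0) return(mask)
  core <- function(m) mean(m[(margin[1] + 1L):(shape[1] - margin[1]),
                             (margin[2] + 1L):(shape[2] - margin[2]),
                             (margin[3] + 1L):(shape[3] - margin[3])])
  n_placed <- 0L
  max_cells <- 5000L
  accepted <- NULL                 # blob centres already placed (blobby mode)
  while (core(mask) < target && n_placed < max_cells) {
    if (params$glial_morphology == "filamentous") {
      segs <- filament_cell_segments(extent)
      p0 <- t(vapply(segs, `[[`, numeric(3), "p0"))
      p1 <- t(vapply(segs, `[[`, numeric(3), "p1"))
      r <- vapply(segs, `[[`, numeric(1), "r")
      mask <- cpp_fill_capsules(mask, shape, vs, p0, p1, r, NULL)
    } else {
      # many small phago-lysosomal blobs spread through the stack (so every
      # thresholding window sees some structure), spaced like cellular
      # compartments rather than falling as a Poisson rain
      ctr <- NULL
      for (try in 1:30) {
        cand <- runif(3, 0, 1) * extent
        if (is.null(accepted) || nrow(accepted) == 0L ||
            min(colSums((t(accepted) - cand)^2)) > 3.0^2) {
          ctr <- matrix(cand, 1L)
          break
        }
      }
      if (is.null(ctr)) ctr <- matrix(runif(3, 0, 1) * extent, 1L)
      accepted <- rbind(accepted, ctr)
      ax <- matrix(c(runif(1, 0.5, 0.87), runif(2, 0.8, 1.38)), 1L)
      mask <- cpp_fill_ellipsoids(mask, shape, vs, ctr, ax)
    }
    n_placed <- n_placed + 1L
  }
  mask
}

# Matern-II-style spaced sampling of voxel indices: candidates are taken in
# random order and accepted unless within min_dist_um (physical, anisotropy
# respected) of an accepted point; if the region jams before n are placed,
# the remainder is drawn uniformly. Phago-lysosomal compartments are spread
# along glial processes by transport rather than falling as a Poisson rain,
# and this quasi-regular spacing reproduces that.
sample_spaced <- function(idx_pool, n, shape, vs, min_dist_um) {
  if (n >= length(idx_pool)) {
    return(sample(idx_pool, n, replace = n > length(idx_pool)))
  }
  rz <- max(1L, floor(min_dist_um / vs[1]))
  ry <- max(1L, floor(min_dist_um / vs[2]))
  rx <- max(1L, floor(min_dist_um / vs[3]))
  blocked <- array(FALSE, dim = shape)
  cand <- sample(idx_pool)
  out <- integer(n)
  got <- 0L
  for (i in cand) {
    if (blocked[i]) next
    got <- got + 1L
    out[got] <- i
    if (got == n) break
    z <- ((i - 1L) %% shape[1]) + 1L
    y <- (((i - 1L) %/% shape[1]) %% shape[2]) + 1L
    x <- ((i - 1L) %/% (shape[1] * shape[2])) + 1L
    blocked[max(1L, z - rz):min(shape[1], z + rz),
            max(1L, y - ry):min(shape[2], y + ry),
            max(1L, x - rx):min(shape[3], x + rx)] <- TRUE
  }
  if (got < n)                       # region jammed; fill in uniformly
    out[(got + 1L):n] <- sample(setdiff(idx_pool, out[seq_len(got)]),
                                n - got)
  out
}

# voxel linear index -> 0-based (z, y, x) matrix
index_to_zyx0 <- function(idx, shape) {
  idx0 <- idx - 1L
  z <- idx0 %% shape[1]
  y <- (idx0 %/% shape[1]) %% shape[2]
  x <- idx0 %/% (shape[1] * shape[2])
  cbind(z, y, x)
}

# stamp ground-truth punctum labels (support: 1.5 sigma ellipsoid)
stamp_punctum_labels <- function(shape, vs, centers0, sigma_vox) {
  lab <- array(0L, dim = shape)
  h <- ceiling(1.5 * sigma_vox)
  n <- nrow(centers0)
  if (n == 0L) return(lab)
  if (all(1.5 * sigma_vox <= 1)) {
    # sub-voxel support: the label is the centre voxel
    lin <- centers0[, 1] + 1L + shape[1] * (centers0[, 2] +
             shape[2] * centers0[, 3])
    lab[lin] <- seq_len(n)
    return(lab)
  }
  for (i in seq_len(n)) {
    c0 <- centers0[i, ]
    z <- max(0, c0[1] - h[1]):min(shape[1] - 1, c0[1] + h[1])
    y <- max(0, c0[2] - h[2]):min(shape[2] - 1, c0[2] + h[2])
    x <- max(0, c0[3] - h[3]):min(shape[3] - 1, c0[3] + h[3])
    dz <- (z - c0[1]) / sigma_vox[1]
    dy <- (y - c0[2]) / sigma_vox[2]
    dx <- (x - c0[3]) / sigma_vox[3]
    r2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
    sel <- which(r2 <= 1.5^2, arr.ind = TRUE)
    if (nrow(sel) == 0L) next
    lin <- (z[sel[, 1]] + 1L) +
      shape[1] * (y[sel[, 2]]) +
      shape[1] * shape[2] * (x[sel[, 3]])
    lab[lin] <- i
  }
  lab
}

render_channel <- function(clean, params) {
  shape <- params$shape_zyx
  kz <- gauss_kernel(params$psf_sigma_zyx[1])
  ky <- gauss_kernel(params$psf_sigma_zyx[2])
  kx <- gauss_kernel(params$psf_sigma_zyx[3])
  blurred <- cpp_conv3_sep(clean, shape, kz, ky, kx)
  lam <- (blurred + params$background_level) * params$photon_scale
  x <- stats::rpois(length(lam), lam) / params$photon_scale
  x <- x + stats::rnorm(length(x), 0, params$read_noise_sd)
  top <- 2^params$bit_depth - 1
  x <- round(pmin(pmax(x, 0), top))
  array(x, dim = shape)
}

#' Simulate one multi-channel stack with ground truth
#'
#' Generates an [image_stack()] and the matching ground truth: integer label
#' volumes per channel, a punctum table with planted engulfment flags, and
#' the parameter record. The same `(params, seed)` pair always returns
#' bit-identical output.
#'
#' Planted geometry: engulfed puncta are centred on voxels sampled uniformly
#' from the glial ground-truth volume; all other puncta are placed with
#' their full support clear of the glia (structures cannot overlap in
#' space unless engulfment is planted). Background neurite tubes likewise
#' avoid the glial volume; co-engulfed neurite fragments are short tubes
#' threaded through a planted subset of the engulfed puncta.
#'
#' @param params A [stack_sim_params()] object.
#' @param seed Integer seed; fully determines the output.
#' @param stack_id,case_id Identifiers stored on the stack.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   only (fast path for planted-truth tallies).
#' @return List with elements `stack` (an `ImageStack`, `NULL` when
#'   `render = FALSE`) and `truth` (class `GroundTruth`).
#' @export
generate_stack <- function(params, seed, stack_id = "stack1",
                           case_id = NA_character_, render = TRUE) {
  stopifnot(inherits(params, "StackSimParams"))
  withr::with_seed(as.integer(seed), {
    # simulate inside a guard margin and crop: the imaged volume sits inside
    # continuous tissue, so structures and light must continue past its faces
    margin <- c(4L, 6L, 6L)
    out_shape <- params$shape_zyx
    shape <- out_shape + 2L * margin
    params_pad <- params
    params_pad$shape_zyx <- shape
    vs <- params$voxel_size_zyx
    extent <- (shape - 1) * vs
    phys_vol <- prod(shape) * voxel_volume_um3(vs)

    glia_mask <- simulate_glia_mask(params_pad, margin)
    # blobby (phago-lysosomal) staining also shows abundant sub-micron
    # specks; they carry negligible volume but are real stain
    n_speck <- 0L
    speck0 <- NULL
    if (params$glial_morphology == "blobby") {
      n_speck <- stats::rpois(1L, 0.035 * phys_vol)
      if (n_speck > 0L) {
        sidx <- sample.int(prod(shape), n_speck)
        speck0 <- index_to_zyx0(sidx, shape)
        glia_mask[sidx] <- TRUE
      }
    }
    glia_lab <- cpp_label3(glia_mask, shape, 26L)
    glia_d2 <- cpp_edt3_sq(glia_mask, shape, vs)   # distance to glia, um^2

    # ---- synaptic puncta ----
    n_puncta <- if (params$punctum_density > 0)
      stats::rpois(1L, params$punctum_density * phys_vol) else 0L
    sigma_vox <- params$punctum_radius / vs
    clearance_um <- 0.35      # keeps planted structures from overlapping

    glia_idx <- which(glia_mask)
    f_eng <- min(params$engulfed_fraction, 1)
    n_eng <- if (n_puncta > 0L && length(glia_idx) > 0L)
      stats::rbinom(1L, n_puncta, f_eng) else 0L
    n_out <- n_puncta - n_eng

    centers0 <- matrix(numeric(0), 0L, 3L)
    engulfed <- logical(0)
    host <- integer(0)
    if (n_eng > 0L) {
      idx <- sample_spaced(glia_idx, n_eng, shape, vs, min_dist_um = 0.55)
      centers0 <- rbind(centers0, index_to_zyx0(idx, shape))
      engulfed <- c(engulfed, rep(TRUE, n_eng))
      host <- c(host, glia_lab[idx])
    }
    if (n_out > 0L) {
      # sample centres whose whole punctum support avoids the glial volume
      free_idx <- which(glia_d2 > clearance_um^2)
      if (length(free_idx) == 0L)
        stop("no free space left for non-engulfed puncta", call. = FALSE)
      idx <- sample(free_idx, n_out, replace = n_out > length(free_idx))
      centers0 <- rbind(centers0, index_to_zyx0(idx, shape))
      engulfed <- c(engulfed, rep(FALSE, n_out))
      host <- c(host, rep(NA_integer_, n_out))
    }
    syn_lab <- stamp_punctum_labels(shape, vs, centers0, sigma_vox)
    lab_counts <- if (n_puncta > 0L) tabulate(syn_lab, nbins = n_puncta)
                  else integer(0)

    # ---- neurites ----
    has_neurite <- params$neurite_density > 0 ||
      params$neurite_engulfed_volume_ratio > 0
    neurite_mask <- NULL
    triple_ids <- integer(0)
    if (has_neurite) {
      neurite_mask <- empty_mask(shape)
      n_bg <- stats::rpois(1L, params$neurite_density)
      if (n_bg > 0L) {
        for (i in seq_len(n_bg)) {
          p <- runif(3, 0.05, 0.95) * extent
          u <- rnorm(3)                       # dendrites cross the slab in 3D
          u <- u / sqrt(sum(u^2))
          len <- runif(1, 8, 18)
          # 3-segment polyline with slight curvature, clipped out of glia
          pts <- matrix(0, 4L, 3L)
          pts[1L, ] <- p - u * len / 2
          for (s in 2:4) {
            u <- u + 0.25 * rnorm(3); u <- u / sqrt(sum(u^2))
            pts[s, ] <- pts[s - 1L, ] + u * len / 3
          }
          pts <- pmin(pmax(pts, 0), matrix(extent, 4L, 3L, byrow = TRUE))
          # clip well clear of the glia so the rendered tube's blurred
          # foreground cannot bleed into the glial foreground
          neurite_mask <- cpp_fill_capsules(
            neurite_mask, shape, vs, pts[1:3, , drop = FALSE],
            pts[2:4, , drop = FALSE], rep(runif(1, 0.25, 0.35), 3L),
            array(glia_d2 <= 0.45^2, dim = shape))
        }
      }
      n_triple <- round(params$neurite_engulfed_volume_ratio * n_eng)
      if (n_triple > 0L) {
        # a co-engulfed neurite is a short dendrite stub caught at its
        # synapse: it covers the punctum and points out of the glia, so it
        # does not run through neighbouring engulfed cargo; stubs are
        # threaded through locally isolated cargo so the stub cannot graze
        # a neighbouring engulfed punctum
        eng_rows <- which(engulfed)
        ec <- centers0[eng_rows, , drop = FALSE] *
          matrix(vs, length(eng_rows), 3L, byrow = TRUE)
        dm <- as.matrix(stats::dist(ec))
        diag(dm) <- Inf
        nn <- apply(dm, 1L, min)
        triple_ids <- eng_rows[order(-nn, stats::runif(length(nn)))[
          seq_len(n_triple)]]
        ctr_um <- centers0[triple_ids, , drop = FALSE] *
          matrix(vs, n_triple, 3L, byrow = TRUE)
        u <- matrix(0, n_triple, 3L)
        probe <- seq(0.15, 1.2, by = 0.15)
        for (k in seq_len(n_triple)) {
          best <- NULL
          best_score <- Inf
          for (try in 1:24) {
            cand <- rnorm(3)
            cand <- cand / sqrt(sum(cand^2))
            pz <- pmin(pmax(round((ctr_um[k, 1] + probe * cand[1]) / vs[1]),
                            0), shape[1] - 1)
            py <- pmin(pmax(round((ctr_um[k, 2] + probe * cand[2]) / vs[2]),
                            0), shape[2] - 1)
            px <- pmin(pmax(round((ctr_um[k, 3] + probe * cand[3]) / vs[3]),
                            0), shape[3] - 1)
            score <- sum(glia_mask[pz + 1L + shape[1] * (py + shape[2] * px)])
            if (score < best_score) { best_score <- score; best <- cand }
            if (score == 0L) break
          }
          u[k, ] <- best
        }
        neurite_mask <- cpp_fill_capsules(
          neurite_mask, shape, vs, ctr_um - 0.3 * u, ctr_um + 1.2 * u,
          rep(0.25, n_triple), NULL)
      }
    }

    # ---- plaques ----
    plaque_lab <- NULL
    if (params$plaque_count > 0L) {
      pm <- empty_mask(shape)
      for (i in seq_len(params$plaque_count)) {
        ctr <- matrix(runif(3, 0.15, 0.85) * extent, 1L)
        r <- runif(1, 2, 4)
        ax <- matrix(r * c(runif(1, 0.7, 1), runif(2, 0.85, 1.15)), 1L)
        pm <- cpp_fill_ellipsoids(pm, shape, vs, ctr, ax)
      }
      plaque_lab <- cpp_label3(pm, shape, 26L)
    }

    # ---- crop the guard margin away ----
    crop3 <- function(a) a[(margin[1] + 1L):(margin[1] + out_shape[1]),
                           (margin[2] + 1L):(margin[2] + out_shape[2]),
                           (margin[3] + 1L):(margin[3] + out_shape[3]),
                           drop = FALSE]
    keep <- if (n_puncta > 0L)
      centers0[, 1] >= margin[1] & centers0[, 1] < margin[1] + out_shape[1] &
      centers0[, 2] >= margin[2] & centers0[, 2] < margin[2] + out_shape[2] &
      centers0[, 3] >= margin[3] & centers0[, 3] < margin[3] + out_shape[3]
    else logical(0)
    n_kept <- sum(keep)
    remap <- integer(n_puncta)
    remap[which(keep)] <- seq_len(n_kept)
    centers_c <- centers0[keep, , drop = FALSE]
    if (n_kept > 0L)
      centers_c <- centers_c - matrix(margin, n_kept, 3L, byrow = TRUE)

    syn_lab_c <- crop3(syn_lab)
    pos <- syn_lab_c > 0L
    syn_lab_c[pos] <- remap[syn_lab_c[pos]]
    lab_counts_c <- if (n_kept > 0L) tabulate(syn_lab_c, nbins = n_kept)
                    else integer(0)

    glia_mask_c <- crop3(glia_mask)
    glia_lab_c <- cpp_label3(glia_mask_c, out_shape, 26L)
    host_c <- rep(NA_integer_, n_kept)
    eng_c <- engulfed[keep]
    if (n_kept > 0L && any(eng_c)) {
      lin <- centers_c[, 1] + 1L + out_shape[1] *
        (centers_c[, 2] + out_shape[2] * centers_c[, 3])
      host_c[eng_c] <- glia_lab_c[lin[eng_c]]
    }

    puncta <- data.frame(
      id = seq_len(n_kept),
      z_um = if (n_kept) centers_c[, 1] * vs[1] else numeric(0),
      y_um = if (n_kept) centers_c[, 2] * vs[2] else numeric(0),
      x_um = if (n_kept) centers_c[, 3] * vs[3] else numeric(0),
      volume_um3 = lab_counts_c * voxel_volume_um3(vs),
      engulfed = eng_c,
      host_glia_id = host_c,
      coengulfed_neurite = which(keep) %in% triple_ids)

    truth <- structure(list(
      labels = c(list(glia = glia_lab_c, syn = syn_lab_c),
                 if (has_neurite) list(neurite = crop3(neurite_mask)),
                 if (!is.null(plaque_lab)) list(plaque = {
                   pl <- crop3(plaque_lab)
                   cpp_label3(pl > 0L, out_shape, 26L)
                 })),
      puncta = puncta,
      params = params, seed = as.integer(seed),
      stack_id = stack_id, case_id = case_id), class = "GroundTruth")

    if (!render) return(list(stack = NULL, truth = truth))

    # ---- render channels (signal -> PSF -> Poisson -> read noise -> 8 bit)
    amp <- params$amplitudes
    glia_clean <- array(0, dim = shape)
    if (any(glia_mask)) {
      # per-object brightness jitter
      n_obj <- max(glia_lab)
      bright <- amp[["glia"]] * runif(n_obj, 0.8, 1.2)
      glia_clean[glia_idx] <- bright[glia_lab[glia_idx]]
    }
    if (params$glial_morphology == "blobby" && n_speck > 0L) {
      glia_clean <- cpp_add_spots(glia_clean, shape, speck0,
                                  0.1 / vs, rep(600, n_speck), 2.5)
    }
    channels <- list(glia = render_channel(glia_clean, params_pad))

    syn_clean <- array(0, dim = shape)
    if (n_puncta > 0L) {
      # engulfed cargo is aggregated material in phago-lysosomal compartments
      # and reads brighter than free neuropil puncta
      bright_syn <- amp[["syn"]] * ifelse(engulfed, runif(n_puncta, 1.2, 1.8),
                                          runif(n_puncta, 0.7, 1.3))
      syn_clean <- cpp_add_spots(syn_clean, shape, centers0, sigma_vox,
                                 bright_syn, 2.5)
    }
    channels$syn <- render_channel(syn_clean, params_pad)

    if (has_neurite) {
      ne_clean <- array(0, dim = shape)
      ne_clean[neurite_mask] <- amp[["neurite"]]
      channels$neurite <- render_channel(ne_clean, params_pad)
    }
    if (!is.null(plaque_lab)) {
      pl_clean <- array(0, dim = shape)
      pl_clean[plaque_lab > 0L] <- amp[["plaque"]]
      channels$plaque <- render_channel(pl_clean, params_pad)
    }
    channels <- lapply(channels, crop3)

    stack <- image_stack(channels, vs, stack_id = stack_id, case_id = case_id)
    list(stack = stack, truth = truth)
  })
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf(
    "GroundTruth '%s': %d puncta (%d engulfed), glial volume fraction %.3f\n",
    x$stack_id, nrow(x$puncta), sum(x$puncta$engulfed),
    mean(x$labels$glia > 0L)))
  invisible(x)
}
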