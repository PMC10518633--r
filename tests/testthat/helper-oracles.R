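# Shared oracles and fixture builders. Everything is generated in code at
# test time; no stored fixtures.

# brute-force per-slice local window mean with replicate padding
oracle_local_mean <- function(x, w) {
  d <- dim(x)
  lo <- (w - 1) %/% 2
  hi <- w - 1 - lo
  out <- array(0, d)
  for (z in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (xx in seq_len(d[3])) {
        ys <- pmin(pmax((y - lo):(y + hi), 1), d[2])
        xs <- pmin(pmax((xx - lo):(xx + hi), 1), d[3])
        out[z, y, xx] <- mean(x[z, ys, xs])
      }
  out
}

# flood-fill connected components (BFS), connectivity 6/18/26
oracle_flood_fill <- function(mask, conn) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  s <- rowSums(abs(offs))
  keep <- s > 0 & s <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(conn)]
  offs <- offs[keep, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      i0 <- cur - 1L
      z <- i0 %% d[1]; y <- (i0 %/% d[1]) %% d[2]; x <- i0 %/% (d[1] * d[2])
      for (k in seq_len(nrow(offs))) {
        zz <- z + offs$dz[k]; yy <- y + offs$dy[k]; xc <- x + offs$dx[k]
        if (zz < 0 || zz >= d[1] || yy < 0 || yy >= d[2] ||
            xc < 0 || xc >= d[3]) next
        j <- zz + d[1] * (yy + d[2] * xc) + 1L
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# do two label volumes define the same partition of the foreground?
same_partition <- function(a, b) {
  fg <- a > 0L
  if (!identical(fg, b > 0L)) return(FALSE)
  max(a) == max(b) &&
    length(unique(paste(a[fg], b[fg]))) == max(a)
}

# a ChannelSegmentation built directly from a label volume; objects need
# not be connected, which lets worked examples pin exact voxel counts
seg_from_labels <- function(lab, voxel_size = default_voxel_size(),
                            channel = "test") {
  n <- max(lab)
  counts <- tabulate(lab, nbins = n)
  structure(list(
    labels = lab,
    objects = data.frame(id = seq_len(n), voxel_count = counts,
                         volume_um3 = counts * prod(voxel_size)),
    channel = channel, voxel_size_zyx = voxel_size, connectivity = 26L),
    class = "ChannelSegmentation")
}

# two voxel objects (a: na voxels, b: nb voxels) sharing exactly `overlap`
# voxels, in one 6 x 30 x 30 stack; returns list(seg_a, seg_b)
make_overlap_pair <- function(na, nb, overlap) {
  stopifnot(na >= overlap, nb >= overlap)
  d <- c(6L, 30L, 30L)
  la <- array(0L, d); lb <- array(0L, d)
  off <- na - overlap
  la[seq_len(na)] <- 1L
  lb[(off + 1L):(off + nb)] <- 1L
  list(seg_a = seg_from_labels(la), seg_b = seg_from_labels(lb))
}

# small fast simulation parameters for unit tests
tiny_sim_params <- function(...) {
  stack_sim_params(shape_zyx = c(16L, 48L, 48L), ...)
}
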