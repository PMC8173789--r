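# Independent brute-force oracles: literal loops over voxels/points, kept
# deliberately naive and separate from the package's vectorised paths.

# Surface voxels by scanning all 6 face neighbours of every voxel.
brute_surface_indices <- function(grid) {
  d <- dim(grid)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!grid[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    boundary <- FALSE
    for (n in nb) {
      if (any(n < 1) || any(n > d) || !grid[n[1], n[2], n[3]]) {
        boundary <- TRUE
        break
      }
    }
    if (boundary) out <- rbind(out, c(i, j, k))
  }
  out
}

brute_surface_points <- function(mask) {
  idx <- brute_surface_indices(mask$grid)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# Directed nearest-neighbour distances, one explicit loop per point pair.
brute_nn <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      dd <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (dd < best) best <- dd
    }
    out[i] <- best
  }
  out
}

brute_hausdorff_cm <- function(m1, m2) {
  a <- brute_surface_points(m1)
  b <- brute_surface_points(m2)
  dab <- brute_nn(a, b)
  dba <- brute_nn(b, a)
  c(mhd_cm = max(max(dab), max(dba)) / 10,
    ahd_cm = (mean(dab) + mean(dba)) / 2 / 10)
}

# Random blob mask: iid voxel occupancy, retried until nonempty.
random_mask <- function(dims, p = 0.2, spacing = c(1, 1, 1)) {
  repeat {
    g <- array(stats::runif(prod(dims)) < p, dims)
    if (any(g)) return(voxel_mask(g, spacing))
  }
}

box_mask <- function(dims, from, to, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  g <- array(FALSE, dims)
  g[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  voxel_mask(g, spacing, origin)
}

thorax_mean_metrics_df <- function() {
  m <- thorax_index_means()
  data.frame(oar = m$oar, dsc = m$dsc, cmd_cm = m$cmd_cm, dv_pct = m$dv_pct,
             mhd_cm = m$mhd_cm, ahd_cm = m$ahd_cm, stringsAsFactors = FALSE)
}
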