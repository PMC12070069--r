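# Fixture builders and independent oracles shared across test files.

# build a normalized_profile directly from positions + per-channel values
make_profile <- function(positions, values, stack_id = "s1", line_label = "l1") {
  structure(list(positions = positions, values = values,
                 norm_params = NULL,
                 source = list(stack_id = stack_id, line_label = line_label)),
            class = "normalized_profile")
}

# build a raw line_profile from positions + per-channel intensities
make_raw_profile <- function(positions, intensities, stack_id = "s1",
                             line_label = "l1") {
  structure(list(positions = positions, intensities = intensities,
                 source = list(stack_id = stack_id, line_label = line_label)),
            class = "line_profile")
}

# analytic Gaussian-mixture profile values on a grid
gauss_mix <- function(x, centers, widths, amps, baseline = 0) {
  v <- rep(baseline, length(x))
  for (k in seq_along(centers))
    v <- v + amps[k] * exp(-(x - centers[k])^2 / (2 * widths[k]^2))
  v
}

# build an average_profile directly from per-channel mean vectors
make_average <- function(grid, means, sems = NULL, n = 5L) {
  chans <- lapply(names(means), function(ch)
    list(mean = means[[ch]],
         sem = if (is.null(sems)) rep(0, length(grid)) else sems[[ch]]))
  names(chans) <- names(means)
  structure(list(grid = grid, channels = chans, n = n,
                 reference_channel = names(means)[1]),
            class = "average_profile")
}

# brute-force per-pixel maximum projection (independent of max_project)
loop_max_project <- function(arr) {
  nz <- dim(arr)[1]; H <- dim(arr)[2]; W <- dim(arr)[3]
  out <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    m <- arr[1, r, c]
    for (z in seq_len(nz)) if (arr[z, r, c] > m) m <- arr[z, r, c]
    out[r, c] <- m
  }
  out
}

# scalar, loop-based bilinear sampler (independent of bilinear_sample)
loop_bilinear <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    ri <- min(max(r[i], 0), H - 1); ci <- min(max(c[i], 0), W - 1)
    r0 <- min(floor(ri), H - 2); c0 <- min(floor(ci), W - 2)
    fr <- ri - r0; fc <- ci - c0
    out[i] <- (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1] +
      (1 - fr) * fc * img[r0 + 1, c0 + 2] +
      fr * (1 - fc) * img[r0 + 2, c0 + 1] +
      fr * fc * img[r0 + 2, c0 + 2]
  }
  out
}

# two-pass loop computation of mean and sd/sqrt(n) per grid point
loop_mean_sem <- function(mat) {   # rows = grid points, cols = profiles
  n <- ncol(mat)
  mu <- numeric(nrow(mat)); sem <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    s <- 0
    for (j in seq_len(n)) s <- s + mat[i, j]
    mu[i] <- s / n
    ss <- 0
    for (j in seq_len(n)) ss <- ss + (mat[i, j] - mu[i])^2
    sem[i] <- sqrt(ss / (n - 1)) / sqrt(n)
  }
  list(mean = mu, sem = sem)
}

# run a scene through the full in-memory pipeline: project -> profile ->
# normalize -> align -> average; returns the scene, aligned set and average
scene_average <- function(cfg, reference_channel) {
  scene <- generate_scene(cfg)
  gl <- scene$ground_truth$lines
  profiles <- lapply(seq_along(scene$stacks), function(i) {
    proj <- max_project(scene$stacks[[i]])
    row <- gl[gl$stack_id == scene$stacks[[i]]$id, ]
    ls <- line_spec(c(row$start_row, row$start_col),
                    c(row$end_row, row$end_col),
                    linewidth = row$linewidth, label = row$label,
                    medial_end = row$medial_end)
    normalize_profile(extract_profile(proj, ls))
  })
  aligned <- align_profiles(profiles, reference_channel)
  list(scene = scene, aligned = aligned, avg = average_profiles(aligned))
}

# small fast scene used in several end-to-end tests
small_preset <- function(name, seed = 1L, ...) {
  scene_preset(name, n_z = 2L, image_height = 64L, seed = seed, ...)
}
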