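#' Stripe specification for one synthetic channel
#'
#' Describes one fluorescence channel of a synthetic scene as a
#' mixture-of-Gaussians band pattern along the medial-lateral axis: one
#' band centre gives a unimodal stripe, two centres a bimodal/flanking
#' pattern. Intensities are unit-scaled (images are stored as float TIFFs
#' in \[0, 1\]).
#'
#' @param channel_label Channel name (e.g. `"pax3"`).
#' @param band_centers Numeric vector of band centres, in pixels of signed
#'   distance along the stripe axis.
#' @param band_widths Gaussian sigmas (pixels), same length as
#'   `band_centers`; all > 0.
#' @param amplitudes Peak intensities above background, same length; all
#'   >= 0.
#' @param background Constant background intensity, >= 0.
#' @return A `stripe_spec` object.
#' @export
#' @examples
#' stripe_spec("pax3", band_centers = 128, band_widths = 12, amplitudes = 0.8)
stripe_spec <- function(channel_label, band_centers, band_widths, amplitudes,
                        background = 0.05) {
  check_string(channel_label, "channel_label")
  n <- length(band_centers)
  if (n < 1L) stop_field("band_centers", "needs at least one band")
  if (length(band_widths) != n)
    stop_field("band_widths", "must match length of band_centers")
  if (length(amplitudes) != n)
    stop_field("amplitudes", "must match length of band_centers")
  if (!all(is.finite(band_centers))) stop_field("band_centers", "must be finite")
  if (!all(is.finite(band_widths)) || any(band_widths <= 0))
    stop_field("band_widths", "must all be > 0")
  if (!all(is.finite(amplitudes)) || any(amplitudes < 0))
    stop_field("amplitudes", "must all be >= 0")
  check_scalar_number(background, "background", min = 0)
  structure(list(channel_label = channel_label,
                 band_centers = as.numeric(band_centers),
                 band_widths = as.numeric(band_widths),
                 amplitudes = as.numeric(amplitudes),
                 background = as.numeric(background)),
            class = "stripe_spec")
}

#' Synthetic scene configuration
#'
#' Bundles the geometry, noise model and replication settings for a
#' synthetic multi-channel image scene emulating confocal maximum
#' projections of stripe-shaped expression domains.
#'
#' @param channels List of [stripe_spec()] objects (unique labels).
#' @param image_height,image_width Image dimensions in pixels (>= 64).
#' @param n_z Number of z-slices per stack (same pattern, independent
#'   noise per slice).
#' @param stripe_axis_angle Orientation of the medial-lateral axis in the
#'   image plane, degrees; 0 means the axis runs along columns.
#' @param noise_sd Additive Gaussian noise sd (intensity units, >= 0);
#'   noisy pixels are truncated at 0.
#' @param replicate_jitter_sd Per-replicate rigid shift sd (pixels) applied
#'   to all band centres of all channels of that replicate.
#' @param n_replicates Number of replicate stacks (embryos).
#' @param seed Integer seed; identical seed gives bit-identical scenes.
#' @return A `scene_config` object.
#' @export
scene_config <- function(channels,
                         image_height = 128L, image_width = 256L, n_z = 3L,
                         stripe_axis_angle = 0, noise_sd = 0.02,
                         replicate_jitter_sd = 3, n_replicates = 5L,
                         seed = 1L) {
  if (!is.list(channels) || length(channels) == 0L ||
      !all(vapply(channels, inherits, logical(1), "stripe_spec")))
    stop_field("channels", "must be a non-empty list of stripe_spec objects")
  labels <- vapply(channels, `[[`, character(1), "channel_label")
  if (anyDuplicated(labels)) stop_field("channels", "channel labels must be unique")
  check_scalar_number(image_height, "image_height", min = 64, integer = TRUE)
  check_scalar_number(image_width, "image_width", min = 64, integer = TRUE)
  check_scalar_number(n_z, "n_z", min = 1, integer = TRUE)
  check_scalar_number(stripe_axis_angle, "stripe_axis_angle")
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(replicate_jitter_sd, "replicate_jitter_sd", min = 0)
  check_scalar_number(n_replicates, "n_replicates", min = 1, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_z = as.integer(n_z),
                 channels = channels,
                 stripe_axis_angle = as.numeric(stripe_axis_angle),
                 noise_sd = as.numeric(noise_sd),
                 replicate_jitter_sd = as.numeric(replicate_jitter_sd),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Named scene presets mirroring the early/late neurula geometries
#'
#' `"stage13"`: a query channel (`klf17`) broadly overlapping the reference
#' stripe (`pax3`) at the neural plate border. `"stage17"`: the query split
#' into two bands strictly outside the FWHM of a non-overlapping reference
#' stripe (`snai2`), i.e. medial and lateral domains flanking the neural
#' crest domain.
#'
#' @param name `"stage13"` or `"stage17"`.
#' @param ... Overrides passed to [scene_config()] (e.g. `seed`,
#'   `noise_sd`, `n_replicates`).
#' @return A `scene_config`.
#' @export
#' @examples
#' cfg <- scene_preset("stage17", seed = 11L)
scene_preset <- function(name = c("stage13", "stage17"), ...) {
  name <- match.arg(name)
  channels <- switch(name,
    stage13 = list(
      stripe_spec("pax3",  band_centers = 128, band_widths = 12,
                  amplitudes = 0.80, background = 0.05),
      stripe_spec("klf17", band_centers = 127, band_widths = 14,
                  amplitudes = 0.70, background = 0.05)),
    stage17 = list(
      stripe_spec("snai2", band_centers = 128, band_widths = 10,
                  amplitudes = 0.85, background = 0.05),
      # bands 38 px either side of the reference centre: well outside the
      # reference FWHM half-width of ~11.8 px
      stripe_spec("klf17", band_centers = c(90, 166), band_widths = c(9, 9),
                  amplitudes = c(0.70, 0.65), background = 0.05)))
  defaults <- list(channels = channels, image_height = 128L,
                   image_width = 256L, n_z = 3L, stripe_axis_angle = 0,
                   noise_sd = 0.02, replicate_jitter_sd = 3,
                   n_replicates = 5L, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_config, args)
}

#' Analytic expected intensity of a stripe channel
#'
#' Noiseless model value at signed axis distance `d`:
#' `background + sum_k amplitude_k * exp(-(d - center_k)^2 / (2 width_k^2))`.
#'
#' @param spec A [stripe_spec()].
#' @param d Numeric vector of signed distances along the stripe axis (px).
#' @param shift Rigid shift added to all band centres (replicate jitter).
#' @return Numeric vector of expected intensities.
#' @export
stripe_intensity <- function(spec, d, shift = 0) {
  v <- rep(spec$background, length(d))
  for (k in seq_along(spec$band_centers)) {
    ck <- spec$band_centers[k] + shift
    v <- v + spec$amplitudes[k] *
      exp(-(d - ck)^2 / (2 * spec$band_widths[k]^2))
  }
  v
}

# signed axis distance of every pixel; 0-based (row, col) coordinates
axis_distance_matrix <- function(height, width, angle_deg) {
  th <- angle_deg * pi / 180
  rows <- matrix(0:(height - 1), height, width)
  cols <- matrix(0:(width - 1), height, width, byrow = TRUE)
  cols * cos(th) + rows * sin(th)
}

# default measurement line: through the image centre along the stripe axis,
# clipped to the image bounds; returns 0-based endpoints
default_line_endpoints <- function(height, width, angle_deg) {
  th <- angle_deg * pi / 180
  u <- c(sin(th), cos(th))               # (d_row, d_col) per unit distance
  centre <- c((height - 1) / 2, (width - 1) / 2)
  tr <- if (abs(u[1]) > 1e-12) sort(c((0 - centre[1]) / u[1], (height - 1 - centre[1]) / u[1])) else c(-Inf, Inf)
  tc <- if (abs(u[2]) > 1e-12) sort(c((0 - centre[2]) / u[2], (width - 1 - centre[2]) / u[2])) else c(-Inf, Inf)
  t0 <- max(tr[1], tc[1]); t1 <- min(tr[2], tc[2])
  list(start = centre + t0 * u, end = centre + t1 * u)
}

#' Generate a seeded synthetic scene
#'
#' Renders `n_replicates` multi-channel, multi-z image stacks from a
#' [scene_config()], together with the ground truth actually realized:
#' per-replicate jittered band parameters and the default medial-to-lateral
#' measurement line for each replicate. Stripe cross-sections are Gaussian
#' along the axis coordinate and constant perpendicular to it; z-slices
#' share the pattern with independent additive Gaussian noise, truncated
#' at 0.
#'
#' @param config A valid [scene_config()].
#' @return A list with elements `stacks` (list of [image_stack()]s, one per
#'   replicate), `ground_truth` (list with `bands` and `lines` data frames;
#'   `lines$axis_offset` is the axis distance at the line's medial
#'   endpoint, so a band at centre c sits at profile position
#'   `c - axis_offset`), and `config`.
#' @export
#' @examples
#' sc <- generate_scene(scene_preset("stage13", n_replicates = 2L, n_z = 1L))
#' length(sc$stacks)
generate_scene <- function(config) {
  if (!inherits(config, "scene_config"))
    stop_field("config", "must be a scene_config object")
  H <- config$image_height; W <- config$image_width
  d <- axis_distance_matrix(H, W, config$stripe_axis_angle)
  ep <- default_line_endpoints(H, W, config$stripe_axis_angle)
  th <- config$stripe_axis_angle * pi / 180
  axis_offset <- ep$start[2] * cos(th) + ep$start[1] * sin(th)

  set.seed(config$seed)
  stacks <- vector("list", config$n_replicates)
  bands <- list(); lines <- list()
  for (i in seq_len(config$n_replicates)) {
    jitter <- rnorm(1, 0, config$replicate_jitter_sd)
    stack_id <- sprintf("rep%02d", i)
    channels <- vector("list", length(config$channels))
    for (ci in seq_along(config$channels)) {
      spec <- config$channels[[ci]]
      expected <- matrix(stripe_intensity(spec, as.vector(d), shift = jitter), H, W)
      arr <- array(0, dim = c(config$n_z, H, W))
      for (z in seq_len(config$n_z)) {
        slice <- if (config$noise_sd > 0)
          expected + matrix(rnorm(H * W, 0, config$noise_sd), H, W)
        else expected
        arr[z, , ] <- pmax(slice, 0)
      }
      channels[[ci]] <- arr
      bands[[length(bands) + 1L]] <- data.frame(
        replicate = i, stack_id = stack_id,
        channel = spec$channel_label,
        band = seq_along(spec$band_centers),
        center = spec$band_centers + jitter,
        width = spec$band_widths,
        amplitude = spec$amplitudes,
        background = spec$background,
        jitter = jitter)
    }
    labels <- vapply(config$channels, `[[`, character(1), "channel_label")
    names(channels) <- labels
    stacks[[i]] <- image_stack(channels, channel_labels = labels, id = stack_id)
    lines[[length(lines) + 1L]] <- data.frame(
      replicate = i, stack_id = stack_id, label = "ml_axis",
      start_row = ep$start[1], start_col = ep$start[2],
      end_row = ep$end[1], end_col = ep$end[2],
      linewidth = 1, medial_end = "start", axis_offset = axis_offset)
  }
  list(stacks = stacks,
       ground_truth = list(bands = do.call(rbind, bands),
                           lines = do.call(rbind, lines)),
       config = config)
}

#' Write a synthetic scene to disk
#'
#' One 32-bit float multi-page TIFF per replicate (pages ordered
#' channel-major: all z of channel 1, then channel 2, ...), each with a
#' JSON sidecar declaring the axis layout, plus `ground_truth.json` and a
#' `lines.csv` usable directly by [read_line_specs()].
#'
#' @param scene Result of [generate_scene()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a character vector of all files written.
#' @export
write_scene <- function(scene, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (stack in scene$stacks) {
    paths <- write_image_stack(stack, file.path(outdir, paste0(stack$id, ".tif")))
    written <- c(written, paths)
  }
  gt_path <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(scene$ground_truth, gt_path, dataframe = "columns",
                       digits = NA, pretty = TRUE)
  lines_path <- file.path(outdir, "lines.csv")
  ln <- scene$ground_truth$lines
  utils::write.csv(
    ln[, c("stack_id", "label", "start_row", "start_col", "end_row",
           "end_col", "linewidth", "medial_end")],
    lines_path, row.names = FALSE)
  invisible(c(written, gt_path, lines_path))
}
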