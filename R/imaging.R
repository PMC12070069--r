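#' Multi-channel, multi-z image stack
#'
#' The raw pixel container for the pipeline. Each channel is a 3-D array
#' in (z, row, column) order; all channels must share dimensions.
#' Coordinates are 0-based (row, column) throughout the package.
#'
#' @param channels Named list of 3-D numeric arrays (z, row, col), or a
#'   list plus a separate `channel_labels` vector.
#' @param channel_labels Channel names; defaults to `names(channels)`.
#' @param pixel_size Optional physical size of one pixel (micrometres).
#' @param id Stack identifier used in profile provenance.
#' @return An `image_stack` object.
#' @export
image_stack <- function(channels, channel_labels = names(channels),
                        pixel_size = NULL, id = "stack") {
  if (!is.list(channels) || length(channels) == 0L)
    stop_field("channels", "must be a non-empty list of 3-D arrays")
  if (is.null(channel_labels) || length(channel_labels) != length(channels))
    stop_field("channel_labels", "must name every channel")
  if (anyDuplicated(channel_labels))
    stop_field("channel_labels", "must be unique")
  dims <- lapply(channels, function(a) {
    if (!is.array(a) || length(dim(a)) != 3L)
      stop_field("channels", "each channel must be a 3-D (z, row, col) array")
    dim(a)
  })
  if (length(unique(lapply(dims, identity))) != 1L)
    stop_field("channels", "all channels must share (z, row, col) dimensions")
  names(channels) <- channel_labels
  structure(list(channels = channels,
                 channel_labels = as.character(channel_labels),
                 dim = dims[[1]], pixel_size = pixel_size, id = id),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack '%s'> %d channel(s) [%s], %d z x %d x %d px\n",
              x$id, length(x$channels),
              paste(x$channel_labels, collapse = ", "),
              x$dim[1], x$dim[2], x$dim[3]))
  invisible(x)
}

#' Write an image stack as float TIFF plus JSON sidecar
#'
#' Pages are ordered channel-major (all z of the first channel, then the
#' next); the sidecar records the axis order, dimensions and labels so the
#' file is self-describing.
#'
#' @param stack An [image_stack()]. Storage is unit-scaled: values outside
#'   \[0, 1\] are clipped on write (the detector-saturation analogue);
#'   in-memory stacks keep their model values.
#' @param path Output `.tif` path; the sidecar is written next to it with
#'   a `.json` extension.
#' @return Invisibly, `c(tiff_path, sidecar_path)`.
#' @export
write_image_stack <- function(stack, path) {
  pages <- list()
  for (ch in stack$channel_labels) {
    arr <- stack$channels[[ch]]
    for (z in seq_len(dim(arr)[1]))
      pages[[length(pages) + 1L]] <- pmin(pmax(arr[z, , ], 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(
    axes = "CZYX", page_order = "channel_major",
    n_channels = length(stack$channel_labels), n_z = stack$dim[1],
    height = stack$dim[2], width = stack$dim[3],
    channel_labels = stack$channel_labels,
    pixel_size_um = stack$pixel_size, id = stack$id),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(c(path, sidecar))
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path Path to the `.tif` file; its `.json` sidecar must sit next
#'   to it.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path) {
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(sidecar))
    stop_field("path", sprintf("sidecar JSON not found: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_z; nc <- meta$n_channels
  if (length(pages) != nz * nc)
    stop_field("path", sprintf("expected %d pages, found %d", nz * nc, length(pages)))
  channels <- vector("list", nc)
  for (ci in seq_len(nc)) {
    arr <- array(0, dim = c(nz, meta$height, meta$width))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[(ci - 1L) * nz + z]]
    channels[[ci]] <- arr
  }
  names(channels) <- meta$channel_labels
  image_stack(channels, channel_labels = meta$channel_labels,
              pixel_size = meta$pixel_size_um, id = meta$id %||% basename(path))
}

#' Maximum intensity projection over z
#'
#' Collapses each channel of a stack to a 2-D image whose every pixel is
#' the maximum over the z-slices at that (row, column). A single-slice
#' stack projects to an identical copy of the slice.
#'
#' @param stack An [image_stack()].
#' @return A `projection` object: per-channel 2-D matrices plus provenance.
#' @export
#' @examples
#' st <- image_stack(list(g = array(c(1, 5, 2, 0), dim = c(2, 1, 2))),
#'                   channel_labels = "g")
#' max_project(st)$pixels$g
max_project <- function(stack) {
  if (!inherits(stack, "image_stack")) stop_field("stack", "must be an image_stack")
  pixels <- lapply(stack$channels, function(arr) {
    out <- arr[1, , , drop = TRUE]
    if (!is.matrix(out)) out <- matrix(out, dim(arr)[2], dim(arr)[3])
    nz <- dim(arr)[1]
    if (nz > 1) for (z in 2:nz) out <- pmax(out, arr[z, , ])
    out
  })
  structure(list(pixels = pixels, channel_labels = stack$channel_labels,
                 provenance = stack$id, pixel_size = stack$pixel_size),
            class = "projection")
}

#' Line specification for profile extraction
#'
#' A user-defined measurement segment in 0-based (row, column) pixel
#' coordinates, with the medial endpoint flagged so every profile is
#' oriented medial to lateral regardless of how the endpoints were
#' supplied.
#'
#' @param start,end Numeric `(row, col)` pairs; must differ.
#' @param linewidth Perpendicular averaging width in pixels (>= 1).
#' @param label Line identifier.
#' @param medial_end `"start"` or `"end"`: which endpoint is medial.
#' @return A `line_spec` object.
#' @export
line_spec <- function(start, end, linewidth = 1L, label = "line",
                      medial_end = c("start", "end")) {
  medial_end <- match.arg(medial_end)
  if (length(start) != 2L || length(end) != 2L ||
      !all(is.finite(c(start, end))))
    stop_field("start/end", "must be finite (row, col) pairs")
  if (all(start == end)) stop_field("end", "must differ from start (zero-length line)")
  check_scalar_number(linewidth, "linewidth", min = 1)
  check_string(label, "label")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 linewidth = as.numeric(linewidth), label = label,
                 medial_end = medial_end),
            class = "line_spec")
}

#' Read line specifications from a delimited file
#'
#' Expected columns: `stack_id, label, start_row, start_col, end_row,
#' end_col, linewidth, medial_end`.
#'
#' @param path CSV path.
#' @return Named list (by `stack_id`) of lists of [line_spec()]s.
#' @export
read_line_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stack_id", "label", "start_row", "start_col", "end_row",
            "end_col", "linewidth", "medial_end")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_field("path", paste("missing columns:", paste(missing, collapse = ", ")))
  out <- list()
  for (i in seq_len(nrow(df))) {
    ls <- line_spec(c(df$start_row[i], df$start_col[i]),
                    c(df$end_row[i], df$end_col[i]),
                    linewidth = df$linewidth[i], label = df$label[i],
                    medial_end = df$medial_end[i])
    sid <- df$stack_id[i]
    out[[sid]] <- c(out[[sid]], list(ls))
  }
  out
}

# bilinear interpolation on a matrix at 0-based fractional (row, col);
# coordinates are clamped to the image border
bilinear_sample <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 0), H - 1)
  c <- pmin(pmax(c, 0), W - 1)
  r0 <- pmin(floor(r), max(H - 2, 0))
  c0 <- pmin(floor(c), max(W - 2, 0))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  i00 <- img[cbind(r0 + 1, c0 + 1)]; i01 <- img[cbind(r0 + 1, c1 + 1)]
  i10 <- img[cbind(r1 + 1, c0 + 1)]; i11 <- img[cbind(r1 + 1, c1 + 1)]
  (1 - fr) * (1 - fc) * i00 + (1 - fr) * fc * i01 +
    fr * (1 - fc) * i10 + fr * fc * i11
}

#' Extract an intensity line profile from a projection
#'
#' Samples every channel at unit spacing along the segment, oriented from
#' the medial endpoint (position 0) to the lateral endpoint. Each sample
#' is the mean of `linewidth` bilinear interpolations taken perpendicular
#' to the line; all channels are sampled at identical coordinates.
#'
#' @param projection A `projection` from [max_project()].
#' @param line A [line_spec()]; both endpoints must lie inside the image.
#' @return A `line_profile`: integer `positions` 0, 1, ... and a named
#'   list `intensities` with one numeric vector per channel.
#' @export
extract_profile <- function(projection, line) {
  if (!inherits(projection, "projection"))
    stop_field("projection", "must be a projection")
  if (!inherits(line, "line_spec")) stop_field("line", "must be a line_spec")
  H <- nrow(projection$pixels[[1]]); W <- ncol(projection$pixels[[1]])
  p0 <- line$start; p1 <- line$end
  if (line$medial_end == "end") { tmp <- p0; p0 <- p1; p1 <- tmp }
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > H - 1 || p[2] < 0 || p[2] > W - 1)
      stop_field("line", sprintf("endpoint (%g, %g) outside %d x %d image",
                                 p[1], p[2], H, W))
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop_field("line", "zero-length line")
  n_pos <- round(len)
  positions <- 0:n_pos
  u <- (p1 - p0) / len
  perp <- c(-u[2], u[1])
  k <- round(line$linewidth)
  offsets <- seq_len(k) - (k + 1) / 2
  rows <- outer(positions * u[1] + p0[1], offsets * perp[1], `+`)
  cols <- outer(positions * u[2] + p0[2], offsets * perp[2], `+`)
  intensities <- lapply(projection$pixels, function(img) {
    vals <- matrix(bilinear_sample(img, as.vector(rows), as.vector(cols)),
                   nrow = length(positions))
    rowMeans(vals)
  })
  structure(list(positions = positions, intensities = intensities,
                 source = list(stack_id = projection$provenance,
                               line_label = line$label)),
            class = "line_profile")
}

#' Normalize a line profile to the unit interval, per channel
#'
#' Subtracts each channel's minimum over the profile and divides by its
#' range, so every channel spans exactly \[0, 1\]. The (min, max) pair used
#' per channel is recorded in `norm_params` for auditability.
#'
#' @param profile A `line_profile` from [extract_profile()].
#' @return A `normalized_profile` with `values` in \[0, 1\] per channel.
#' @export
#' @examples
#' pr <- structure(list(positions = 0:2,
#'                      intensities = list(g = c(10, 30, 50)),
#'                      source = list(stack_id = "s", line_label = "l")),
#'                 class = "line_profile")
#' normalize_profile(pr)$values$g
normalize_profile <- function(profile) {
  if (!inherits(profile, "line_profile"))
    stop_field("profile", "must be a line_profile")
  norm_params <- list()
  values <- list()
  for (ch in names(profile$intensities)) {
    v <- profile$intensities[[ch]]
    lo <- min(v); hi <- max(v)
    if (hi <= lo)
      stop(sprintf("degenerate profile: channel `%s` is constant (min = max = %g); normalization undefined",
                   ch, lo), call. = FALSE)
    values[[ch]] <- (v - lo) / (hi - lo)
    norm_params[[ch]] <- c(min = lo, max = hi)
  }
  structure(list(positions = profile$positions, values = values,
                 norm_params = norm_params, source = profile$source),
            class = "normalized_profile")
}

#' Write normalized profiles as tidy CSV
#'
#' Long format with columns `stack_id, line_label, channel, position_px,
#' value`, one row per sample.
#'
#' @param profiles List of `normalized_profile` objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    do.call(rbind, lapply(names(p$values), function(ch)
      data.frame(stack_id = p$source$stack_id,
                 line_label = p$source$line_label,
                 channel = ch, position_px = p$positions,
                 value = p$values[[ch]])))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read profiles written by [write_profiles()]
#'
#' @param path CSV path.
#' @return List of `normalized_profile` objects (norm_params are not
#'   round-tripped; they document the original normalization).
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stack_id", "line_label", "channel", "position_px", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_field("path", paste("missing columns:", paste(missing, collapse = ", ")))
  out <- list()
  for (key in unique(paste(df$stack_id, df$line_label, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$stack_id == parts[1] & df$line_label == parts[2], ]
    channels <- unique(sub$channel)
    pos <- sort(unique(sub$position_px))
    values <- lapply(channels, function(ch) {
      s <- sub[sub$channel == ch, ]
      s$value[order(s$position_px)]
    })
    names(values) <- channels
    out[[length(out) + 1L]] <- structure(
      list(positions = pos, values = values, norm_params = NULL,
           source = list(stack_id = parts[1], line_label = parts[2])),
      class = "normalized_profile")
  }
  out
}
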