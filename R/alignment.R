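#' Fit a single peak to a profile
#'
#' Bounded least-squares fit of a Gaussian-form peak with baseline,
#' `v(x) = baseline + amplitude * exp(-(x - center)^2 / (2 width^2))`,
#' the functional form used to locate the reference-channel peak before
#' centering. The centre is constrained inside the sampled range.
#' Initialization is deterministic: baseline = min(values), amplitude =
#' range, centre = position of the first maximum, width = a quarter of the
#' sampled range. A quarter-range width start can leave the optimizer with
#' a numerically singular Jacobian when the true peak is much narrower
#' than the grid, so on failure the fit retries a fixed ladder of smaller
#' width starts (1/8, 1/16, 1/32 of the range, then 2 px) before falling
#' back to the argmax (smallest position wins ties) with
#' `converged = FALSE`.
#'
#' @param positions Ordered numeric positions (>= 5 samples).
#' @param values Intensities at `positions`, typically normalized \[0, 1\].
#' @param model Peak model; only `"gaussian"` is implemented and it is the
#'   default (kept as an argument so the functional-form choice stays
#'   visible in configs).
#' @return A `peak_fit` with `amplitude`, `center`, `width`, `baseline`,
#'   `rss` and `converged`.
#' @export
#' @examples
#' x <- 0:99
#' y <- 0.1 + 0.8 * exp(-(x - 37)^2 / (2 * 6^2))
#' fit_peak(x, y)$center
fit_peak <- function(positions, values, model = "gaussian") {
  if (!identical(model, "gaussian"))
    stop_field("model", "only the 'gaussian' peak model is implemented")
  if (length(positions) < 5L || length(values) != length(positions))
    stop_field("positions", "need at least 5 (position, value) samples")
  x <- as.numeric(positions); y <- as.numeric(values)
  b0 <- min(y); a0 <- max(y) - b0
  c0 <- x[which.max(y)]                     # which.max: first index = smallest position
  w0 <- diff(range(x)) / 4
  fallback <- function(conv) {
    pred <- b0 + a0 * exp(-(x - c0)^2 / (2 * w0^2))
    structure(list(amplitude = a0, center = c0, width = w0, baseline = b0,
                   rss = sum((y - pred)^2), converged = conv),
              class = "peak_fit")
  }
  if (a0 <= 0) return(fallback(FALSE))
  fit <- NULL
  for (w_start in unique(pmax(c(w0, w0 / 2, w0 / 4, w0 / 8, 2), 1e-3))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + a * exp(-(x - cc)^2 / (2 * w^2)),
        start = list(b = b0, a = a0, cc = c0, w = w_start),
        lower = c(b = -Inf, a = 0, cc = min(x), w = 1e-6),
        upper = c(b = Inf, a = Inf, cc = max(x), w = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fallback(FALSE))
  cf <- stats::coef(fit)
  structure(list(amplitude = unname(cf["a"]), center = unname(cf["cc"]),
                 width = unname(cf["w"]), baseline = unname(cf["b"]),
                 rss = sum(stats::residuals(fit)^2), converged = TRUE),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit> center %.3f, width %.3f, amplitude %.3f, baseline %.3f (rss %.3g, %s)\n",
              x$center, x$width, x$amplitude, x$baseline, x$rss,
              if (x$converged) "converged" else "fallback"))
  invisible(x)
}

# position-wise mean of the reference channel across one image's profiles,
# restricted to positions present in all of them
reference_average <- function(profiles, reference_channel) {
  pos <- Reduce(intersect, lapply(profiles, `[[`, "positions"))
  if (length(pos) == 0L)
    stop("profiles of one image share no positions; cannot average the reference channel",
         call. = FALSE)
  pos <- sort(pos)
  vals <- vapply(profiles, function(p) {
    idx <- match(pos, p$positions)
    p$values[[reference_channel]][idx]
  }, numeric(length(pos)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(pos))
  list(positions = pos, values = rowMeans(vals))
}

#' Centre replicate profiles on the reference channel's fitted peak
#'
#' For each image, the reference-channel values of that image's profiles
#' are averaged position-wise, a peak is fitted to the average with
#' [fit_peak()], and the fitted centre is subtracted from the positions of
#' every profile (all channels) of that image. In the default integer-grid
#' mode the centre is rounded to the nearest pixel first, so integer
#' positions stay integers and the grids intersect on a shared lattice;
#' with `subpixel = TRUE` the exact centre is subtracted and each profile
#' is re-interpolated onto the integer lattice. The common grid is the set
#' intersection of all shifted position sets.
#'
#' @param profiles List of `normalized_profile`s.
#' @param reference_channel Channel used for peak fitting and centering.
#' @param grouping Character vector, one image/embryo id per profile;
#'   defaults to each profile's source `stack_id`.
#' @param subpixel Logical; see above. Default `FALSE`.
#' @param peak_model Passed to [fit_peak()].
#' @return An `aligned_profile_set`: shifted `profiles`, per-profile
#'   `shifts`, per-image `fits`, `common_grid` and `reference_channel`.
#' @export
align_profiles <- function(profiles, reference_channel, grouping = NULL,
                           subpixel = FALSE, peak_model = "gaussian") {
  if (length(profiles) == 0L) stop_field("profiles", "empty input")
  check_string(reference_channel, "reference_channel")
  for (p in profiles)
    if (!reference_channel %in% names(p$values))
      stop_field("reference_channel",
                 sprintf("channel '%s' missing from profile %s/%s",
                         reference_channel, p$source$stack_id, p$source$line_label))
  if (is.null(grouping))
    grouping <- vapply(profiles, function(p) p$source$stack_id, character(1))
  if (length(grouping) != length(profiles))
    stop_field("grouping", "must map every profile to an image")

  shifted <- profiles
  shifts <- numeric(length(profiles))
  fits <- list()
  for (img in unique(grouping)) {
    idx <- which(grouping == img)
    ref <- reference_average(profiles[idx], reference_channel)
    fit <- fit_peak(ref$positions, ref$values, model = peak_model)
    fits[[img]] <- fit
    shift <- if (subpixel) fit$center else round(fit$center)
    for (i in idx) {
      shifted[[i]]$positions <- profiles[[i]]$positions - shift
      shifts[i] <- shift
    }
  }
  if (subpixel) {
    for (i in seq_along(shifted)) {
      pos <- shifted[[i]]$positions
      grid <- seq(ceiling(min(pos)), floor(max(pos)))
      shifted[[i]]$values <- lapply(shifted[[i]]$values, function(v)
        stats::approx(pos, v, xout = grid)$y)
      shifted[[i]]$positions <- grid
    }
  }
  common_grid <- sort(Reduce(intersect, lapply(shifted, `[[`, "positions")))
  structure(list(reference_channel = reference_channel, profiles = shifted,
                 shifts = shifts, fits = fits, grouping = grouping,
                 common_grid = common_grid),
            class = "aligned_profile_set")
}

#' Average aligned profiles into a mean +/- s.e.m. profile
#'
#' Per channel and common-grid point, the mean over all profiles and the
#' standard error of the mean (sample sd / sqrt(n)). Every profile covers
#' the common grid by construction, so n is constant across the grid.
#'
#' @param aligned An `aligned_profile_set` with >= 2 profiles.
#' @return An `average_profile`: `grid`, per-channel `mean` and `sem`
#'   matrices-as-lists, and `n`.
#' @export
average_profiles <- function(aligned) {
  if (!inherits(aligned, "aligned_profile_set"))
    stop_field("aligned", "must be an aligned_profile_set")
  if (length(aligned$profiles) < 2L)
    stop_field("aligned", "need at least 2 profiles to average")
  grid <- aligned$common_grid
  if (length(grid) == 0L)
    stop("empty common grid: replicate lines do not overlap after centering; use longer or retargeted lines",
         call. = FALSE)
  channels <- names(aligned$profiles[[1]]$values)
  n <- length(aligned$profiles)
  chans <- lapply(channels, function(ch) {
    m <- vapply(aligned$profiles, function(p) {
      p$values[[ch]][match(grid, p$positions)]
    }, numeric(length(grid)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(grid))
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    list(mean = mu, sem = sdv / sqrt(n))
  })
  names(chans) <- channels
  structure(list(grid = grid, channels = chans, n = n,
                 reference_channel = aligned$reference_channel),
            class = "average_profile")
}

#' @export
print.average_profile <- function(x, ...) {
  cat(sprintf("<average_profile> %d channel(s) on grid [%g, %g] (%d points), n = %d\n",
              length(x$channels), min(x$grid), max(x$grid),
              length(x$grid), x$n))
  invisible(x)
}

#' Write an average profile as tidy CSV
#'
#' Columns: `channel, position_px, mean, sem, n`.
#'
#' @param avg An `average_profile`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_average_profile <- function(avg, path) {
  rows <- do.call(rbind, lapply(names(avg$channels), function(ch)
    data.frame(channel = ch, position_px = avg$grid,
               mean = avg$channels[[ch]]$mean,
               sem = avg$channels[[ch]]$sem, n = avg$n)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read an average profile written by [write_average_profile()]
#'
#' @param path CSV path.
#' @param reference_channel Optional reference-channel name to record.
#' @return An `average_profile`.
#' @export
read_average_profile <- function(path, reference_channel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "position_px", "mean", "sem", "n")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_field("path", paste("missing columns:", paste(missing, collapse = ", ")))
  grid <- sort(unique(df$position_px))
  chans <- lapply(unique(df$channel), function(ch) {
    s <- df[df$channel == ch, ]
    s <- s[order(s$position_px), ]
    list(mean = s$mean, sem = s$sem)
  })
  names(chans) <- unique(df$channel)
  structure(list(grid = grid, channels = chans, n = df$n[1],
                 reference_channel = reference_channel),
            class = "average_profile")
}
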