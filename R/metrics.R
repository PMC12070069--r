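#' Full width at half maximum of the reference domain
#'
#' On the averaged, peak-centered profile, finds the maximal contiguous
#' interval containing 0 where the baseline-subtracted reference mean is at
#' least half its maximum. Interval endpoints are located by linear
#' interpolation between grid points; the baseline is the minimum of the
#' mean profile on the grid.
#'
#' @param avg An `average_profile` (reference peak centered near 0).
#' @param reference_channel Reference channel name.
#' @return Numeric `c(lo, hi)` in pixels around 0.
#' @export
reference_fwhm <- function(avg, reference_channel) {
  ch <- avg$channels[[reference_channel]]
  if (is.null(ch)) stop_field("reference_channel",
                              sprintf("channel '%s' not in average profile", reference_channel))
  g <- avg$grid; m <- ch$mean
  baseline <- min(m)
  peak <- max(m)
  if (peak <= baseline)
    stop("reference maximum is not above baseline; no peak to measure", call. = FALSE)
  half <- baseline + (peak - baseline) / 2
  above <- m >= half
  i0 <- which.min(abs(g))                 # grid point nearest the centre
  if (!above[i0])
    stop("no half-maximum interval containing 0; alignment contract violated", call. = FALSE)
  lo_i <- i0; while (lo_i > 1L && above[lo_i - 1L]) lo_i <- lo_i - 1L
  hi_i <- i0; while (hi_i < length(g) && above[hi_i + 1L]) hi_i <- hi_i + 1L
  lo <- if (lo_i == 1L) g[1] else {
    # crossing between lo_i - 1 (below) and lo_i (above)
    g[lo_i - 1L] + (half - m[lo_i - 1L]) / (m[lo_i] - m[lo_i - 1L]) *
      (g[lo_i] - g[lo_i - 1L])
  }
  hi <- if (hi_i == length(g)) g[length(g)] else {
    g[hi_i] + (half - m[hi_i]) / (m[hi_i + 1L] - m[hi_i]) *
      (g[hi_i + 1L] - g[hi_i])
  }
  c(lo = lo, hi = hi)
}

#' Detect query-channel modes on an average profile
#'
#' Local maxima of the query mean with prominence at least
#' `min_prominence`, ordered medial to lateral. The prominence of a peak
#' is its height above the lower of the two flanking minima (each minimum
#' taken between the peak and the nearest higher point or grid edge).
#'
#' @param avg An `average_profile`.
#' @param query_channel Query channel name.
#' @param min_prominence Minimum prominence in normalized units.
#' @return Numeric vector of mode positions (possibly empty).
#' @export
find_query_modes <- function(avg, query_channel, min_prominence = 0.1) {
  ch <- avg$channels[[query_channel]]
  if (is.null(ch)) stop_field("query_channel",
                              sprintf("channel '%s' not in average profile", query_channel))
  g <- avg$grid; m <- ch$mean
  n <- length(m)
  if (n < 3L) return(numeric(0))
  peaks <- which(m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n]) + 1L
  keep <- numeric(0)
  for (i in peaks) {
    j <- i; left_min <- m[i]
    while (j > 1L && m[j - 1L] <= m[i]) { j <- j - 1L; left_min <- min(left_min, m[j]) }
    j <- i; right_min <- m[i]
    while (j < n && m[j + 1L] <= m[i]) { j <- j + 1L; right_min <- min(right_min, m[j]) }
    prominence <- m[i] - min(left_min, right_min)
    if (prominence >= min_prominence) keep <- c(keep, g[i])
  }
  sort(keep)
}

#' Classify the spatial relation between query and reference domains
#'
#' Computes the reference FWHM interval, the query modes, and the overlap
#' coefficient -- the share of baseline-subtracted query signal mass lying
#' inside the reference FWHM -- then makes the categorical call:
#' `overlapping` if the coefficient is at least `t_hi`; `flanking` if it
#' is at most `t_lo` and at least two query modes lie on opposite sides of
#' 0 outside the FWHM; otherwise `partial`. This operationalizes the
#' overlapping-at-stage-13 versus flanking-at-stage-17 transition of
#' paired expression domains; the numeric thresholds are this package's
#' definition, always reported alongside the call.
#'
#' @param avg An `average_profile` centered on the reference peak.
#' @param reference_channel,query_channel Channel names.
#' @param t_hi,t_lo Overlap-coefficient thresholds, `0 < t_lo < t_hi < 1`.
#' @param min_prominence Passed to [find_query_modes()].
#' @return A `domain_relation` with fields `reference_fwhm`,
#'   `query_modes`, `peak_offsets`, `overlap_coefficient`, `call`,
#'   `thresholds_used`.
#' @export
classify_relation <- function(avg, reference_channel, query_channel,
                              t_hi = 0.5, t_lo = 0.2, min_prominence = 0.1) {
  if (!(t_lo > 0 && t_hi < 1 && t_lo < t_hi))
    stop_field("t_hi/t_lo", "need 0 < t_lo < t_hi < 1")
  fwhm <- reference_fwhm(avg, reference_channel)
  modes <- find_query_modes(avg, query_channel, min_prominence)
  q <- avg$channels[[query_channel]]$mean
  g <- avg$grid
  mass <- pmax(q - min(q), 0)
  total <- sum(mass)
  if (total <= 0)
    stop("query channel has no signal mass above baseline", call. = FALSE)
  inside <- g >= fwhm[["lo"]] & g <= fwhm[["hi"]]
  oc <- sum(mass[inside]) / total
  flanks <- any(modes < fwhm[["lo"]] & modes < 0) &&
    any(modes > fwhm[["hi"]] & modes > 0)
  call <- if (oc >= t_hi) "overlapping"
  else if (oc <= t_lo && flanks) "flanking"
  else "partial"
  structure(list(reference_channel = reference_channel,
                 query_channel = query_channel,
                 reference_fwhm = unname(fwhm),
                 query_modes = modes,
                 peak_offsets = modes,     # signed distance from the centered reference peak
                 overlap_coefficient = oc,
                 call = call,
                 thresholds_used = list(t_hi = t_hi, t_lo = t_lo),
                 min_prominence = min_prominence),
            class = "domain_relation")
}

#' @export
print.domain_relation <- function(x, ...) {
  cat(sprintf("<domain_relation> %s vs %s: %s (overlap %.3f, ref FWHM [%.1f, %.1f], %d query mode(s))\n",
              x$query_channel, x$reference_channel, x$call,
              x$overlap_coefficient, x$reference_fwhm[1], x$reference_fwhm[2],
              length(x$query_modes)))
  invisible(x)
}

#' Write a domain relation as JSON
#'
#' @param relation A `domain_relation`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_relation <- function(relation, path) {
  jsonlite::write_json(unclass(relation), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
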