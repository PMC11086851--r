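# Continuous-wavelet-transform peak detection (ricker wavelet + ridge lines),
# after Du, Kibbe & Lin (2006), Bioinformatics 22(17):2059-2065.  Peaks are
# relative maxima that persist across wavelet scales and pass an SNR filter.

#' Ricker (Mexican hat) wavelet
#'
#' @param points Number of points in the returned wavelet vector.
#' @param a Width (scale) parameter of the wavelet.
#' @return Numeric vector of length `points`, normalised so that the wavelet
#'   has unit energy scaling `2 / (sqrt(3 a) pi^(1/4))`.
#' @keywords internal
ricker_wavelet <- function(points, a) {
  vec <- seq_len(points) - 1 - (points - 1) / 2
  amp <- 2 / (sqrt(3 * a) * pi^0.25)
  amp * (1 - (vec / a)^2) * exp(-vec^2 / (2 * a^2))
}

# 'same'-mode linear convolution (centred, output length = length(x))
conv_same <- function(x, w) {
  n <- length(x)
  m <- length(w)
  full <- stats::convolve(x, rev(w), type = "open")
  start <- (m - 1L) %/% 2L
  full[(start + 1L):(start + n)]
}

# CWT matrix: one row per width, columns follow the signal
cwt_ricker <- function(x, widths) {
  n <- length(x)
  out <- matrix(0, nrow = length(widths), ncol = n)
  for (i in seq_along(widths)) {
    npts <- min(10 * widths[i], n)
    out[i, ] <- conv_same(x, ricker_wavelet(npts, widths[i]))
  }
  out
}

# strict relative maxima (order 1, edge-clipped: endpoints never qualify)
relative_maxima <- function(v) {
  n <- length(v)
  v > v[pmin(seq_len(n) + 1L, n)] & v > v[pmax(seq_len(n) - 1L, 1L)]
}

# Link per-row relative maxima into ridge lines, walking from the largest
# width down; a line tolerates up to gap_thresh consecutive rows without a
# connectable maximum within max_distances[row].
identify_ridge_lines <- function(cwt_mat, max_distances, gap_thresh) {
  n_rows <- nrow(cwt_mat)
  max_cols <- t(apply(cwt_mat, 1L, relative_maxima))
  if (n_rows == 1L) max_cols <- matrix(max_cols, nrow = 1L)
  has_relmax <- which(rowSums(max_cols) > 0)
  if (!length(has_relmax)) return(list())
  start_row <- max(has_relmax)
  # a ridge line: list(rows, cols, gap)
  ridge_lines <- lapply(which(max_cols[start_row, ]), function(col) {
    list(rows = start_row, cols = col, gap = 0L)
  })
  final_lines <- list()
  for (row in rev(seq_len(start_row - 1L))) {
    this_max_cols <- which(max_cols[row, ])
    for (i in seq_along(ridge_lines)) {
      ridge_lines[[i]]$gap <- ridge_lines[[i]]$gap + 1L
    }
    prev_ridge_cols <- vapply(
      ridge_lines, function(l) l$cols[length(l$cols)], numeric(1))
    for (col in this_max_cols) {
      line_idx <- NULL
      if (length(prev_ridge_cols)) {
        diffs <- abs(col - prev_ridge_cols)
        closest <- which.min(diffs)
        if (diffs[closest] <= max_distances[row]) line_idx <- closest
      }
      if (!is.null(line_idx)) {
        ridge_lines[[line_idx]]$rows <- c(ridge_lines[[line_idx]]$rows, row)
        ridge_lines[[line_idx]]$cols <- c(ridge_lines[[line_idx]]$cols, col)
        ridge_lines[[line_idx]]$gap <- 0L
      } else {
        ridge_lines[[length(ridge_lines) + 1L]] <-
          list(rows = row, cols = col, gap = 0L)
      }
    }
    keep <- vapply(ridge_lines, function(l) l$gap <= gap_thresh, logical(1))
    final_lines <- c(final_lines, ridge_lines[!keep])
    ridge_lines <- ridge_lines[keep]
  }
  lapply(c(final_lines, ridge_lines), function(l) {
    ord <- order(l$rows)
    list(rows = l$rows[ord], cols = l$cols[ord])
  })
}

# Keep ridge lines that are long enough and whose smallest-scale CWT value
# clears min_snr times the local noise floor (noise_perc-th percentile of
# the smallest-scale row within a window around the line's position).
filter_ridge_lines <- function(cwt_mat, ridge_lines, window_size = NULL,
                               min_length = NULL, min_snr = 1,
                               noise_perc = 10) {
  num_points <- ncol(cwt_mat)
  if (is.null(min_length)) min_length <- ceiling(nrow(cwt_mat) / 4)
  if (is.null(window_size)) window_size <- ceiling(num_points / 20)
  hf <- window_size %/% 2L
  odd <- window_size %% 2L
  row_one <- cwt_mat[1L, ]
  noises <- vapply(seq_len(num_points), function(i) {
    lo <- max(i - hf, 1L)
    hi <- min(i + hf + odd - 1L, num_points)
    stats::quantile(row_one[lo:hi], probs = noise_perc / 100,
                    names = FALSE, type = 7)
  }, numeric(1))
  Filter(function(line) {
    if (length(line$rows) < min_length) return(FALSE)
    col0 <- line$cols[1L]
    snr <- abs(cwt_mat[line$rows[1L], col0] / noises[col0])
    is.finite(snr) && snr >= min_snr
  }, ridge_lines)
}

#' Wavelet-based peak detection in a 1-D signal
#'
#' Finds peaks by convolving the signal with ricker wavelets over a range of
#' widths, linking relative maxima of the wavelet transform into ridge lines
#' across scales, and keeping ridges that span at least a quarter of the
#' scales with sufficient signal-to-noise ratio.
#'
#' @param x Numeric signal vector.
#' @param widths Integer vector of wavelet widths (in samples) covering the
#'   expected peak widths.
#' @param gap_thresh Maximum number of scale rows a ridge line may skip
#'   without a connectable maximum (default `ceiling(widths[1])`).
#' @param max_distances Per-scale maximum column distance for connecting
#'   maxima across rows (default `widths / 4`).
#' @param min_length Minimum ridge-line length in scales (default a quarter
#'   of `length(widths)`).
#' @param min_snr Minimum signal-to-noise ratio (default 1).
#' @param noise_perc Percentile of the smallest-scale transform used as the
#'   noise floor (default 10).
#' @param window_size Window (samples) for the local noise floor (default
#'   `ceiling(length(x) / 20)`).
#' @return Sorted integer vector of peak indices (1-based).
#' @export
find_peaks_cwt <- function(x, widths, gap_thresh = NULL,
                           max_distances = NULL, min_length = NULL,
                           min_snr = 1, noise_perc = 10,
                           window_size = NULL) {
  widths <- as.numeric(widths)
  if (!length(widths) || any(widths <= 0)) {
    stop("widths must be positive", call. = FALSE)
  }
  if (is.null(gap_thresh)) gap_thresh <- ceiling(widths[1L])
  if (is.null(max_distances)) max_distances <- widths / 4
  cwt_mat <- cwt_ricker(as.numeric(x), widths)
  ridge_lines <- identify_ridge_lines(cwt_mat, max_distances, gap_thresh)
  filtered <- filter_ridge_lines(cwt_mat, ridge_lines,
                                 window_size = window_size,
                                 min_length = min_length,
                                 min_snr = min_snr, noise_perc = noise_perc)
  sort(vapply(filtered, function(l) l$cols[1L], numeric(1)))
}
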