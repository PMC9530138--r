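# Preprocessing: raw 8-channel traces -> the 1 x 2 x 4 x T model input.
#
# Each channel is min-max normalized and Savitzky-Golay smoothed, resampled
# onto a fixed time grid, and the eight channels are arranged on a 2 x 4
# spatial grid: row 1 holds the horizontal gauges of sites S1..S4, row 2 the
# vertical gauges, so neighbouring cells are physically adjacent sensors.

#' Preprocessing configuration
#'
#' @param savgol_window odd filter window in samples (default 15, i.e. 50 ms
#'   at 300 Hz: long enough to suppress sensor noise, short against the
#'   ~100 ms articulation bumps).
#' @param savgol_polyorder polynomial order of the filter (default 3).
#' @param normalize_first if `TRUE` (default) normalize before smoothing and
#'   clip the smoothed trace back into `[0, 1]`; if `FALSE` smooth first, then
#'   normalize (range is then exact without clipping).
#' @param out_len number of samples of the output grid (default 600).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(savgol_window = 15L,
                              savgol_polyorder = 3L,
                              normalize_first = TRUE,
                              out_len = 600L) {
  savgol_window <- as.integer(savgol_window)
  savgol_polyorder <- as.integer(savgol_polyorder)
  if (savgol_window %% 2L == 0L) stop("savgol_window must be odd", call. = FALSE)
  if (savgol_polyorder >= savgol_window) {
    stop("savgol_polyorder must be < savgol_window", call. = FALSE)
  }
  if (out_len < 2L) stop("out_len must be >= 2", call. = FALSE)
  structure(
    list(savgol_window = savgol_window, savgol_polyorder = savgol_polyorder,
         normalize_first = isTRUE(normalize_first), out_len = as.integer(out_len)),
    class = "preprocess_config"
  )
}

#' Min-max normalize a trace to [0, 1]
#'
#' `(x - min) / (max - min)`. A constant trace maps to all zeros (the 0/0 case
#' is defined away; such records are degenerate and flagged upstream).
#'
#' @param trace numeric vector, finite, length >= 1.
#' @return normalized trace of the same length.
#' @export
minmax_normalize <- function(trace) {
  if (!is.numeric(trace) || length(trace) < 1L) {
    stop("trace must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(trace))) stop("trace contains non-finite values", call. = FALSE)
  rng <- range(trace)
  if (rng[1] == rng[2]) return(rep(0, length(trace)))
  (trace - rng[1]) / (rng[2] - rng[1])
}

# Central Savitzky-Golay smoothing weights for one (window, polyorder).
savgol_weights <- function(window, polyorder) {
  proj <- signal::sgolay(p = polyorder, n = window)
  as.numeric(proj[(window + 1L) %/% 2L, ])
}

#' Savitzky-Golay smoothing
#'
#' Replaces each sample by the value at its position of the least-squares
#' polynomial of degree `polyorder` fitted over the centered window. Edges are
#' handled by mirror padding (reflection without repeating the end sample), so
#' the filter reduces to a single convolution with the central weights.
#'
#' @param trace numeric vector, length >= `window`.
#' @param window odd window length in samples.
#' @param polyorder polynomial degree, `< window`.
#' @return smoothed trace, same length as the input.
#' @export
savgol_smooth <- function(trace, window = 15L, polyorder = 3L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (!is.numeric(trace) || any(!is.finite(trace))) {
    stop("trace must be finite numeric", call. = FALSE)
  }
  n <- length(trace)
  if (n < window) stop("trace shorter than the filter window", call. = FALSE)
  h <- (window - 1L) %/% 2L
  w <- savgol_weights(window, polyorder)
  padded <- c(rev(trace[2:(h + 1L)]), trace, rev(trace[(n - h):(n - 1L)]))
  sm <- stats::filter(padded, w, method = "convolution", sides = 2)
  as.numeric(sm[(h + 1L):(h + n)])
}

#' Resample a trace onto a fixed uniform grid
#'
#' Linear interpolation onto `out_len` points at times
#' `(j-1) * out_duration / out_len`, matching the acquisition convention where
#' sample j is taken at `(j-1)/rate`. An input already on the target grid is
#' returned unchanged.
#'
#' @param trace numeric vector, length >= 2.
#' @param in_rate input sampling rate in Hz.
#' @param out_len number of output samples (>= 2).
#' @param out_duration duration in seconds spanned by the output grid.
#' @return resampled trace of length `out_len`.
#' @export
to_fixed_grid <- function(trace, in_rate, out_len, out_duration) {
  if (length(trace) < 2L) stop("trace must have at least 2 samples", call. = FALSE)
  if (in_rate <= 0) stop("in_rate must be > 0", call. = FALSE)
  if (out_len < 2L) stop("out_len must be >= 2", call. = FALSE)
  t_in <- (seq_along(trace) - 1) / in_rate
  t_out <- (seq_len(out_len) - 1) * out_duration / out_len
  stats::approx(t_in, trace, xout = t_out, rule = 2)$y
}

#' Arrange eight preprocessed channels as a 1 x 2 x 4 x T tensor
#'
#' Row 1 (`H` index 1) holds the horizontal gauges of sites S1..S4 in columns
#' 1..4; row 2 holds the vertical gauges in the same site order. With channels
#' numbered so that site s carries channels `2s-1` (horizontal) and `2s`
#' (vertical), channel c maps to row `2 - (c %% 2)` and column `ceiling(c/2)`.
#'
#' @param channels an 8 x T numeric matrix (one row per channel).
#' @param label optional class id stored on the tensor.
#' @return an object of class `signal_tensor` with fields `values`
#'   (array `1 x 2 x 4 x T`), `channel_map` (data frame channel/row/col) and
#'   `label`.
#' @export
assemble_tensor <- function(channels, label = NULL) {
  if (!is.matrix(channels) || nrow(channels) != 8L) {
    stop("channels must be an 8 x T matrix", call. = FALSE)
  }
  if (any(!is.finite(channels))) stop("channels contain non-finite values", call. = FALSE)
  t_len <- ncol(channels)
  if (t_len < 1L) stop("channels must have at least one sample", call. = FALSE)
  values <- array(0, dim = c(1L, 2L, 4L, t_len))
  map <- data.frame(channel = 1:8,
                    row = ifelse(1:8 %% 2L == 1L, 1L, 2L),
                    col = (1:8 + 1L) %/% 2L)
  for (c in 1:8) {
    values[1, map$row[c], map$col[c], ] <- channels[c, ]
  }
  structure(list(values = values, channel_map = map,
                 label = if (is.null(label)) NULL else as.integer(label)),
            class = "signal_tensor")
}

#' Recover the 8 x T channel matrix from a tensor
#'
#' Inverse of [assemble_tensor()]: reads each channel back from its grid cell
#' using the stored channel map.
#'
#' @param tensor a `signal_tensor`.
#' @return an 8 x T matrix.
#' @export
tensor_to_channels <- function(tensor) {
  stopifnot(inherits(tensor, "signal_tensor"))
  t_len <- dim(tensor$values)[4]
  out <- matrix(0, nrow = 8L, ncol = t_len)
  map <- tensor$channel_map
  for (i in seq_len(nrow(map))) {
    out[map$channel[i], ] <- tensor$values[1, map$row[i], map$col[i], ]
  }
  out
}

#' Preprocess one record into a model-ready tensor
#'
#' Per channel: min-max normalize, Savitzky-Golay smooth (clipping back into
#' `[0, 1]`; the clipped fraction is recorded), resample to the output grid,
#' then assemble the 2 x 4 spatial layout. With
#' `normalize_first = FALSE` the smoothing runs before normalization and no
#' clipping is needed.
#'
#' @param record a `strain_record`.
#' @param config a [preprocess_config()].
#' @param sampling_rate input sampling rate in Hz (default 300).
#' @return a `signal_tensor` with the record's class id as label and an
#'   attribute `clip_fraction` (fraction of samples clipped into range).
#' @export
preprocess_record <- function(record, config = preprocess_config(),
                              sampling_rate = 300) {
  stopifnot(inherits(record, "strain_record"), inherits(config, "preprocess_config"))
  w <- record$waveform
  t_in <- ncol(w)
  duration <- t_in / sampling_rate
  out <- matrix(0, nrow = 8L, ncol = config$out_len)
  clipped <- 0L
  for (c in 1:8) {
    x <- w[c, ]
    if (config$normalize_first) {
      x <- minmax_normalize(x)
      x <- savgol_smooth(x, config$savgol_window, config$savgol_polyorder)
      n_out_of_range <- sum(x < 0 | x > 1)
      if (n_out_of_range > 0L) {
        clipped <- clipped + n_out_of_range
        x <- pmin(pmax(x, 0), 1)
      }
    } else {
      x <- savgol_smooth(x, config$savgol_window, config$savgol_polyorder)
      x <- minmax_normalize(x)
    }
    out[c, ] <- to_fixed_grid(x, sampling_rate, config$out_len, duration)
  }
  tensor <- assemble_tensor(out, label = record$class_id)
  attr(tensor, "clip_fraction") <- clipped / (8 * t_in)
  tensor
}

#' Preprocess a list of records
#'
#' @param records list of `strain_record` objects.
#' @param config a [preprocess_config()].
#' @param sampling_rate input sampling rate in Hz.
#' @return list of `signal_tensor` objects.
#' @export
preprocess_dataset <- function(records, config = preprocess_config(),
                               sampling_rate = 300) {
  lapply(records, preprocess_record, config = config,
         sampling_rate = sampling_rate)
}

# Flatten a tensor to a feature vector (used by the correlation and SVM
# baselines).
tensor_features <- function(tensor) as.numeric(tensor$values)

tensor_labels <- function(tensors) {
  vapply(tensors, function(x) as.integer(x$label), integer(1))
}
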