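#' Butterworth IIR design (bilinear transform)
#'
#' Designs digital Butterworth low- or high-pass coefficients from the
#' analog prototype via frequency pre-warping and the bilinear transform.
#' Used because no DSP package is assumed; validated against the standard
#' SciPy designs during development.
#'
#' @param order filter order (>= 1).
#' @param cutoff cutoff frequency, Hz (0 < cutoff < fs/2).
#' @param fs sampling rate, Hz.
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, cutoff > 0)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency fs/2")
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * cutoff / fs)  # pre-warped cutoff (rad/s)
  if (type == "low") {
    pa <- wc * p
    za <- complex(0)
  } else {
    pa <- wc / p
    za <- rep(0 + 0i, order)
  }
  # bilinear transform s -> 2 fs (z-1)/(z+1)
  pz <- (2 * fs + pa) / (2 * fs - pa)
  zz <- c((2 * fs + za) / (2 * fs - za), rep(-1 + 0i, order - length(za)))
  poly_from_roots <- function(r) {
    cf <- 1 + 0i
    for (ri in r) cf <- c(cf, 0) - c(0, cf) * ri
    cf
  }
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(zz))
  ref <- if (type == "low") 1 + 0i else -1 + 0i  # unit gain at DC / Nyquist
  h <- sum(b * ref^(0:(length(b) - 1))) / sum(a * ref^(0:(length(a) - 1)))
  list(b = b / Re(h), a = a)
}

# direct-form-II-transposed IIR filter with optional initial state
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) for (k in 1:(n - 2)) z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# steady-state filter state for a unit step input (removes the start-up
# transient when scaled by the first sample)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n < 2) return(numeric(0))
  # companion matrix of a
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[2:n]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[2:n] - b[1] * a[2:n]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forward and backward with odd reflection padding so
#' that peaks are not shifted in time (attribution timing depends on this).
#'
#' @param b,a coefficients from [butter_design()].
#' @param x signal.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_bw <- function(b, a, x) {
  padlen <- 3 * max(length(a), length(b))
  if (length(x) <= padlen) {
    stop(sprintf("signal too short for zero-phase filtering: need > %d samples", padlen))
  }
  # odd extension at both ends + steady-state initial conditions
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  xe <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xe, zi * xe[1])
  y <- rev(y)
  y <- rev(iir_filter(b, a, y, zi * y[1]))
  y[(padlen + 1):(padlen + length(x))]
}

#' Low-pass denoising
#'
#' Zero-phase Butterworth low-pass applied to the raw signal before phasic
#' extraction. Defaults: order 4, 1 Hz cutoff at the 4 Hz device rate.
#'
#' @param signal numeric series.
#' @param sampling_rate Hz.
#' @param cutoff Hz, must be below Nyquist.
#' @param order filter order.
#' @return denoised series of equal length.
#' @export
lowpass_denoise <- function(signal, sampling_rate, cutoff = 1, order = 4) {
  d <- butter_design(order, cutoff, sampling_rate, "low")
  filtfilt_bw(d$b, d$a, signal)
}

#' Phasic extraction: first-order 0.05 Hz high-pass
#'
#' Removes the tonic level and slow drift of skin conductance, leaving the
#' phasic component. First-order Butterworth high-pass at 0.05 Hz, applied
#' zero-phase.
#'
#' @inheritParams lowpass_denoise
#' @export
highpass_phasic <- function(signal, sampling_rate, cutoff = 0.05, order = 1) {
  d <- butter_design(order, cutoff, sampling_rate, "high")
  filtfilt_bw(d$b, d$a, signal)
}

#' Skin-temperature band filter
#'
#' The temperature channel is filtered with the same first-order 0.05 Hz
#' high-pass as the phasic EDA extraction by default; the band is
#' configurable since only slow slope changes carry stress information.
#'
#' @inheritParams lowpass_denoise
#' @export
filter_st <- function(signal, sampling_rate, cutoff = 0.05, order = 1) {
  highpass_phasic(signal, sampling_rate, cutoff = cutoff, order = order)
}

#' Downsample with anti-aliasing
#'
#' Zero-phase low-pass at 80% of the target Nyquist, then decimation by the
#' integer rate ratio. Output length is `floor(n * to_rate / from_rate)`.
#'
#' @param signal numeric series.
#' @param from_rate,to_rate Hz; `from_rate` must be an integer multiple of
#'   `to_rate`.
#' @export
downsample <- function(signal, from_rate, to_rate) {
  if (from_rate %% to_rate != 0) stop("from_rate must be an integer multiple of to_rate")
  k <- from_rate / to_rate
  if (k == 1) return(signal)
  y <- lowpass_denoise(signal, from_rate, cutoff = 0.8 * to_rate / 2, order = 4)
  n_out <- floor(length(signal) / k)
  y[seq.int(1, by = k, length.out = n_out)]
}

#' Standardize a series to mean 0, sd 1
#'
#' Uses the population standard deviation (divide by N). A constant input
#' returns all zeros with a warning (degenerate guard).
#'
#' @param signal numeric series, length >= 2.
#' @export
standardize <- function(signal) {
  if (length(signal) < 2) stop("standardize needs at least 2 samples")
  mu <- mean(signal)
  sd_pop <- sqrt(mean((signal - mu)^2))
  if (sd_pop < 1e-12) {
    warning("constant signal: standardization returns all zeros")
    return(numeric(length(signal)))
  }
  (signal - mu) / sd_pop
}

#' Full preprocessing chain for one recording
#'
#' low-pass denoise -> 0.05 Hz high-pass (EDA phasic / ST band) ->
#' downsample to 1 Hz -> standardize per channel over the full session.
#'
#' @param rec a `recording`.
#' @param to_rate target rate, Hz (default 1).
#' @param lp_cutoff,lp_order denoising low-pass parameters.
#' @param hp_cutoff phasic high-pass cutoff, Hz.
#' @param channels `"eda"` or `c("eda","st")` (used later for the ablation).
#' @return A `filtered_recording` with standardized 1 Hz channels.
#' @export
preprocess_recording <- function(rec, to_rate = 1, lp_cutoff = 1, lp_order = 4,
                                 hp_cutoff = 0.05, channels = c("eda", "st")) {
  stopifnot(inherits(rec, "recording"))
  sr <- rec$sampling_rate
  chain <- function(x, hp_fun) {
    x <- lowpass_denoise(x, sr, cutoff = lp_cutoff, order = lp_order)
    x <- hp_fun(x, sr)
    x <- downsample(x, sr, to_rate)
    standardize(x)
  }
  out <- list(subject_id = rec$subject_id, sampling_rate = to_rate,
              protocol = rec$protocol, channels = channels)
  out$phasic_eda <- chain(rec$eda, function(x, s) highpass_phasic(x, s, cutoff = hp_cutoff))
  if ("st" %in% channels) {
    out$st_filtered <- chain(rec$st, function(x, s) filter_st(x, s, cutoff = hp_cutoff))
  }
  structure(out, class = "filtered_recording")
}

#' Label one analysis window
#'
#' Default rule: a window is a stress window iff its start second lies in
#' `[t - pre_s, t + post_s]` for some reference stressor `t`, mirroring the
#' asymmetric event-evaluation window.
#'
#' @param window_start_s window start, seconds.
#' @param protocol a `stimulus_protocol`.
#' @param pre_s,post_s labeling interval around each stressor, seconds.
#' @return integer 0/1.
#' @export
label_window <- function(window_start_s, protocol, pre_s = 2, post_s = 6) {
  tt <- protocol$stressor_times
  as.integer(any(window_start_s >= tt - pre_s & window_start_s <= tt + post_s))
}

#' Cut a filtered recording into fixed-length windows
#'
#' @param frec a `filtered_recording` at 1 Hz.
#' @param window_s window length, seconds (16 by default).
#' @param stride_s window stride, seconds.
#' @param pre_s,post_s labeling rule, see [label_window()].
#' @return A `windowed_dataset`: `windows` (n x window_s x n_channels array),
#'   `labels`, `window_start_s`, `subject_ids`, `synthetic` flags,
#'   `channels`.
#' @export
make_windows <- function(frec, window_s = 16, stride_s = 1,
                         pre_s = 2, post_s = 6) {
  stopifnot(inherits(frec, "filtered_recording"), stride_s >= 1)
  sr <- frec$sampling_rate
  chans <- list(frec$phasic_eda)
  ch_names <- "eda"
  if (!is.null(frec$st_filtered)) {
    chans <- c(chans, list(frec$st_filtered))
    ch_names <- c(ch_names, "st")
  }
  n <- length(chans[[1]])
  wlen <- window_s * sr
  if (n < wlen) stop("recording shorter than one window")
  starts <- seq.int(0, (n - wlen) / sr, by = stride_s)
  nw <- length(starts)
  W <- array(0, dim = c(nw, wlen, length(chans)))
  for (ci in seq_along(chans)) {
    x <- chans[[ci]]
    for (wi in seq_len(nw)) {
      i0 <- starts[wi] * sr + 1
      W[wi, , ci] <- x[i0:(i0 + wlen - 1)]
    }
  }
  labs <- vapply(starts, label_window, integer(1), protocol = frec$protocol,
                 pre_s = pre_s, post_s = post_s)
  structure(list(windows = W, labels = labs, window_start_s = starts,
                 subject_ids = rep(frec$subject_id, nw),
                 synthetic = rep(FALSE, nw), channels = ch_names),
            class = "windowed_dataset")
}

#' Preprocess and window a whole cohort
#' @param cohort a `cohort`.
#' @inheritParams preprocess_recording
#' @inheritParams make_windows
#' @return a combined `windowed_dataset`; filtered recordings are attached
#'   as attribute `"filtered"` for event-level prediction.
#' @export
window_cohort <- function(cohort, channels = c("eda", "st"),
                          window_s = 16, stride_s = 1) {
  frecs <- lapply(cohort$recordings, preprocess_recording, channels = channels)
  wds <- lapply(frecs, make_windows, window_s = window_s, stride_s = stride_s)
  out <- do.call(wd_bind, wds)
  attr(out, "filtered") <- frecs
  out
}

#' Combine windowed datasets
#' @param ... `windowed_dataset` objects with identical window shape.
#' @export
wd_bind <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1)
  W <- do.call(abind_1, lapply(ds, `[[`, "windows"))
  structure(list(windows = W,
                 labels = unlist(lapply(ds, `[[`, "labels")),
                 window_start_s = unlist(lapply(ds, `[[`, "window_start_s")),
                 subject_ids = unlist(lapply(ds, `[[`, "subject_ids")),
                 synthetic = unlist(lapply(ds, `[[`, "synthetic")),
                 channels = ds[[1]]$channels),
            class = "windowed_dataset")
}

# bind 3-d arrays along the first margin
abind_1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], numeric(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Subset a windowed dataset
#' @param wd a `windowed_dataset`.
#' @param idx integer or logical index over windows.
#' @export
wd_subset <- function(wd, idx) {
  structure(list(windows = wd$windows[idx, , , drop = FALSE],
                 labels = wd$labels[idx],
                 window_start_s = wd$window_start_s[idx],
                 subject_ids = wd$subject_ids[idx],
                 synthetic = wd$synthetic[idx],
                 channels = wd$channels),
            class = "windowed_dataset")
}

#' Write / read a windowed dataset as a wide CSV
#'
#' One row per window: `subject_id`, `window_start_s`, `label`, `synthetic`,
#' then one column per (time step, channel), e.g. `t01_eda ... t16_st`.
#'
#' @param wd a `windowed_dataset`.
#' @param path CSV file path.
#' @export
write_windows_csv <- function(wd, path) {
  d <- dim(wd$windows)
  flat <- matrix(aperm(wd$windows, c(1, 2, 3)), d[1], d[2] * d[3])
  colnames(flat) <- as.vector(outer(sprintf("t%02d", seq_len(d[2])),
                                    wd$channels, paste, sep = "_"))
  df <- data.frame(subject_id = wd$subject_ids,
                   window_start_s = wd$window_start_s,
                   label = wd$labels, synthetic = wd$synthetic, flat,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("subject_id", "window_start_s", "label", "synthetic")
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  chans <- unique(sub("^t[0-9]+_", "", colnames(vals)))
  Tn <- length(grep(paste0("_", chans[1], "$"), colnames(vals)))
  W <- array(vals, dim = c(nrow(df), Tn, length(chans)))
  structure(list(windows = W, labels = as.integer(df$label),
                 window_start_s = df$window_start_s,
                 subject_ids = df$subject_id,
                 synthetic = as.logical(df$synthetic), channels = chans),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows of %d s x %d channel(s), %d positive (%.1f%%)\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              sum(x$labels), 100 * mean(x$labels)))
  invisible(x)
}
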