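#' Integrated Gradients attribution for one window
#'
#' Attribution along the straight-line path from a baseline input (the zero
#' vector in standardized space by default) to the window:
#' \deqn{IG_j = (x_j - b_j) \cdot \frac{1}{m}\sum_{k=1}^{m}
#'   \left.\frac{\partial F}{\partial x_j}\right|_{b + \frac{k}{m}(x - b)}}
#' (right Riemann sum). `F` is the model's stress probability. For a
#' `dge_ensemble`, the attribution is the mean of the member attributions,
#' which equals the attribution of the averaged-probability ensemble.
#' The completeness gap `|sum(IG) - (F(x) - F(baseline))|` is recorded and
#' shrinks as `n_steps` grows.
#'
#' @param model a `trained_classifier` or `dge_ensemble`.
#' @param window matrix (T x channels).
#' @param baseline same shape as `window`; default zero vector.
#' @param n_steps Riemann steps (>= 1), default 128.
#' @return An `attribution_map`: `values` (T x channels, signed),
#'   `baseline_type`, `n_steps`, `completeness_gap`, `f_x`, `f_baseline`.
#' @export
integrated_gradients <- function(model, window, baseline = NULL, n_steps = 128) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (inherits(window, "windowed_dataset")) window <- window$windows[1, , ]
  window <- as.matrix(window)
  if (is.null(baseline)) baseline <- window * 0
  stopifnot(all(dim(baseline) == dim(window)))
  if (inherits(model, "dge_ensemble")) {
    maps <- lapply(model$members, function(m)
      integrated_gradients(m$classifier, window, baseline, n_steps))
    vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
    f_x <- mean(vapply(maps, `[[`, 0, "f_x"))
    f_b <- mean(vapply(maps, `[[`, 0, "f_baseline"))
    return(structure(list(values = vals, baseline_type = maps[[1]]$baseline_type,
                          n_steps = n_steps,
                          completeness_gap = abs(sum(vals) - (f_x - f_b)),
                          f_x = f_x, f_baseline = f_b),
                     class = "attribution_map"))
  }
  Tn <- nrow(window); d <- ncol(window)
  diff <- window - baseline
  # batch of m path points: baseline + (k/m)(x - b), k = 1..m
  P <- array(0, dim = c(n_steps, Tn, d))
  for (k in seq_len(n_steps)) P[k, , ] <- baseline + (k / n_steps) * diff
  vg <- model_value_grad(model, P)
  avg_grad <- apply(vg$dX, c(2, 3), mean)
  vals <- diff * avg_grad
  ends <- abind_1(array(window, c(1, Tn, d)), array(baseline, c(1, Tn, d)))
  f_ends <- model_value_grad(model, ends)$f
  f_x <- f_ends[1]
  f_b <- f_ends[2]
  structure(list(values = vals,
                 baseline_type = if (all(baseline == 0)) "zero" else "custom",
                 n_steps = n_steps,
                 completeness_gap = abs(sum(vals) - (f_x - f_b)),
                 f_x = f_x, f_baseline = f_b),
            class = "attribution_map")
}

#' Differentiable-model interface used by Integrated Gradients
#'
#' Returns the model output F and its input gradient for a batch of
#' windows. Methods exist for `trained_classifier` (F = stress probability,
#' gradients by backprop-through-time) and for [linear_model()]
#' (F = sum(w * x) + b, the closed-form oracle used in tests).
#'
#' @param model the model.
#' @param P array (batch x T x channels).
#' @return list with `f` (length batch) and `dX` (same shape as `P`).
#' @export
model_value_grad <- function(model, P) UseMethod("model_value_grad")

#' @export
model_value_grad.trained_classifier <- function(model, P) {
  fwd <- lstm_forward(model$params, P, keep_cache = TRUE)
  dlogit <- fwd$prob * (1 - fwd$prob)  # dF/dlogit for F = probability
  list(f = fwd$prob, dX = lstm_backward(model$params, fwd, dlogit)$dX)
}

#' @export
model_value_grad.linear_model <- function(model, P) {
  B <- dim(P)[1]
  f <- vapply(seq_len(B), function(i) sum(model$w * P[i, , ]) + model$b, 0)
  dX <- array(0, dim = dim(P))
  for (i in seq_len(B)) dX[i, , ] <- model$w
  list(f = f, dX = dX)
}

#' Linear model over a window (test and diagnostic fixture)
#'
#' `F(x) = sum(w * x) + b`; Integrated Gradients with a zero baseline must
#' recover `w * x` exactly for any number of steps.
#'
#' @param w weight matrix (T x channels).
#' @param b intercept.
#' @export
linear_model <- function(w, b = 0) {
  structure(list(w = as.matrix(w), b = b), class = "linear_model")
}

#' Cohort-averaged (global) attribution
#'
#' Integrated Gradients is local; averaging the per-window maps over all
#' stress windows of a test set gives a global picture of which time steps
#' and channels drive stress predictions.
#'
#' @param model classifier or ensemble.
#' @param wd a `windowed_dataset`.
#' @param class_condition average over windows with this label (default 1).
#' @param n_steps Riemann steps per window.
#' @param max_windows cap on averaged windows (subsampled deterministically
#'   by taking the first `max_windows`); `Inf` = all.
#' @return A `global_attribution`: `mean_values` (T x channels),
#'   `n_windows_averaged`, `class_condition`.
#' @export
global_attribution <- function(model, wd, class_condition = 1, n_steps = 128,
                               max_windows = Inf) {
  stopifnot(inherits(wd, "windowed_dataset"))
  idx <- which(wd$labels == class_condition)
  if (!length(idx)) stop("no windows with the requested class label")
  if (length(idx) > max_windows) idx <- idx[seq_len(max_windows)]
  acc <- NULL; gap <- 0
  for (i in idx) {
    m <- integrated_gradients(model, wd$windows[i, , ], n_steps = n_steps)
    acc <- if (is.null(acc)) m$values else acc + m$values
    gap <- gap + m$completeness_gap
  }
  structure(list(mean_values = acc / length(idx),
                 n_windows_averaged = length(idx),
                 class_condition = class_condition, n_steps = n_steps,
                 mean_completeness_gap = gap / length(idx),
                 channels = wd$channels),
            class = "global_attribution")
}

#' Export an attribution map as tidy CSV (time_step, channel, relevance)
#' @param map an `attribution_map` or `global_attribution`.
#' @param path CSV path.
#' @param channels channel names (defaults stored names or ch1..chd).
#' @export
write_attribution_csv <- function(map, path, channels = NULL) {
  vals <- if (inherits(map, "global_attribution")) map$mean_values else map$values
  d <- ncol(vals)
  channels <- channels %||% (if (!is.null(map$channels)) map$channels else paste0("ch", seq_len(d)))
  df <- data.frame(time_step = rep(seq_len(nrow(vals)), d),
                   channel = rep(channels, each = nrow(vals)),
                   relevance = as.vector(vals))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %d x %d, n_steps=%d, completeness gap %.2e\n",
              nrow(x$values), ncol(x$values), x$n_steps, x$completeness_gap))
  invisible(x)
}

#' @export
print.global_attribution <- function(x, ...) {
  cat(sprintf("<global_attribution> mean over %d class-%s windows\n",
              x$n_windows_averaged, format(x$class_condition)))
  invisible(x)
}
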