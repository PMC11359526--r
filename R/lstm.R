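#' Initialize LSTM parameters
#'
#' Recurrent matrices are orthogonal (QR of a Gaussian matrix with sign
#' correction), input weights are xavier-uniform, all biases are zero except
#' the forget-gate input bias which is 1 (mitigates vanishing gradients
#' re-introduced by the forget gate). The readout maps the final hidden
#' state to a single logit.
#'
#' The cell-input activation is sigmoid by default (as in the gating
#' equations implemented here); `cell_act = "tanh"` switches to the
#' classical variant.
#'
#' @param input_size channels per time step.
#' @param hidden_size hidden units.
#' @param cell_act `"sigmoid"` or `"tanh"` for the cell input z_t.
#' @param rng_seed integer seed.
#' @return An `lstm_params` list: `W` (input weights, input x hidden, gates
#'   i/f/z/o), `R` (recurrent, hidden x hidden), `b_i`, `b_h` (bias pairs),
#'   `w_out`, `b_out`, and metadata.
#' @export
lstm_init <- function(input_size, hidden_size, cell_act = c("sigmoid", "tanh"),
                      rng_seed = 1L) {
  cell_act <- match.arg(cell_act)
  with_seed(rng_seed, {
    H <- hidden_size; d <- input_size
    xavier <- function(nin, nout) {
      lim <- sqrt(6 / (nin + nout))
      matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
    }
    orth <- function(n) {
      qrd <- qr(matrix(stats::rnorm(n * n), n, n))
      q <- qr.Q(qrd)
      q %*% diag(sign(diag(qr.R(qrd))), n)
    }
    gates <- c("i", "f", "z", "o")
    W <- lapply(stats::setNames(gates, gates), function(g) xavier(d, H))
    R <- lapply(stats::setNames(gates, gates), function(g) orth(H))
    b_i <- lapply(stats::setNames(gates, gates), function(g) numeric(H))
    b_h <- lapply(stats::setNames(gates, gates), function(g) numeric(H))
    b_i$f <- rep(1, H)  # forget-gate bias 1
    structure(list(W = W, R = R, b_i = b_i, b_h = b_h,
                   w_out = drop(xavier(H, 1)), b_out = 0,
                   input_size = d, hidden_size = H, cell_act = cell_act),
              class = "lstm_params")
  })
}

#' One LSTM step
#'
#' Computes the gate activations, memory cell and hidden state for a single
#' time step:
#' \deqn{i_t = \sigma(W_i x_t + b_{ii} + R_i h_{t-1} + b_{hi})}
#' \deqn{f_t = \sigma(W_f x_t + b_{if} + R_f h_{t-1} + b_{hf})}
#' \deqn{z_t = \sigma(W_z x_t + b_{ig} + R_z h_{t-1} + b_{hg})}
#' \deqn{o_t = \sigma(W_o x_t + b_{io} + R_o h_{t-1} + b_{ho})}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot z_t, \qquad
#'       h_t = o_t \odot \tanh(c_t)}
#' The cell input z_t uses sigmoid by default (`params$cell_act`).
#'
#' @param params an `lstm_params`.
#' @param x_t input, vector of length `input_size` or matrix
#'   (batch x input_size).
#' @param h_prev,c_prev previous hidden / cell state, same batch layout.
#' @return list with `i`, `f`, `z`, `o`, `c`, `h` (matrices batch x hidden).
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  H <- params$hidden_size
  if (is.null(dim(x_t))) x_t <- matrix(x_t, 1)
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, 1)
  if (is.null(dim(c_prev))) c_prev <- matrix(c_prev, 1)
  if (ncol(x_t) != params$input_size) stop("x_t has wrong input size")
  if (ncol(h_prev) != H || ncol(c_prev) != H) stop("state has wrong hidden size")
  B <- nrow(x_t)
  pre <- function(g) {
    x_t %*% params$W[[g]] + h_prev %*% params$R[[g]] +
      matrix(params$b_i[[g]] + params$b_h[[g]], B, H, byrow = TRUE)
  }
  i <- sigmoid(pre("i"))
  f <- sigmoid(pre("f"))
  z <- if (params$cell_act == "sigmoid") sigmoid(pre("z")) else tanh(pre("z"))
  o <- sigmoid(pre("o"))
  c_t <- f * c_prev + i * z
  h_t <- o * tanh(c_t)
  list(i = i, f = f, z = z, o = o, c = c_t, h = h_t)
}

#' Forward pass over a batch of windows
#'
#' Unrolls [lstm_step()] from the zero state over the window length and
#' applies the sigmoid readout to the final hidden state.
#'
#' @param params an `lstm_params`.
#' @param X windows: array (batch x T x input_size), matrix (T x input_size)
#'   for one window, or a `windowed_dataset`.
#' @param keep_cache retain per-step activations for [lstm_backward()].
#' @return list with `prob`, `logit` (length batch) and optionally `cache`.
#' @export
lstm_forward <- function(params, X, keep_cache = FALSE) {
  X <- as_window_array(X, params$input_size)
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- params$hidden_size
  h <- matrix(0, B, H); c_t <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    st <- lstm_step(params, matrix(X[, t, ], B, params$input_size), h, c_t)
    if (keep_cache) {
      st$h_prev <- h; st$c_prev <- c_t
      cache[[t]] <- st
    }
    h <- st$h; c_t <- st$c
  }
  logit <- drop(h %*% params$w_out) + params$b_out
  out <- list(prob = sigmoid(logit), logit = logit)
  if (keep_cache) out$cache <- list(steps = cache, X = X, h_T = h)
  out
}

# coerce the accepted window containers to a batch x T x d array
as_window_array <- function(X, input_size) {
  if (inherits(X, "windowed_dataset")) X <- X$windows
  if (is.matrix(X)) X <- array(X, dim = c(1, nrow(X), ncol(X)))
  stopifnot(length(dim(X)) == 3)
  if (dim(X)[3] != input_size) {
    stop(sprintf("window has %d channels, model expects %d", dim(X)[3], input_size))
  }
  X
}

#' Backpropagation through time
#'
#' Given the cache of a forward pass and the derivative of a scalar
#' objective with respect to each window's logit, returns analytic gradients
#' for every parameter and for the inputs. Used both for training (weighted
#' cross-entropy) and for Integrated Gradients (input gradients).
#'
#' @param params an `lstm_params`.
#' @param fwd result of `lstm_forward(..., keep_cache = TRUE)`.
#' @param dlogit numeric, length batch.
#' @return list with `grads` (same shape as `params`) and `dX`
#'   (batch x T x input_size).
#' @export
lstm_backward <- function(params, fwd, dlogit) {
  cache <- fwd$cache
  X <- cache$X
  B <- dim(X)[1]; Tn <- dim(X)[2]; d <- params$input_size; H <- params$hidden_size
  gr <- list(
    W = lapply(params$W, function(m) m * 0),
    R = lapply(params$R, function(m) m * 0),
    b_i = lapply(params$b_i, function(v) v * 0),
    b_h = lapply(params$b_h, function(v) v * 0),
    w_out = params$w_out * 0, b_out = 0
  )
  h_T <- cache$h_T
  gr$w_out <- drop(crossprod(h_T, dlogit))
  gr$b_out <- sum(dlogit)
  dh <- outer(dlogit, params$w_out)
  dc <- matrix(0, B, H)
  dX <- array(0, dim = dim(X))
  for (t in Tn:1) {
    st <- cache$steps[[t]]
    tc <- tanh(st$c)
    do_ <- dh * tc
    dc <- dc + dh * st$o * (1 - tc^2)
    df <- dc * st$c_prev
    di <- dc * st$z
    dz <- dc * st$i
    da <- list(
      i = di * st$i * (1 - st$i),
      f = df * st$f * (1 - st$f),
      z = if (params$cell_act == "sigmoid") dz * st$z * (1 - st$z) else dz * (1 - st$z^2),
      o = do_ * st$o * (1 - st$o)
    )
    x_t <- matrix(X[, t, ], B, d)
    dh_prev <- matrix(0, B, H)
    dx_t <- matrix(0, B, d)
    for (g in c("i", "f", "z", "o")) {
      gr$W[[g]] <- gr$W[[g]] + crossprod(x_t, da[[g]])
      gr$R[[g]] <- gr$R[[g]] + crossprod(st$h_prev, da[[g]])
      cs <- colSums(da[[g]])
      gr$b_i[[g]] <- gr$b_i[[g]] + cs
      gr$b_h[[g]] <- gr$b_h[[g]] + cs
      dh_prev <- dh_prev + da[[g]] %*% t(params$R[[g]])
      dx_t <- dx_t + da[[g]] %*% t(params$W[[g]])
    }
    dX[, t, ] <- dx_t
    dh <- dh_prev
    dc <- dc * st$f
  }
  list(grads = gr, dX = dX)
}

# ---- parameter flattening for the optimizer ----

flatten_params <- function(p) {
  c(unlist(p$W), unlist(p$R), unlist(p$b_i), unlist(p$b_h), p$w_out, p$b_out)
}

unflatten_params <- function(template, v) {
  p <- template; at <- 0
  take <- function(n) { out <- v[at + seq_len(n)]; at <<- at + n; out }
  for (slot in c("W", "R")) for (g in names(p[[slot]])) {
    m <- p[[slot]][[g]]
    p[[slot]][[g]] <- matrix(take(length(m)), nrow(m), ncol(m))
  }
  for (slot in c("b_i", "b_h")) for (g in names(p[[slot]])) {
    p[[slot]][[g]] <- take(length(p[[slot]][[g]]))
  }
  p$w_out <- take(length(p$w_out))
  p$b_out <- take(1)
  p
}

# weighted binary cross-entropy and its logit derivative
wbce <- function(prob, y, w) {
  eps <- 1e-12
  l <- -(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  sum(w * l) / sum(w)
}

#' Train the LSTM classifier
#'
#' Minimizes class-weighted binary cross-entropy with Adam; the positive
#' class is up-weighted by `n_neg / n_pos` (window labels are heavily
#' imbalanced at small strides). Validation is split at the subject level
#' and training stops once validation loss stops improving for `patience`
#' epochs; the best-validation parameters are returned. Deterministic given
#' `rng_seed`.
#'
#' @param wd a `windowed_dataset` containing both classes.
#' @param hidden_size,cell_act architecture, see [lstm_init()].
#' @param lr,batch_size,epochs,patience optimization controls.
#' @param validation_split fraction of subjects held out for early stopping.
#' @param threshold probability cutoff stored with the model.
#' @param class_weight positive-class weight; `NULL` = `n_neg / n_pos`.
#' @param rng_seed integer seed.
#' @return A `trained_classifier`: `params`, `threshold`, `training_log`
#'   (epoch, train_loss, val_loss), `config_fingerprint`.
#' @export
train_lstm <- function(wd, hidden_size = 8, cell_act = "sigmoid",
                       lr = 1e-2, batch_size = 128, epochs = 60, patience = 8,
                       validation_split = 0.2, threshold = 0.5,
                       class_weight = NULL, rng_seed = 1L) {
  stopifnot(inherits(wd, "windowed_dataset"))
  y <- wd$labels
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  d <- dim(wd$windows)[3]
  if (is.null(class_weight)) class_weight <- sum(y == 0) / sum(y == 1)
  cfg <- list(hidden_size = hidden_size, cell_act = cell_act, lr = lr,
              batch_size = batch_size, epochs = epochs, patience = patience,
              validation_split = validation_split, class_weight = class_weight,
              rng_seed = rng_seed)
  with_seed(rng_seed, {
    real <- !(wd$synthetic %||% rep(FALSE, length(y)))
    subs <- unique(wd$subject_ids[real])
    if (length(subs) >= 2 && validation_split > 0) {
      n_val <- max(1, round(validation_split * length(subs)))
      val_subs <- sample(subs, n_val)
      # all windows of a validation subject leave the training set (their
      # augmented copies included); validation loss uses real windows only
      held <- wd$subject_ids %in% val_subs
      tr <- which(!held)
      va <- which(held & real)
    } else {
      va <- sample(seq_along(y), max(1, round(validation_split * length(y))))
      tr <- setdiff(seq_along(y), va)
    }
    if (!length(va) || !length(tr)) {
      va <- which(seq_along(y) <= length(y) / 5)
      tr <- setdiff(seq_along(y), va)
    }
    Xtr <- wd$windows[tr, , , drop = FALSE]; ytr <- y[tr]
    Xva <- wd$windows[va, , , drop = FALSE]; yva <- y[va]
    wts <- function(yy) ifelse(yy == 1, class_weight, 1)

    params <- lstm_init(d, hidden_size, cell_act, rng_seed = sample.int(2^30, 1))
    theta <- flatten_params(params)
    m <- v <- numeric(length(theta)); b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0
    best <- list(loss = Inf, theta = theta, epoch = 0)
    log_rows <- list()
    bad <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(length(ytr))
      ep_loss <- 0; nb <- 0
      for (b0 in seq(1, length(ord), by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
        Xb <- Xtr[idx, , , drop = FALSE]; yb <- ytr[idx]; wb <- wts(yb)
        fwd <- lstm_forward(params, Xb, keep_cache = TRUE)
        loss <- wbce(fwd$prob, yb, wb)
        dlogit <- wb * (fwd$prob - yb) / sum(wb)
        bk <- lstm_backward(params, fwd, dlogit)
        g <- flatten_params(bk$grads)
        step <- step + 1
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mh <- m / (1 - b1^step); vh <- v / (1 - b2^step)
        theta <- theta - lr * mh / (sqrt(vh) + eps)
        params <- unflatten_params(params, theta)
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      pv <- lstm_forward(params, Xva)$prob
      val_loss <- wbce(pv, yva, wts(yva))
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, theta = theta, epoch = ep)
        bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= patience) break
      }
    }
    params <- unflatten_params(params, best$theta)
    structure(list(params = params, threshold = threshold,
                   training_log = do.call(rbind, log_rows),
                   best_epoch = best$epoch,
                   config_fingerprint = config_fingerprint(cfg), config = cfg),
              class = "trained_classifier")
  })
}

#' Predict window probabilities
#' @param clf a `trained_classifier` or `dge_ensemble`.
#' @param X windows (array / matrix / `windowed_dataset`).
#' @return numeric probabilities in (0, 1).
#' @export
predict_prob <- function(clf, X) {
  if (inherits(clf, "dge_ensemble")) return(dge_predict(clf, X))
  stopifnot(inherits(clf, "trained_classifier"))
  lstm_forward(clf$params, X)$prob
}

#' Subject-level cross-validation folds
#'
#' Shuffles subjects and deals them into `k` folds of near-equal size
#' (28 subjects, k = 5 gives sizes 6,6,6,5,5); no subject appears in two
#' folds, preventing leakage between partitions.
#'
#' @param subject_ids character per-window subject ids (or unique subjects).
#' @param k number of folds (>= 2).
#' @param rng_seed integer seed.
#' @return list of character vectors of subject ids, one per fold.
#' @export
subject_folds <- function(subject_ids, k = 5, rng_seed = 1L) {
  stopifnot(k >= 2)
  subs <- unique(subject_ids)
  if (length(subs) < k) stop("fewer subjects than folds")
  with_seed(rng_seed, {
    sh <- sample(subs)
    split(sh, rep(seq_len(k), length.out = length(sh)))
  })
}

#' Grid search with subject-level cross-validation
#'
#' Evaluates every hyperparameter combination by k-fold CV with folds split
#' at the subject level; selection maximizes mean window-level F1 across
#' folds, ties broken by higher mean recall, then by smaller hidden size.
#'
#' @param wd a `windowed_dataset`.
#' @param grid data.frame of hyperparameter combinations (columns matching
#'   [train_lstm()] arguments, e.g. `hidden_size`, `lr`).
#' @param k_folds number of folds.
#' @param rng_seed integer seed.
#' @param ... fixed arguments passed to [train_lstm()].
#' @return list with `best` (row of `grid`), `results` (per-point mean F1 /
#'   recall), `folds`.
#' @export
grid_search_cv <- function(wd, grid, k_folds = 5, rng_seed = 1L, ...) {
  if (is.null(grid) || nrow(as.data.frame(grid)) == 0) stop("empty grid")
  grid <- as.data.frame(grid)
  folds <- subject_folds(wd$subject_ids, k_folds, rng_seed)
  res <- data.frame(grid, mean_f1 = NA_real_, mean_recall = NA_real_)
  for (gi in seq_len(nrow(grid))) {
    f1s <- recs <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      te <- wd$subject_ids %in% folds[[fi]]
      clf <- do.call(train_lstm, c(list(wd_subset(wd, !te),
                                        rng_seed = derive_seed(rng_seed, paste0("cv", fi))),
                                   as.list(grid[gi, , drop = FALSE]), list(...)))
      p <- predict_prob(clf, wd_subset(wd, te))
      yhat <- as.integer(p >= clf$threshold)
      yte <- wd$labels[te]
      tp <- sum(yhat == 1 & yte == 1); fp <- sum(yhat == 1 & yte == 0)
      fn <- sum(yhat == 0 & yte == 1)
      recs[fi] <- if (tp + fn > 0) tp / (tp + fn) else 0
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      f1s[fi] <- if (prec + recs[fi] > 0) 2 * prec * recs[fi] / (prec + recs[fi]) else 0
    }
    res$mean_f1[gi] <- mean(f1s); res$mean_recall[gi] <- mean(recs)
  }
  size <- if ("hidden_size" %in% names(grid)) grid$hidden_size else rep(0, nrow(grid))
  ord <- order(-res$mean_f1, -res$mean_recall, size)
  list(best = grid[ord[1], , drop = FALSE], results = res, folds = folds)
}

#' Save / load a trained classifier as a JSON checkpoint
#' @param clf a `trained_classifier`.
#' @param path file path (JSON).
#' @export
save_classifier <- function(clf, path) {
  p <- clf$params
  jsonlite::write_json(list(
    W = p$W, R = p$R, b_i = p$b_i, b_h = p$b_h,
    w_out = p$w_out, b_out = p$b_out,
    input_size = p$input_size, hidden_size = p$hidden_size,
    cell_act = p$cell_act, threshold = clf$threshold,
    config_fingerprint = clf$config_fingerprint,
    training_log = clf$training_log
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- structure(list(
    W = lapply(x$W, as.matrix), R = lapply(x$R, as.matrix),
    b_i = lapply(x$b_i, as.numeric), b_h = lapply(x$b_h, as.numeric),
    w_out = as.numeric(x$w_out), b_out = x$b_out,
    input_size = x$input_size, hidden_size = x$hidden_size,
    cell_act = x$cell_act), class = "lstm_params")
  structure(list(params = par, threshold = x$threshold,
                 training_log = x$training_log,
                 config_fingerprint = x$config_fingerprint),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> hidden=%d, %d epochs (best %d), threshold %.2f\n",
              x$params$hidden_size, nrow(x$training_log),
              x$best_epoch %||% NA, x$threshold))
  invisible(x)
}
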