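#' Augmentation configuration
#'
#' Noise-and-scale augmentation of stress windows: each new sample is
#' `scale * window + noise` with `scale ~ U[scale_min, scale_max]` and
#' i.i.d. Gaussian noise per sample point (standardized units).
#'
#' @param noise_sd Gaussian noise sd (>= 0), standardized units.
#' @param scale_min,scale_max amplitude scale bounds, 0 < min <= max.
#' @param n_augment_per_positive new samples per input window.
#' @export
augment_config <- function(noise_sd = 0.05, scale_min = 0.8, scale_max = 1.2,
                           n_augment_per_positive = 1) {
  stopifnot(noise_sd >= 0, scale_min > 0, scale_min <= scale_max,
            n_augment_per_positive >= 0)
  structure(list(noise_sd = noise_sd, scale_min = scale_min,
                 scale_max = scale_max,
                 n_augment_per_positive = n_augment_per_positive),
            class = "augment_config")
}

#' Augment positive windows with noise and amplitude scaling
#'
#' @param wd a `windowed_dataset` of positive (stress) windows, non-empty.
#' @param config an [augment_config()].
#' @param rng_seed integer seed.
#' @return a `windowed_dataset` of `n_augment_per_positive * n` windows,
#'   flagged synthetic.
#' @export
augment_windows <- function(wd, config = augment_config(), rng_seed = 1L) {
  stopifnot(inherits(wd, "windowed_dataset"))
  n <- dim(wd$windows)[1]
  if (n == 0) stop("no windows to augment")
  reps <- config$n_augment_per_positive
  with_seed(rng_seed, {
    idx <- rep(seq_len(n), reps)
    W <- wd$windows[idx, , , drop = FALSE]
    scales <- stats::runif(length(idx), config$scale_min, config$scale_max)
    W <- W * scales  # recycles over the first margin
    W <- W + array(stats::rnorm(length(W), 0, config$noise_sd), dim = dim(W))
    structure(list(windows = W, labels = wd$labels[idx],
                   window_start_s = wd$window_start_s[idx],
                   subject_ids = wd$subject_ids[idx],
                   synthetic = rep(TRUE, length(idx)),
                   channels = wd$channels),
              class = "windowed_dataset")
  })
}

#' Fit a class-conditional generative model of 16 s windows
#'
#' Two generator types are available:
#' \describe{
#'   \item{`"cgan"`}{a small label-conditioned GAN: one-hidden-layer MLP
#'     generator and discriminator over flattened windows, trained with the
#'     non-saturating adversarial loss and Adam (manual gradients).}
#'   \item{`"bootstrap"`}{parametric resampling: stores the class-conditional
#'     window pools and samples `pool window * scale + noise`. Deterministic,
#'     cheap, and used to exercise the ensemble logic at desk scale.}
#' }
#'
#' @param wd a `windowed_dataset` with both classes.
#' @param type `"cgan"` or `"bootstrap"`.
#' @param latent_dim latent noise dimension (cgan).
#' @param hidden hidden units of generator/discriminator MLPs (cgan).
#' @param epochs adversarial epochs (cgan).
#' @param lr Adam learning rate (cgan).
#' @param batch_size minibatch size (cgan); batches are class-balanced.
#' @param fm_weight weight of the per-class feature-matching (batch-mean)
#'   term in the generator loss; stabilizes the conditional mean (cgan).
#' @param noise_sd,scale_min,scale_max bootstrap resampling parameters.
#' @param rng_seed integer seed; fully determines training.
#' @return A `generative_model`.
#' @export
fit_generator <- function(wd, type = c("bootstrap", "cgan"), latent_dim = 16,
                          hidden = 32, epochs = 300, lr = 1e-3,
                          batch_size = 64, fm_weight = 20, noise_sd = 0.05,
                          scale_min = 0.9, scale_max = 1.1, rng_seed = 1L) {
  type <- match.arg(type)
  stopifnot(inherits(wd, "windowed_dataset"))
  if (length(unique(wd$labels)) < 2) stop("generator needs both classes")
  dims <- dim(wd$windows)[2:3]
  if (type == "bootstrap") {
    gm <- list(type = "bootstrap", dims = dims, channels = wd$channels,
               pool = list(pos = wd$windows[wd$labels == 1, , , drop = FALSE],
                           neg = wd$windows[wd$labels == 0, , , drop = FALSE]),
               noise_sd = noise_sd, scale_min = scale_min,
               scale_max = scale_max, training_seed = rng_seed)
    gm$fingerprint <- config_fingerprint(list(type = "bootstrap", seed = rng_seed,
                                              n = dim(wd$windows)[1]))
    return(structure(gm, class = "generative_model"))
  }
  # --- conditional GAN, manual backprop ---
  D_in <- prod(dims)
  Xf <- matrix(wd$windows, dim(wd$windows)[1], D_in)  # flattened windows
  y <- wd$labels
  with_seed(rng_seed, {
    init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
    G <- list(W1 = init(latent_dim + 1, hidden), b1 = numeric(hidden),
              W2 = init(hidden, D_in), b2 = numeric(D_in))
    D <- list(W1 = init(D_in + 1, hidden), b1 = numeric(hidden),
              W2 = init(hidden, 1), b2 = 0)
    g_fwd <- function(G, Z, lab) {
      A <- cbind(Z, lab)
      H1 <- tanh(sweep(A %*% G$W1, 2, G$b1, "+"))
      X <- sweep(H1 %*% G$W2, 2, G$b2, "+")
      list(A = A, H1 = H1, X = X)
    }
    d_fwd <- function(D, X, lab) {
      A <- cbind(X, lab)
      H1 <- tanh(sweep(A %*% D$W1, 2, D$b1, "+"))
      s <- drop(H1 %*% D$W2) + D$b2
      list(A = A, H1 = H1, p = sigmoid(s))
    }
    # gradients of mean BCE(d, target) wrt D params and wrt its input X
    d_back <- function(D, fw, target) {
      B <- nrow(fw$A)
      ds <- (fw$p - target) / B
      gW2 <- drop(crossprod(fw$H1, ds)); gb2 <- sum(ds)
      dH1 <- outer(ds, drop(D$W2)) * (1 - fw$H1^2)
      gW1 <- crossprod(fw$A, dH1); gb1 <- colSums(dH1)
      dA <- dH1 %*% t(D$W1)
      list(g = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
           dX = dA[, seq_len(ncol(fw$A) - 1), drop = FALSE])
    }
    adam_new <- function(p) list(m = lapply(p, function(x) x * 0),
                                 v = lapply(p, function(x) x * 0), t = 0)
    adam_step <- function(p, g, st, lr) {
      st$t <- st$t + 1
      for (k in names(p)) {
        st$m[[k]] <- 0.9 * st$m[[k]] + 0.1 * g[[k]]
        st$v[[k]] <- 0.999 * st$v[[k]] + 0.001 * g[[k]]^2
        mh <- st$m[[k]] / (1 - 0.9^st$t); vh <- st$v[[k]] / (1 - 0.999^st$t)
        p[[k]] <- p[[k]] - lr * mh / (sqrt(vh) + 1e-8)
      }
      list(p = p, st = st)
    }
    oG <- adam_new(G); oD <- adam_new(D)
    n <- nrow(Xf)
    # class-balanced minibatches: the stress class is rare at small strides
    # and an unbalanced discriminator never learns the conditioning
    wsel <- ifelse(y == 1, 0.5 / max(1, sum(y == 1)), 0.5 / max(1, sum(y == 0)))
    n_batches <- max(1L, ceiling(n / batch_size))
    log_d <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      for (bi in seq_len(n_batches)) {
        idx <- sample(n, min(batch_size, n), replace = TRUE, prob = wsel)
        B <- length(idx)
        # discriminator step: real -> 1, fake -> 0
        Z <- matrix(stats::rnorm(B * latent_dim), B)
        lab <- 2 * y[idx] - 1  # +/-1 label coding conditions both networks
        fake <- g_fwd(G, Z, lab)$X
        fr <- d_fwd(D, Xf[idx, , drop = FALSE], lab)
        ff <- d_fwd(D, fake, lab)
        br <- d_back(D, fr, rep(1, B)); bf <- d_back(D, ff, rep(0, B))
        gD <- Map(`+`, br$g, bf$g)
        up <- adam_step(D, gD, oD, lr); D <- up$p; oD <- up$st
        # generator step: non-saturating loss, plus per-class feature
        # matching (batch-mean matching) which stabilizes the conditional
        # mean that adversarial training alone drifts around at this scale
        Z <- matrix(stats::rnorm(B * latent_dim), B)
        gf <- g_fwd(G, Z, lab)
        df <- d_fwd(D, gf$X, lab)
        bb <- d_back(D, df, rep(1, B))   # dX = d loss / d fake input
        dX_g <- bb$dX
        for (cl in c(-1, 1)) {
          ic <- which(lab == cl)
          if (length(ic) < 2) next
          mf <- colMeans(gf$X[ic, , drop = FALSE])
          mr <- colMeans(Xf[idx[ic], , drop = FALSE])
          dX_g[ic, ] <- dX_g[ic, ] +
            matrix(fm_weight * 2 * (mf - mr) / (D_in * length(ic)),
                   length(ic), D_in, byrow = TRUE)
        }
        dH1 <- (dX_g %*% t(G$W2)) * (1 - gf$H1^2)
        gG <- list(W1 = crossprod(gf$A, dH1), b1 = colSums(dH1),
                   W2 = crossprod(gf$H1, dX_g), b2 = colSums(dX_g))
        up <- adam_step(G, gG, oG, lr); G <- up$p; oG <- up$st
      }
      log_d[ep] <- mean(d_fwd(D, Xf, y)$p)
    }
    structure(list(type = "cgan", dims = dims, channels = wd$channels,
                   G = G, D = D, latent_dim = latent_dim,
                   training_seed = rng_seed, d_real_curve = log_d,
                   fingerprint = config_fingerprint(
                     list(seed = rng_seed, w = sum(abs(G$W2))))),
              class = "generative_model")
  })
}

#' Sample a balanced synthetic dataset from a generative model
#'
#' @param gen a `generative_model`.
#' @param n_per_class windows per class (>= 1).
#' @param rng_seed integer seed.
#' @return a `windowed_dataset` with `synthetic = TRUE` throughout.
#' @export
sample_synthetic <- function(gen, n_per_class, rng_seed = 1L) {
  stopifnot(inherits(gen, "generative_model"), n_per_class >= 1)
  Tn <- gen$dims[1]; d <- gen$dims[2]
  n <- 2 * n_per_class
  lab <- rep(c(1L, 0L), each = n_per_class)
  W <- with_seed(rng_seed, {
    if (gen$type == "bootstrap") {
      draw <- function(pool, m) {
        src <- pool[sample(dim(pool)[1], m, replace = TRUE), , , drop = FALSE]
        src <- src * stats::runif(m, gen$scale_min, gen$scale_max)
        src + array(stats::rnorm(length(src), 0, gen$noise_sd), dim = dim(src))
      }
      abind_1(draw(gen$pool$pos, n_per_class), draw(gen$pool$neg, n_per_class))
    } else {
      Z <- matrix(stats::rnorm(n * gen$latent_dim), n)
      A <- cbind(Z, 2 * lab - 1)
      H1 <- tanh(sweep(A %*% gen$G$W1, 2, gen$G$b1, "+"))
      Xf <- sweep(H1 %*% gen$G$W2, 2, gen$G$b2, "+")
      array(Xf, dim = c(n, Tn, d))
    }
  })
  structure(list(windows = W, labels = lab,
                 window_start_s = rep(NA_real_, n),
                 subject_ids = rep("synthetic", n),
                 synthetic = rep(TRUE, n), channels = gen$channels),
            class = "windowed_dataset")
}

#' Train a Deep Generative Ensemble
#'
#' For each of K members: fit a generative model under a member-specific
#' seed, sample a synthetic dataset from it, merge real windows +
#' noise/scale-augmented positives + synthetic windows, and train one LSTM
#' classifier. Member predictions are averaged ([dge_predict()]), which
#' mitigates overfitting to any single generative model's samples.
#'
#' @param wd real training `windowed_dataset`.
#' @param K ensemble size (>= 1); 5 in the reference configuration.
#' @param aug_config an [augment_config()] for the positive class.
#' @param generator `"bootstrap"` or `"cgan"`, see [fit_generator()].
#' @param n_synth_per_class synthetic windows per class per member;
#'   `NULL` = number of real positives (1:1:1 real:augmented:synthetic
#'   mixing for the positive class).
#' @param rng_seed integer seed; member seeds are derived from it.
#' @param gen_args extra arguments for [fit_generator()].
#' @param ... passed to [train_lstm()] (hidden_size, lr, ...).
#' @return A `dge_ensemble`: `members` (list of classifier + seeds),
#'   `K`, `manifest`.
#' @export
dge_train <- function(wd, K = 5, aug_config = augment_config(),
                      generator = "bootstrap", n_synth_per_class = NULL,
                      rng_seed = 1L, gen_args = list(), ...) {
  stopifnot(K >= 1)
  n_pos <- sum(wd$labels == 1)
  if (is.null(n_synth_per_class)) n_synth_per_class <- max(1, n_pos)
  members <- vector("list", K)
  for (k in seq_len(K)) {
    seed_k <- derive_seed(rng_seed, paste0("dge-member-", k))
    gen <- do.call(fit_generator,
                   c(list(wd, type = generator, rng_seed = seed_k), gen_args))
    syn <- sample_synthetic(gen, n_synth_per_class,
                            rng_seed = derive_seed(seed_k, "sample"))
    aug <- augment_windows(wd_subset(wd, wd$labels == 1), aug_config,
                           rng_seed = derive_seed(seed_k, "augment"))
    train_set <- wd_bind(wd, aug, syn)
    clf <- train_lstm(train_set, rng_seed = derive_seed(seed_k, "train"), ...)
    members[[k]] <- list(seed = seed_k, generator_fingerprint = gen$fingerprint,
                         classifier = clf)
  }
  structure(list(members = members, K = K,
                 manifest = list(rng_seed = rng_seed, K = K,
                                 generator = generator,
                                 member_seeds = vapply(members, `[[`, 0L, "seed"),
                                 aug_config = unclass(aug_config),
                                 n_synth_per_class = n_synth_per_class)),
            class = "dge_ensemble")
}

#' Ensemble prediction: arithmetic mean of member probabilities
#' @param ensemble a `dge_ensemble`.
#' @param X windows (array / `windowed_dataset`).
#' @export
dge_predict <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "dge_ensemble"))
  if (!length(ensemble$members)) stop("untrained ensemble")
  ps <- vapply(ensemble$members,
               function(m) predict_prob(m$classifier, X),
               numeric(n_windows_of(X)))
  if (is.null(dim(ps))) ps <- matrix(ps, nrow = 1)
  rowMeans(ps)
}

n_windows_of <- function(X) {
  if (inherits(X, "windowed_dataset")) return(dim(X$windows)[1])
  if (is.matrix(X)) return(1L)
  dim(X)[1]
}

#' Homogeneous outer ensemble of classifiers
#'
#' Trains M classifiers (each optionally a full DGE) differing only in
#' seed, and averages their probabilities — the "ensemble of LSTMs" layer
#' on top of DGE.
#'
#' @param wd training `windowed_dataset`.
#' @param M outer ensemble size.
#' @param inner `"dge"` (each member is a DGE) or `"single"`.
#' @param rng_seed integer seed.
#' @param ... passed to [dge_train()] or [train_lstm()].
#' @return a `dge_ensemble` whose members may themselves be ensembles.
#' @export
lstm_ensemble <- function(wd, M = 5, inner = c("single", "dge"),
                          rng_seed = 1L, ...) {
  inner <- match.arg(inner)
  members <- lapply(seq_len(M), function(m) {
    seed_m <- derive_seed(rng_seed, paste0("outer-", m))
    clf <- if (inner == "dge") dge_train(wd, rng_seed = seed_m, ...)
           else train_lstm(wd, rng_seed = seed_m, ...)
    list(seed = seed_m, classifier = clf)
  })
  structure(list(members = members, K = M,
                 manifest = list(rng_seed = rng_seed, M = M, inner = inner)),
            class = "dge_ensemble")
}

#' Save / load a DGE ensemble checkpoint directory
#'
#' Writes one JSON checkpoint per member plus a `manifest.json` with the
#' seeds and configuration needed to reproduce the ensemble.
#'
#' @param ensemble a `dge_ensemble` (members must be single classifiers).
#' @param dir checkpoint directory.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "dge_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ensemble$members)) {
    save_classifier(ensemble$members[[k]]$classifier,
                    file.path(dir, sprintf("member_%02d.json", k)))
  }
  jsonlite::write_json(ensemble$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  files <- sort(list.files(dir, pattern = "^member_\\d+\\.json$",
                           full.names = TRUE))
  if (!length(files)) stop("no member checkpoints in ", dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  members <- lapply(files, function(f) list(classifier = load_classifier(f)))
  structure(list(members = members, K = length(members), manifest = manifest),
            class = "dge_ensemble")
}

#' @export
print.dge_ensemble <- function(x, ...) {
  cat(sprintf("<dge_ensemble> K=%d members\n", x$K))
  invisible(x)
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf("<generative_model> type=%s, %d x %d windows\n",
              x$type, x$dims[1], x$dims[2]))
  invisible(x)
}
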