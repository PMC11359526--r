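# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

# small easy cohort: 6 full-responder subjects, low noise, no spurious peaks
fx_cohort <- function() fixture("cohort", function() {
  gen_cohort(6, cohort_preset("easy"), rng_seed = 42)
})

fx_wd_train <- function() fixture("wd_train", function() {
  window_cohort(fx_cohort(), stride_s = 2)
})

fx_wd_eval <- function() fixture("wd_eval", function() {
  window_cohort(fx_cohort(), stride_s = 1)
})

# a small trained classifier reused across explanation / evaluation tests
fx_clf <- function() fixture("clf", function() {
  train_lstm(fx_wd_train(), hidden_size = 6, epochs = 25, patience = 6,
             rng_seed = 7)
})

# -- independent scalar-loop oracle of the LSTM recurrence ------------------
# Deliberately written without matrices or shared helpers: every gate is a
# per-unit loop of explicit sums, mirroring the printed equations.
oracle_lstm_prob <- function(params, X) {
  H <- params$hidden_size
  d <- params$input_size
  sig <- function(u) 1 / (1 + exp(-u))
  h <- rep(0, H); cc <- rep(0, H)
  for (t in seq_len(nrow(X))) {
    i <- f <- z <- o <- numeric(H)
    for (j in seq_len(H)) {
      s_i <- params$b_i$i[j] + params$b_h$i[j]
      s_f <- params$b_i$f[j] + params$b_h$f[j]
      s_z <- params$b_i$z[j] + params$b_h$z[j]
      s_o <- params$b_i$o[j] + params$b_h$o[j]
      for (k in seq_len(d)) {
        s_i <- s_i + params$W$i[k, j] * X[t, k]
        s_f <- s_f + params$W$f[k, j] * X[t, k]
        s_z <- s_z + params$W$z[k, j] * X[t, k]
        s_o <- s_o + params$W$o[k, j] * X[t, k]
      }
      for (k in seq_len(H)) {
        s_i <- s_i + params$R$i[k, j] * h[k]
        s_f <- s_f + params$R$f[k, j] * h[k]
        s_z <- s_z + params$R$z[k, j] * h[k]
        s_o <- s_o + params$R$o[k, j] * h[k]
      }
      i[j] <- sig(s_i); f[j] <- sig(s_f)
      z[j] <- if (params$cell_act == "sigmoid") sig(s_z) else tanh(s_z)
      o[j] <- sig(s_o)
    }
    for (j in seq_len(H)) {
      cc[j] <- f[j] * cc[j] + i[j] * z[j]
      h[j] <- o[j] * tanh(cc[j])
    }
  }
  sig(sum(params$w_out * h) + params$b_out)
}

# -- exhaustive optimal matching oracle (igraph maximum bipartite matching) --
oracle_match_count <- function(predictions, references, pre_s = 2, post_s = 6) {
  if (!length(predictions) || !length(references)) return(0L)
  np <- length(predictions); nr <- length(references)
  edges <- integer(0)
  for (i in seq_len(np)) for (j in seq_len(nr)) {
    if (predictions[i] >= references[j] - pre_s &&
        predictions[i] <= references[j] + post_s) {
      edges <- c(edges, i, np + j)
    }
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, np), rep(TRUE, nr)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# build a stub classifier whose probability is constant for any input
stub_classifier <- function(prob, input_size = 2, hidden_size = 2) {
  p <- lstm_init(input_size, hidden_size, rng_seed = 1)
  for (g in names(p$W)) { p$W[[g]][] <- 0; p$R[[g]][] <- 0 }
  for (g in names(p$b_i)) { p$b_i[[g]][] <- 0; p$b_h[[g]][] <- 0 }
  p$w_out[] <- 0
  p$b_out <- log(prob / (1 - prob))
  structure(list(params = p, threshold = 0.5), class = "trained_classifier")
}
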