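test_that("noise/scale augmentation obeys its configuration", {
  wd <- fx_wd_train()
  pos <- wd_subset(wd, wd$labels == 1)
  # identity configuration reproduces the inputs exactly
  ident <- augment_windows(pos, augment_config(noise_sd = 0, scale_min = 1,
                                               scale_max = 1), rng_seed = 1)
  expect_equal(ident$windows, pos$windows, tolerance = 1e-12)
  expect_true(all(ident$synthetic))
  # count contract
  a3 <- augment_windows(pos, augment_config(n_augment_per_positive = 3),
                        rng_seed = 1)
  expect_identical(dim(a3$windows)[1], 3L * dim(pos$windows)[1])
  # pure scaling bounds the per-window amplitude ratio
  sc <- augment_windows(pos, augment_config(noise_sd = 0, scale_min = 0.8,
                                            scale_max = 1.2), rng_seed = 2)
  r <- apply(abs(sc$windows), 1, max) / apply(abs(pos$windows), 1, max)
  expect_true(all(r >= 0.8 - 1e-9 & r <= 1.2 + 1e-9))
  # Monte-Carlo: mean squared deviation per point ~ noise_sd^2
  nz <- augment_windows(pos, augment_config(noise_sd = 0.1, scale_min = 1,
                                            scale_max = 1,
                                            n_augment_per_positive = 5),
                        rng_seed = 3)
  src <- nz$windows - pos$windows[rep(seq_len(dim(pos$windows)[1]), 5), , ,
                                  drop = FALSE]
  expect_lt(abs(mean(src^2) - 0.01), 0.001)
  expect_error(augment_windows(wd_subset(wd, rep(FALSE, length(wd$labels)))),
               "no windows")
})

test_that("bootstrap generator: shapes, determinism, provenance, seed sensitivity", {
  wd <- fx_wd_train()
  gen <- fit_generator(wd, type = "bootstrap", rng_seed = 5)
  syn <- sample_synthetic(gen, 100, rng_seed = 6)
  expect_identical(dim(syn$windows), c(200L, 16L, 2L))
  expect_identical(sum(syn$labels), 100L)
  expect_true(all(is.finite(syn$windows)))
  expect_true(all(syn$synthetic))
  expect_equal(sample_synthetic(gen, 100, rng_seed = 6)$windows, syn$windows,
               tolerance = 1e-15)
  expect_false(isTRUE(all.equal(sample_synthetic(gen, 100, rng_seed = 7)$windows,
                                syn$windows)))
  expect_error(fit_generator(wd_subset(wd, wd$labels == 0)), "both classes")
})

test_that("conditional GAN learns the class-conditional stress shape", {
  co4 <- fixture("cohort4", function() gen_cohort(4, cohort_preset("easy"),
                                                  rng_seed = 2))
  wd <- fixture("wd4", function() window_cohort(co4, stride_s = 2))
  real_pos <- apply(wd$windows[wd$labels == 1, , 1], 2, mean)
  gen <- fit_generator(wd, type = "cgan", epochs = 250, rng_seed = 3)
  syn <- sample_synthetic(gen, 500, rng_seed = 4)
  expect_identical(dim(syn$windows), c(1000L, 16L, 2L))
  expect_true(all(is.finite(syn$windows)))
  syn_pos <- apply(syn$windows[syn$labels == 1, , 1], 2, mean)
  # peak of the synthetic conditional mean inside the real full-width-at-
  # half-maximum band
  band <- which(real_pos >= 0.5 * max(real_pos))
  expect_true(which.max(syn_pos) %in% band)
  # conditioning separates the classes
  syn_neg <- apply(syn$windows[syn$labels == 0, , 1], 2, mean)
  expect_gt(max(syn_pos), max(syn_neg) + 0.5)
  # seed sensitivity of the fitted generator
  gen2 <- fit_generator(wd, type = "cgan", epochs = 5, rng_seed = 8)
  expect_false(identical(gen$fingerprint, gen2$fingerprint))
})

test_that("DGE training, prediction averaging and determinism", {
  wd <- fx_wd_train()
  X <- fx_wd_eval()$windows[1:20, , , drop = FALSE]
  e1 <- dge_train(wd, K = 1, rng_seed = 4, epochs = 6, patience = 3,
                  hidden_size = 4)
  expect_equal(dge_predict(e1, X), predict_prob(e1$members[[1]]$classifier, X),
               tolerance = 1e-12)
  e3 <- dge_train(wd, K = 3, rng_seed = 4, epochs = 6, patience = 3,
                  hidden_size = 4)
  expect_identical(length(unique(e3$manifest$member_seeds)), 3L)
  # retraining from the manifest seed reproduces the members bit-for-bit
  e3b <- dge_train(wd, K = 3, rng_seed = 4, epochs = 6, patience = 3,
                   hidden_size = 4)
  expect_equal(dge_predict(e3, X), dge_predict(e3b, X), tolerance = 1e-12)
  # ensemble probability is the arithmetic mean and lies within member range
  stub <- structure(list(members = list(list(classifier = stub_classifier(0.2)),
                                        list(classifier = stub_classifier(0.8))),
                         K = 2), class = "dge_ensemble")
  p <- dge_predict(stub, X)
  expect_equal(p, rep(0.5, 20), tolerance = 1e-9)
  ps <- sapply(e3$members, function(m) predict_prob(m$classifier, X))
  pe <- dge_predict(e3, X)
  expect_true(all(pe >= apply(ps, 1, min) - 1e-12 &
                  pe <= apply(ps, 1, max) + 1e-12))
  expect_error(dge_predict(structure(list(members = list(), K = 0),
                                     class = "dge_ensemble"), X), "untrained")
})

test_that("augmented positives keep their class signal", {
  wd <- fx_wd_train()
  clf <- fx_clf()
  pos <- wd_subset(wd, wd$labels == 1)
  aug <- augment_windows(pos, augment_config(), rng_seed = 11)
  neg <- wd_subset(wd, wd$labels == 0)
  expect_gt(mean(predict_prob(clf, aug)),
            mean(predict_prob(clf, neg)))
})
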