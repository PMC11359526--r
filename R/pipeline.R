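#' Phenotype range presets for experiments
#'
#' `"default"` is the mixed cohort; `"easy"` makes every subject a full
#' responder with negligible noise and no spurious peaks (detection upper
#' bound); `"hard"` is the non-responder phenotype where only ~40% of
#' stimuli elicit an SCR, which caps attainable recall.
#'
#' @param preset `"default"`, `"easy"`, or `"hard"`.
#' @return ranges list for [gen_cohort()].
#' @export
cohort_preset <- function(preset = c("default", "easy", "hard")) {
  preset <- match.arg(preset)
  switch(preset,
    default = phenotype_ranges(),
    easy = phenotype_ranges(responder_prob = c(1, 1),
                            spurious_rate = c(0, 0),
                            noise_sd = c(0.005, 0.01),
                            scr_amplitude = c(0.5, 0.9)),
    hard = phenotype_ranges(responder_prob = c(0.4, 0.4),
                            spurious_rate = c(0, 0),
                            noise_sd = c(0.005, 0.01),
                            scr_amplitude = c(0.5, 0.9))
  )
}

#' Experiment configuration
#'
#' Collects all stage parameters; every stochastic stage derives its seed
#' from `rng_seed` plus the stage name, so one integer reproduces a run.
#'
#' @param rng_seed global seed.
#' @param n_subjects cohort size.
#' @param preset cohort preset, see [cohort_preset()].
#' @param split_seeds seeds of the subject-level train/test splits.
#' @param n_test_subjects held-out subjects per split (10 of 28 by default).
#' @param channels `"eda"` or `c("eda","st")`.
#' @param K DGE ensemble size.
#' @param outer_M outer homogeneous ensemble size (1 = DGE only).
#' @param generator `"bootstrap"` or `"cgan"`.
#' @param train_stride_s window stride for training sets (evaluation always
#'   uses stride 1); larger strides cut training cost.
#' @param hidden_size,lr,epochs,patience,batch_size classifier training.
#' @param threshold probability cutoff for events.
#' @param ig_steps Integrated-Gradients steps for the report map.
#' @param ig_max_windows cap of windows averaged in the global map.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(rng_seed = 1L, n_subjects = 28,
                              preset = "easy", split_seeds = 1:3,
                              n_test_subjects = 10,
                              channels = c("eda", "st"), K = 5, outer_M = 1,
                              generator = "bootstrap", train_stride_s = 2,
                              hidden_size = 8, lr = 1e-2, epochs = 40,
                              patience = 5, batch_size = 128,
                              threshold = 0.5, ig_steps = 64,
                              ig_max_windows = 60) {
  structure(as.list(environment()), class = "experiment_config")
}

#' Rule-based stand-in detector: phasic peaks over a z-threshold
#'
#' Simple comparator for the learned models (the published rule-based
#' systems live elsewhere): flags local maxima of the standardized phasic
#' EDA above `z_threshold`, with a minimum separation between events.
#'
#' @param frec a `filtered_recording` (1 Hz, standardized).
#' @param z_threshold detection threshold in standardized units.
#' @param min_sep_s minimum time between detections, seconds.
#' @return numeric prediction times, seconds.
#' @export
baseline_detector <- function(frec, z_threshold = 1, min_sep_s = 8) {
  x <- frec$phasic_eda
  n <- length(x)
  if (n < 3) return(numeric(0))
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
               FALSE) & x >= z_threshold
  t <- (which(is_peak) - 1) / frec$sampling_rate
  merge_predictions(t, min_sep_s)
}

#' Run the full pipeline: simulate, preprocess, train, predict, explain,
#' evaluate
#'
#' For each split seed: hold out `n_test_subjects` subjects, train a DGE
#' (optionally wrapped in an outer homogeneous ensemble) on the remaining
#' subjects' windows, convert held-out window probabilities to moments of
#' stress, and score them against the protocol with the -2 s/+6 s matching
#' and 8 s merge/negative windows. Also scores the rule-based stand-in
#' detector, and computes a cohort-averaged Integrated-Gradients map on the
#' first split's test stress windows.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for the report files (metrics JSON,
#'   attribution CSV, manifest JSON).
#' @param verbose print per-stage progress.
#' @return an `experiment_report`: per-seed and mean metrics for the
#'   detectors, the global attribution, and the run manifest.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  cohort <- gen_cohort(config$n_subjects, cohort_preset(config$preset),
                       rng_seed = derive_seed(config$rng_seed, "simulate"))
  say("simulated %d subjects", config$n_subjects)
  wd_eval <- window_cohort(cohort, channels = config$channels, stride_s = 1)
  frecs <- attr(wd_eval, "filtered")
  wd_train_all <- if (config$train_stride_s == 1) wd_eval else
    window_cohort(cohort, channels = config$channels,
                  stride_s = config$train_stride_s)
  subjects <- vapply(cohort$recordings, `[[`, "", "subject_id")
  say("windowed: %d eval / %d train windows",
      dim(wd_eval$windows)[1], dim(wd_train_all$windows)[1])

  seed_rows <- list()
  attribution <- NULL
  for (si in seq_along(config$split_seeds)) {
    ss <- config$split_seeds[si]
    test_subs <- with_seed(derive_seed(config$rng_seed, paste0("split", ss)),
                           sample(subjects, config$n_test_subjects))
    tr_wd <- wd_subset(wd_train_all, !(wd_train_all$subject_ids %in% test_subs))
    model_seed <- derive_seed(config$rng_seed, paste0("model", ss))
    model <- if (config$outer_M > 1) {
      lstm_ensemble(tr_wd, M = config$outer_M, inner = "dge",
                    rng_seed = model_seed, K = config$K,
                    generator = config$generator,
                    hidden_size = config$hidden_size, lr = config$lr,
                    epochs = config$epochs, patience = config$patience,
                    batch_size = config$batch_size)
    } else {
      dge_train(tr_wd, K = config$K, generator = config$generator,
                rng_seed = model_seed,
                hidden_size = config$hidden_size, lr = config$lr,
                epochs = config$epochs, patience = config$patience,
                batch_size = config$batch_size)
    }
    say("seed %s: trained %s (K=%d, M=%d)", ss,
        if (config$outer_M > 1) "outer ensemble" else "DGE",
        config$K, config$outer_M)
    evs_model <- list(); evs_base <- list()
    for (sub in test_subs) {
      k <- which(subjects == sub)
      wd_sub <- wd_subset(wd_eval, wd_eval$subject_ids == sub)
      proto <- cohort$recordings[[k]]$protocol
      evs_model[[sub]] <- evaluate_subject(model, wd_sub, proto,
                                           threshold = config$threshold)
      evs_base[[sub]] <- match_events(
        baseline_detector(frecs[[k]]), proto$stressor_times,
        session_duration = proto$session_duration)
    }
    sm <- pool_evaluations(evs_model)
    sb <- pool_evaluations(evs_base)
    seed_rows[[si]] <- data.frame(
      seed = ss,
      model = c("lstm_dge", "baseline"),
      recall = c(sm$recall, sb$recall),
      precision = c(sm$precision, sb$precision),
      accuracy = c(sm$accuracy, sb$accuracy),
      f1 = c(sm$f1, sb$f1),
      tp = c(sm$tp, sb$tp), fp = c(sm$fp, sb$fp),
      fn = c(sm$fn, sb$fn), tn = c(sm$tn, sb$tn))
    if (si == 1) {
      test_wd <- wd_subset(wd_eval, wd_eval$subject_ids %in% test_subs)
      attribution <- global_attribution(model, test_wd, class_condition = 1,
                                        n_steps = config$ig_steps,
                                        max_windows = config$ig_max_windows)
      say("seed %s: attribution over %d stress windows", ss,
          attribution$n_windows_averaged)
    }
  }
  per_seed <- do.call(rbind, seed_rows)
  mean_metrics <- stats::aggregate(
    per_seed[, c("recall", "precision", "accuracy", "f1")],
    by = list(model = per_seed$model), FUN = mean, na.rm = TRUE)
  report <- structure(list(
    per_seed = per_seed, mean_metrics = mean_metrics,
    attribution = attribution,
    manifest = list(config = unclass(config),
                    fingerprint = config_fingerprint(unclass(config)),
                    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "experiment_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(per_seed = per_seed, mean = mean_metrics,
                              manifest = report$manifest),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows")
    write_attribution_csv(attribution, file.path(out_dir, "global_attribution.csv"))
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> mean metrics over",
      length(unique(x$per_seed$seed)), "split seed(s):\n")
  print(x$mean_metrics, row.names = FALSE)
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages:
#' \describe{
#'   \item{`simulate`}{write a cohort as per-subject CSV/JSON files.}
#'   \item{`preprocess`}{filter + window a simulated cohort directory into a
#'     windows CSV.}
#'   \item{`train`}{train a DGE on a windows CSV, save a checkpoint dir.}
#'   \item{`predict`}{write per-window probabilities for a windows CSV.}
#'   \item{`explain`}{write a cohort-averaged attribution CSV.}
#'   \item{`evaluate`}{score a predictions CSV against a protocol JSON.}
#'   \item{`experiment`}{full pipeline from a JSON config.}
#' }
#' Exit codes: 0 success, 2 configuration error, 3 data error.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: stressdge <simulate|preprocess|train|predict|explain|evaluate|experiment> [options]",
    "  simulate   --out DIR [--subjects N] [--preset easy|hard|default] [--seed S]",
    "  preprocess --in DIR --out windows.csv [--stride N] [--channels eda,st]",
    "  train      --windows windows.csv --out MODELDIR [--K N] [--seed S] [--epochs N]",
    "  predict    --model MODELDIR --windows windows.csv --out pred.csv",
    "  explain    --model MODELDIR --windows windows.csv --out attribution.csv [--steps N]",
    "  evaluate   --predictions pred.csv --protocol protocol.json --out metrics.json",
    "  experiment --out DIR [--config config.json] [--seed S]",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(2L)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  res <- tryCatch({
    switch(cmd,
      simulate = {
        out <- opt("out"); if (is.null(out)) stop("--out is required", call. = FALSE)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        co <- gen_cohort(as.integer(opt("subjects", "28")),
                         cohort_preset(opt("preset", "default")),
                         rng_seed = as.integer(opt("seed", "1")))
        for (rec in co$recordings) {
          write_recording_csv(rec, file.path(out, paste0(rec$subject_id, ".csv")))
          write_protocol_json(rec$protocol,
                              file.path(out, paste0(rec$subject_id, "_protocol.json")),
                              subject_id = rec$subject_id)
        }
        utils::write.csv(co$manifest, file.path(out, "manifest.csv"), row.names = FALSE)
        message("wrote ", length(co$recordings), " recordings to ", out)
        0L
      },
      preprocess = {
        ind <- opt("in"); out <- opt("out")
        if (is.null(ind) || is.null(out)) stop("--in and --out are required", call. = FALSE)
        chans <- strsplit(opt("channels", "eda,st"), ",")[[1]]
        csvs <- sort(list.files(ind, pattern = "^S\\d+\\.csv$", full.names = TRUE))
        if (!length(csvs)) stop("no subject CSVs found in ", ind)
        wds <- lapply(csvs, function(f) {
          rec <- read_recording_csv(f, sub("\\.csv$", "_protocol.json", f))
          make_windows(preprocess_recording(rec, channels = chans),
                       stride_s = as.numeric(opt("stride", "1")))
        })
        write_windows_csv(do.call(wd_bind, wds), out)
        message("wrote ", out)
        0L
      },
      train = {
        wpath <- opt("windows"); out <- opt("out")
        if (is.null(wpath) || is.null(out)) stop("--windows and --out are required", call. = FALSE)
        wd <- read_windows_csv(wpath)
        ens <- dge_train(wd, K = as.integer(opt("K", "5")),
                         generator = opt("generator", "bootstrap"),
                         rng_seed = as.integer(opt("seed", "1")),
                         epochs = as.integer(opt("epochs", "40")))
        save_ensemble(ens, out)
        message("wrote ", out)
        0L
      },
      predict = {
        mpath <- opt("model"); wpath <- opt("windows"); out <- opt("out")
        if (is.null(mpath) || is.null(wpath) || is.null(out))
          stop("--model, --windows and --out are required", call. = FALSE)
        ens <- load_ensemble(mpath)
        wd <- read_windows_csv(wpath)
        utils::write.csv(data.frame(subject_id = wd$subject_ids,
                                    time_s = wd$window_start_s,
                                    probability = dge_predict(ens, wd)),
                         out, row.names = FALSE)
        message("wrote ", out)
        0L
      },
      explain = {
        mpath <- opt("model"); wpath <- opt("windows"); out <- opt("out")
        if (is.null(mpath) || is.null(wpath) || is.null(out))
          stop("--model, --windows and --out are required", call. = FALSE)
        ens <- load_ensemble(mpath)
        wd <- read_windows_csv(wpath)
        g <- global_attribution(ens, wd,
                                class_condition = as.integer(opt("class", "1")),
                                n_steps = as.integer(opt("steps", "128")),
                                max_windows = as.numeric(opt("max-windows", "200")))
        write_attribution_csv(g, out)
        message("wrote ", out)
        0L
      },
      experiment = {
        out <- opt("out"); if (is.null(out)) stop("--out is required", call. = FALSE)
        cfg <- experiment_config(rng_seed = as.integer(opt("seed", "1")))
        cfg_path <- opt("config")
        if (!is.null(cfg_path)) {
          ov <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
          for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
        }
        rep <- run_experiment(cfg, out_dir = out, verbose = TRUE)
        print(rep)
        0L
      },
      evaluate = {
        pred_path <- opt("predictions"); proto_path <- opt("protocol")
        if (is.null(pred_path) || is.null(proto_path))
          stop("--predictions and --protocol are required", call. = FALSE)
        df <- utils::read.csv(pred_path)
        proto <- read_protocol_json(proto_path)
        times <- prob_to_events(df$probability, df$time_s,
                                threshold = as.numeric(opt("threshold", "0.5")))
        ev <- match_events(times, proto$stressor_times,
                           session_duration = proto$session_duration)
        s <- score_events(ev)
        out <- opt("out", "metrics.json")
        jsonlite::write_json(s, out, auto_unbox = TRUE, digits = 10)
        message("wrote ", out)
        0L
      },
      { cat(usage, "\n"); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("required|usage|unknown", conditionMessage(e))) 2L else 3L
  })
  invisible(res)
}
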