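#' Merge nearby stress predictions
#'
#' Greedy left-to-right clustering: a prediction joins the current cluster
#' while it is within `merge_window_s` of the cluster's first member; each
#' cluster is represented by its earliest time. Prevents an artificially
#' high number of detections when consecutive windows fire.
#'
#' @param times sorted numeric prediction times, seconds.
#' @param merge_window_s merge span, seconds (default 8).
#' @param representative `"earliest"` (default) or `"median"` cluster member.
#'   The median is robust when a run of consecutive firing windows starts
#'   right at the edge of the asymmetric matching window.
#' @return merged representative times.
#' @export
merge_predictions <- function(times, merge_window_s = 8,
                              representative = c("earliest", "median")) {
  representative <- match.arg(representative)
  if (!length(times)) return(numeric(0))
  if (is.unsorted(times)) stop("prediction times must be sorted")
  first <- times[1]
  cluster <- list(first)
  for (t in times[-1]) {
    if (t - first > merge_window_s) {
      first <- t
      cluster[[length(cluster) + 1]] <- t
    } else {
      cluster[[length(cluster)]] <- c(cluster[[length(cluster)]], t)
    }
  }
  vapply(cluster, function(cl)
    if (representative == "earliest") cl[1] else stats::median(cl), 0)
}

#' Match predicted moments of stress to reference stressors
#'
#' A prediction p is a true positive when it falls in the asymmetric window
#' `[r - pre_s, r + post_s]` of a reference stressor r (default 2 s before,
#' 6 s after); matching is earliest-prediction-first and one-to-one. Every
#' unmatched reference is a false negative (each reference contributes to
#' exactly one of TP/FN). An unmatched prediction with no reference within
#' `neg_window_s` is a false positive; unmatched predictions that lie within
#' `neg_window_s` of some reference (but outside its matching window, or the
#' reference was already taken) are dropped as ambiguous and reported in
#' `n_ignored`. True negatives are counted over non-overlapping
#' `neg_window_s` slots tiling the session that contain neither a prediction
#' nor a reference.
#'
#' @param predictions sorted merged prediction times, seconds.
#' @param references sorted reference stressor times, seconds.
#' @param pre_s,post_s matching window, seconds before/after a reference.
#' @param neg_window_s negative/merge window, seconds (default 8).
#' @param session_duration seconds, used for the TN slot grid.
#' @return An `event_evaluation`: `tp`, `fp`, `fn`, `tn`, `n_ignored`,
#'   `matched_pairs` (data.frame), plus the inputs.
#' @export
match_events <- function(predictions, references, pre_s = 2, post_s = 6,
                         neg_window_s = 8, session_duration = NULL) {
  if (is.unsorted(predictions) || is.unsorted(references)) {
    stop("prediction and reference times must be sorted")
  }
  matched_ref <- rep(FALSE, length(references))
  matched_pred <- rep(FALSE, length(predictions))
  pairs <- list()
  for (i in seq_along(predictions)) {
    p <- predictions[i]
    cand <- which(!matched_ref &
                    p >= references - pre_s & p <= references + post_s)
    if (length(cand)) {
      r <- cand[1]  # earliest available reference
      matched_ref[r] <- TRUE
      matched_pred[i] <- TRUE
      pairs[[length(pairs) + 1]] <-
        data.frame(prediction_time = p, reference_time = references[r])
    }
  }
  tp <- sum(matched_pred)
  fn <- sum(!matched_ref)  # every reference is TP or FN
  near_ref <- function(p) any(abs(p - references) <= neg_window_s)
  un <- predictions[!matched_pred]
  fp <- sum(!vapply(un, near_ref, logical(1)))
  n_ignored <- length(un) - fp
  tn <- 0L
  if (!is.null(session_duration)) {
    starts <- seq(0, session_duration - neg_window_s, by = neg_window_s)
    in_slot <- function(x, s) any(x >= s & x < s + neg_window_s)
    tn <- sum(vapply(starts, function(s)
      !in_slot(predictions, s) && !in_slot(references, s), logical(1)))
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n_ignored = n_ignored,
                 matched_pairs = if (length(pairs)) do.call(rbind, pairs)
                                 else data.frame(prediction_time = numeric(0),
                                                 reference_time = numeric(0)),
                 predictions = predictions, references = references,
                 pre_s = pre_s, post_s = post_s, neg_window_s = neg_window_s,
                 session_duration = session_duration),
            class = "event_evaluation")
}

#' Confusion-matrix metrics for an event evaluation
#'
#' recall = tp/(tp+fn), precision = tp/(tp+fp),
#' accuracy = (tp+tn)/(tp+fp+fn+tn), f1 harmonic mean. Undefined ratios
#' (zero denominators) are reported as `NA`, not 0.
#'
#' @param ev an `event_evaluation` (or a list with tp/fp/fn/tn counts).
#' @return named list recall/precision/accuracy/f1 plus the counts.
#' @export
score_events <- function(ev) {
  tp <- ev$tp; fp <- ev$fp; fn <- ev$fn; tn <- ev$tn %||% 0
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- rat(tp, tp + fn)
  precision <- rat(tp, tp + fp)
  accuracy <- rat(tp + tn, tp + fp + fn + tn)
  f1 <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       recall = recall, precision = precision, accuracy = accuracy, f1 = f1)
}

#' Convert window probabilities to prediction times
#'
#' A window predicts a moment of stress at `window_start_s + offset_s` when
#' its probability reaches `threshold`; times are then merged with the
#' `neg_window_s` rule. The median cluster member is used as the event time:
#' at 1 Hz a run of firing windows starts at the very edge of the -2 s
#' matching bound, so the earliest member would flip between hit and miss
#' with the fractional part of the true stressor time.
#'
#' @param prob window probabilities.
#' @param window_start_s window start times, seconds.
#' @param threshold probability cutoff.
#' @param offset_s event time relative to window start (default 0).
#' @param merge_window_s merge span, seconds.
#' @param representative cluster representative, see [merge_predictions()].
#' @return merged prediction times.
#' @export
prob_to_events <- function(prob, window_start_s, threshold = 0.5,
                           offset_s = 0, merge_window_s = 8,
                           representative = "median") {
  t <- sort(window_start_s[prob >= threshold] + offset_s)
  merge_predictions(t, merge_window_s, representative)
}

#' Event-level evaluation of a classifier on one subject
#'
#' @param model classifier or ensemble.
#' @param wd that subject's `windowed_dataset` (stride-1 windows).
#' @param protocol the subject's `stimulus_protocol`.
#' @param threshold probability cutoff.
#' @param ... passed to [match_events()].
#' @return an `event_evaluation`.
#' @export
evaluate_subject <- function(model, wd, protocol, threshold = 0.5, ...) {
  p <- predict_prob(model, wd)
  ev_times <- prob_to_events(p, wd$window_start_s, threshold = threshold)
  match_events(ev_times, protocol$stressor_times,
               session_duration = protocol$session_duration, ...)
}

#' Pool event evaluations over subjects
#' @param evs list of `event_evaluation`.
#' @return pooled metrics from summed counts (see [score_events()]).
#' @export
pool_evaluations <- function(evs) {
  tot <- list(tp = sum(vapply(evs, `[[`, 0L, "tp")),
              fp = sum(vapply(evs, `[[`, 0L, "fp")),
              fn = sum(vapply(evs, `[[`, 0L, "fn")),
              tn = sum(vapply(evs, `[[`, 0L, "tn")))
  score_events(tot)
}

#' @export
print.event_evaluation <- function(x, ...) {
  s <- score_events(x)
  cat(sprintf("<event_evaluation> tp=%d fp=%d fn=%d tn=%d | recall %.3f precision %.3f accuracy %.3f\n",
              x$tp, x$fp, x$fn, x$tn,
              s$recall %||% NA, s$precision %||% NA, s$accuracy %||% NA))
  invisible(x)
}
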