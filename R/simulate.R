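#' Generate a stimulus protocol
#'
#' Draws stressor times for one laboratory-style session: after a fixed
#' baseline (initiation) phase, `n_stressors` audio stimuli are placed with
#' independent uniform inter-stimulus gaps in `[gap_min, gap_max]` seconds.
#' The defaults mirror a protocol of 10 stimuli at random intervals of
#' 52-125 s (mean gap 88.5 s, the uniform midpoint).
#'
#' When `duration` is given, gap sets are redrawn until the last stressor
#' fits inside the session; when `duration = NULL` the session length is
#' defined as the last stressor time plus `tail_s`.
#'
#' @param duration session length in seconds, or `NULL` to let the gaps set it.
#' @param n_stressors number of stimuli (>= 1).
#' @param gap_min,gap_max inter-stimulus gap bounds in seconds.
#' @param baseline_s baseline phase before the first stimulus, seconds.
#' @param tail_s trailing quiet phase when `duration` is `NULL`, seconds.
#' @param rng_seed integer seed; protocols are deterministic given the seed.
#' @return A `stimulus_protocol`: list with `session_duration`,
#'   `stressor_times`, `n_stressors`, `baseline_s`.
#' @export
gen_protocol <- function(duration = NULL, n_stressors = 10,
                         gap_min = 52, gap_max = 125,
                         baseline_s = 60, tail_s = 60, rng_seed = 1L) {
  stopifnot(n_stressors >= 1, gap_min < gap_max, gap_min > 0)
  min_dur <- baseline_s + n_stressors * gap_min
  if (!is.null(duration) && duration < min_dur) {
    stop(sprintf(
      "duration %.0f s infeasible: need at least %.0f s (baseline %.0f + %d gaps of >= %.0f s)",
      duration, min_dur, baseline_s, n_stressors, gap_min))
  }
  times <- with_seed(rng_seed, {
    for (try in 1:1000) {
      gaps <- stats::runif(n_stressors, gap_min, gap_max)
      tt <- baseline_s + cumsum(gaps)
      if (is.null(duration) || tt[n_stressors] <= duration) break
      tt <- NULL
    }
    tt
  })
  if (is.null(times)) {
    stop(sprintf("could not place %d stressors inside %.0f s after 1000 draws; need about %.0f s",
                 n_stressors, duration, baseline_s + n_stressors * (gap_min + gap_max) / 2))
  }
  structure(list(
    session_duration = if (is.null(duration)) times[n_stressors] + tail_s else duration,
    stressor_times = times,
    n_stressors = n_stressors,
    baseline_s = baseline_s
  ), class = "stimulus_protocol")
}

#' Phasic skin-conductance response kernel
#'
#' Bateman-style bi-exponential waveform parameterized directly by the three
#' features used to describe an SCR: latency (stimulus to onset), rise time
#' (onset to peak) and recovery time constant (peak back toward baseline).
#' The waveform is zero before `latency`, rises monotonically to a single
#' maximum equal to `amplitude` at `latency + rise`, then decays
#' monotonically with time constant `recovery`.
#'
#' Internally the fast time constant of the bi-exponential is solved (by
#' root finding) so that the analytic peak falls exactly at `latency + rise`;
#' this requires `rise < recovery`.
#'
#' @param latency,rise,recovery time constants in seconds, all > 0 and
#'   `rise < recovery`.
#' @param amplitude peak height in microsiemens (> 0, or 0 for a null kernel).
#' @param sampling_rate Hz.
#' @param duration kernel support in seconds (default covers the decay).
#' @return numeric waveform sampled at `sampling_rate`.
#' @export
gen_scr_kernel <- function(latency, rise, recovery, amplitude,
                           sampling_rate = 4,
                           duration = latency + rise + 5 * recovery) {
  stopifnot(latency > 0, rise > 0, recovery > 0)
  if (amplitude < 0) stop("amplitude must be non-negative")
  n <- max(1L, round(duration * sampling_rate))
  t <- (seq_len(n) - 1) / sampling_rate
  if (amplitude == 0) return(numeric(n))
  if (rise >= recovery) {
    stop("rise must be smaller than recovery for a bi-exponential kernel")
  }
  # peak time of exp(-s/tau2) - exp(-s/tau1): s* = (tau1 tau2)/(tau2 - tau1) log(tau2/tau1)
  tau2 <- recovery
  f <- function(tau1) (tau1 * tau2) / (tau2 - tau1) * log(tau2 / tau1) - rise
  tau1 <- stats::uniroot(f, c(1e-6, tau2 * (1 - 1e-9)), tol = 1e-12)$root
  s <- t - latency
  w <- ifelse(s <= 0, 0, exp(-s / tau2) - exp(-s / tau1))
  peak <- exp(-rise / tau2) - exp(-rise / tau1)
  amplitude * w / peak
}

#' Subject phenotype for the simulator
#'
#' Bundles the per-subject parameters that shape a synthetic recording:
#' stressor responsiveness, SCR shape, spurious (non-stimulus) SCR rate,
#' tonic level/drift, skin-temperature baseline and response slope, and the
#' additive measurement noise.
#'
#' @param responder_prob probability that a stimulus elicits an SCR.
#' @param scr_amplitude SCR peak, microsiemens.
#' @param scr_latency,scr_rise,scr_recovery SCR shape, seconds.
#' @param spurious_rate spontaneous SCRs per minute.
#' @param tonic_level tonic skin conductance, microsiemens.
#' @param tonic_drift tonic drift, microsiemens per minute.
#' @param st_baseline skin temperature baseline, degrees C.
#' @param st_response_slope post-stimulus temperature slope, degrees C per
#'   second (default 0: temperature carries no stress signal).
#' @param noise_sd additive Gaussian noise sd, signal units.
#' @return A `subject_phenotype` list.
#' @export
phenotype <- function(responder_prob = 1, scr_amplitude = 0.6,
                      scr_latency = 1.5, scr_rise = 2.5, scr_recovery = 6,
                      spurious_rate = 0.3, tonic_level = 2, tonic_drift = 0.02,
                      st_baseline = 33, st_response_slope = 0,
                      noise_sd = 0.02) {
  stopifnot(responder_prob >= 0, responder_prob <= 1,
            scr_latency > 0, scr_rise > 0, scr_recovery > 0,
            spurious_rate >= 0, noise_sd >= 0, scr_amplitude >= 0)
  structure(as.list(environment()), class = "subject_phenotype")
}

#' Generate one synthetic recording
#'
#' EDA = tonic level + drift + one SCR kernel per responded stimulus +
#' Poisson-placed spurious SCRs + Gaussian noise. Skin temperature =
#' baseline + a slow post-stimulus slope change (scaled by
#' `st_response_slope`) + noise. Sampled at 4 Hz like the wristband device.
#'
#' @param protocol a `stimulus_protocol`.
#' @param phen a `subject_phenotype`.
#' @param rng_seed integer seed.
#' @param subject_id identifier stored with the recording.
#' @param sampling_rate Hz (device rate, default 4).
#' @return A `recording`: list with `subject_id`, `sampling_rate`, `eda`,
#'   `st`, `protocol`, and `responded` (logical per stressor, ground truth).
#' @export
gen_recording <- function(protocol, phen, rng_seed = 1L,
                          subject_id = "S1", sampling_rate = 4) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(phen, "subject_phenotype"))
  n <- round(protocol$session_duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  with_seed(rng_seed, {
    eda <- phen$tonic_level + phen$tonic_drift * t / 60
    responded <- stats::runif(protocol$n_stressors) < phen$responder_prob
    add_scr <- function(eda, onset, amp) {
      if (amp <= 0) return(eda)
      k <- gen_scr_kernel(phen$scr_latency, phen$scr_rise, phen$scr_recovery,
                          amp, sampling_rate)
      i0 <- floor(onset * sampling_rate) + 1
      idx <- i0:min(n, i0 + length(k) - 1)
      eda[idx] <- eda[idx] + k[seq_along(idx)]
      eda
    }
    for (j in seq_len(protocol$n_stressors)) {
      if (responded[j]) eda <- add_scr(eda, protocol$stressor_times[j], phen$scr_amplitude)
    }
    # spontaneous SCRs: homogeneous Poisson process, amplitudes 50-100% of scr_amplitude
    n_sp <- stats::rpois(1, phen$spurious_rate * protocol$session_duration / 60)
    sp_times <- sort(stats::runif(n_sp, 0, protocol$session_duration - 1))
    sp_amps <- stats::runif(n_sp, 0.5, 1) * phen$scr_amplitude
    for (j in seq_len(n_sp)) eda <- add_scr(eda, sp_times[j], sp_amps[j])
    eda <- eda + stats::rnorm(n, 0, phen$noise_sd)

    st <- rep(phen$st_baseline, n)
    if (phen$st_response_slope != 0) {
      # slope change lasting 20 s after each stimulus, then held
      for (tt in protocol$stressor_times) {
        dt <- pmin(pmax(t - tt, 0), 20)
        st <- st + phen$st_response_slope * dt
      }
    }
    st <- st + stats::rnorm(n, 0, phen$noise_sd)
    structure(list(subject_id = subject_id, sampling_rate = sampling_rate,
                   eda = eda, st = st, protocol = protocol,
                   responded = responded, spurious_times = sp_times),
              class = "recording")
  })
}

#' Default phenotype ranges for a cohort
#'
#' Ranges (min, max) from which per-subject phenotypes are drawn uniformly.
#' A point range `c(v, v)` fixes the field.
#'
#' @param ... named `c(min, max)` overrides for phenotype fields.
#' @return named list of length-2 numeric ranges.
#' @export
phenotype_ranges <- function(...) {
  r <- list(
    responder_prob = c(1, 1), scr_amplitude = c(0.3, 0.9),
    scr_latency = c(1, 2.5), scr_rise = c(1.5, 3.5), scr_recovery = c(4.5, 7.5),
    spurious_rate = c(0, 0.6), tonic_level = c(1, 8), tonic_drift = c(-0.05, 0.08),
    st_baseline = c(31, 35), st_response_slope = c(0, 0), noise_sd = c(0.01, 0.04)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(r)) stop("unknown phenotype field: ", nm)
    stopifnot(length(ov[[nm]]) == 2)
    r[[nm]] <- as.numeric(ov[[nm]])
  }
  r
}

#' Generate a synthetic cohort
#'
#' One recording per subject, phenotype drawn uniformly from `ranges`,
#' sessions of 10 stimuli with 52-125 s gaps and durations constrained to
#' 15-22 minutes. Returns the recordings plus a manifest of the true
#' phenotypes and per-subject seeds for recovery tests.
#'
#' @param n_subjects cohort size (default 28).
#' @param ranges from [phenotype_ranges()].
#' @param rng_seed integer seed.
#' @param n_stressors,gap_min,gap_max protocol parameters.
#' @param duration_range_s session duration bounds, seconds.
#' @return A `cohort`: list with `recordings` (list of `recording`) and
#'   `manifest` (data.frame of subject ids, seeds, durations, phenotypes).
#' @export
gen_cohort <- function(n_subjects = 28, ranges = phenotype_ranges(),
                       rng_seed = 1L, n_stressors = 10,
                       gap_min = 52, gap_max = 125,
                       duration_range_s = c(900, 1320)) {
  stopifnot(n_subjects >= 1)
  if (!length(ranges)) stop("empty phenotype ranges")
  draws <- with_seed(rng_seed, {
    lapply(seq_len(n_subjects), function(i) {
      ph <- lapply(ranges, function(rg) stats::runif(1, rg[1], rg[2]))
      list(phen = ph,
           duration = stats::runif(1, duration_range_s[1], duration_range_s[2]),
           proto_seed = sample.int(2^30, 1), rec_seed = sample.int(2^30, 1))
    })
  })
  recs <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    d <- draws[[i]]
    ph <- do.call(phenotype, d$phen)
    proto <- gen_protocol(duration = d$duration, n_stressors = n_stressors,
                          gap_min = gap_min, gap_max = gap_max,
                          rng_seed = d$proto_seed)
    sid <- sprintf("S%02d", i)
    recs[[i]] <- gen_recording(proto, ph, rng_seed = d$rec_seed, subject_id = sid)
    rows[[i]] <- data.frame(subject_id = sid, proto_seed = d$proto_seed,
                            rec_seed = d$rec_seed,
                            session_duration_s = proto$session_duration,
                            as.data.frame(d$phen))
  }
  structure(list(recordings = recs, manifest = do.call(rbind, rows),
                 rng_seed = rng_seed),
            class = "cohort")
}

#' Ground-truth label stream at 1 Hz
#'
#' Marks second `floor(t)` for each stressor time `t`; the stream and the
#' stressor times are mutually recoverable.
#'
#' @param protocol a `stimulus_protocol`.
#' @return integer 0/1 vector of length `ceiling(session_duration)`.
#' @export
labels_from_protocol <- function(protocol) {
  n <- ceiling(protocol$session_duration)
  lab <- integer(n)
  lab[floor(protocol$stressor_times) + 1] <- 1L
  lab
}

#' Recover stressor times from a 1 Hz label stream
#' @param labels 0/1 vector from [labels_from_protocol()].
#' @return numeric stressor seconds.
#' @export
stressors_from_labels <- function(labels) which(labels == 1L) - 1

#' Write / read a recording as CSV (time_s, eda_uS, st_C)
#' @param rec a `recording`.
#' @param path CSV file path.
#' @export
write_recording_csv <- function(rec, path) {
  n <- length(rec$eda)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sampling_rate,
                   eda_uS = rec$eda, st_C = rec$st)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param protocol_path JSON file with the protocol (see
#'   [write_protocol_json()]); required to rebuild a full `recording`.
#' @export
read_recording_csv <- function(path, protocol_path) {
  df <- utils::read.csv(path)
  proto <- read_protocol_json(protocol_path)
  sr <- 1 / stats::median(diff(df$time_s))
  structure(list(subject_id = attr(proto, "subject_id") %||% "S?",
                 sampling_rate = round(sr), eda = df$eda_uS, st = df$st_C,
                 protocol = proto),
            class = "recording")
}

#' Write / read a stimulus protocol as JSON
#' @param protocol a `stimulus_protocol`.
#' @param path JSON file path.
#' @param subject_id stored alongside the protocol.
#' @export
write_protocol_json <- function(protocol, path, subject_id = "S?") {
  jsonlite::write_json(
    list(subject_id = subject_id,
         session_duration_s = protocol$session_duration,
         baseline_s = protocol$baseline_s,
         stressor_times_s = protocol$stressor_times),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- structure(list(session_duration = x$session_duration_s,
                      stressor_times = as.numeric(x$stressor_times_s),
                      n_stressors = length(x$stressor_times_s),
                      baseline_s = x$baseline_s %||% 60),
                 class = "stimulus_protocol")
  attr(p, "subject_id") <- x$subject_id
  p
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %d stressors over %.0f s (baseline %.0f s)\n",
              x$n_stressors, x$session_duration, x$baseline_s))
  invisible(x)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %.1f min at %g Hz, %d stressors\n",
              x$subject_id, length(x$eda) / x$sampling_rate / 60,
              x$sampling_rate, x$protocol$n_stressors))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (seed %s)\n", length(x$recordings),
              format(x$rng_seed)))
  invisible(x)
}
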