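#' Synthetic-generator configuration
#'
#' Parameters of the synthetic sedation-recording generator.  The
#' generator targets the statistical structure the measures read, not
#' biophysics: band-limited Gaussian components with state-dependent
#' gains, a state-dependent alpha peak frequency, an EMG-like broadband
#' 60-145 Hz component whose gain and regularity depend on the latent
#' responsiveness state, optional mains interference and Poisson-placed
#' peak artifacts.
#'
#' `effect_size` scales every between-state parameter gap; at 0 the two
#' states are statistically identical (a null generator), and the gaps
#' grow linearly with it.
#'
#' @param n_per_class Number of RSS events per latent class
#'   (responsive / unresponsive), default 100.
#' @param effect_size Standardized separation knob (>= 0), default 1.
#' @param fs Native sampling rate in Hz, default 300.
#' @param emg_gain Baseline gain of the EMG-like 60-145 Hz component.
#' @param artifact_rate High-amplitude peak artifacts per minute
#'   (default 0.5: occasional, as in clinically usable recordings).
#' @param mains_amp Amplitude (uV) of the 50/100 Hz interference.
#' @param seed Integer RNG seed: records are bit-reproducible given the
#'   config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_class = 100L, effect_size = 1,
                             fs = 300, emg_gain = 1, artifact_rate = 0.5,
                             mains_amp = 1, seed = 1L) {
  stopifnot(effect_size >= 0, artifact_rate >= 0, n_per_class >= 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 effect_size = effect_size, fs = fs,
                 emg_gain = emg_gain, artifact_rate = artifact_rate,
                 mains_amp = mains_amp, seed = as.integer(seed)),
            class = "generator_config")
}

# State-dependent generator parameters; every gap scales with
# effect_size and vanishes at 0 (null generator).  Complexity contrasts
# are driven by bandwidth: a narrowband component has a long
# correlation time (high AMIF mean over the 1 s horizon) and, placed in
# the upper VHF range, high lag-1 predictability (low first decay).
.state_params <- function(es) {
  clamp <- function(x, lo = 0.02, hi = Inf) pmin(pmax(x, lo), hi)
  wfrac <- function(x) min(0.85, x)    # narrowband power fraction cap
  list(
    responsive = list(
      delta_gain   = 1.0,
      theta_gain   = 1.0,
      theta_narrow = wfrac(0.45 * es), # regular theta when responsive
      alpha_peak   = 10 + 0.5 * es,
      beta_gain    = clamp(1.0 + 0.25 * es),
      emg_gain     = clamp(1.0 + 0.35 * es),
      emg_narrow   = 0),
    unresponsive = list(
      delta_gain   = clamp(1.0 + 0.20 * es),
      theta_gain   = clamp(1.0 + 0.10 * es),
      theta_narrow = 0,                # broadband theta when sedated
      alpha_peak   = 10 - 0.5 * es,
      beta_gain    = clamp(1.0 - 0.25 * es),
      emg_gain     = clamp(1.0 - 0.35 * es),
      emg_narrow   = wfrac(0.45 * es)))# synchronised SEMG when sedated
}

#' Sedation profile: latent states, events and concentration ramps
#'
#' Lays out one epoch per event: the latent responsiveness state is a
#' two-state step process, effect-site concentrations ramp linearly
#' during the first `ramp_len` seconds of each epoch and stay flat
#' afterwards, and the event is annotated near the epoch end so the
#' pre-event analysis span falls entirely in the stable part.
#' Unresponsive epochs carry RSS = 6 events; responsive epochs carry
#' RSS drawn from 2..5.
#'
#' @param cfg A [generator_config()].
#' @param epoch_len Epoch length in seconds (default 130).
#' @param ramp_len Concentration ramp length at each epoch start
#'   (default 30).
#' @return An object of class `sedation_profile`: per-epoch `states`,
#'   `events` (list of [event_annotation()]), per-second `ce_prop`,
#'   `ce_remi` and `bis`, and `duration` (s).
#' @export
sedation_profile <- function(cfg, epoch_len = 130, ramp_len = 30) {
  set.seed(cfg$seed)
  n_ep <- 2L * cfg$n_per_class
  states <- sample(rep(c("responsive", "unresponsive"),
                       each = cfg$n_per_class))
  duration <- n_ep * epoch_len + 10
  ev_times <- (seq_len(n_ep) - 1) * epoch_len + epoch_len - 5
  rss <- ifelse(states == "unresponsive", 6,
                sample(2:5, n_ep, replace = TRUE))
  events <- lapply(seq_len(n_ep), function(i) {
    event_annotation(ev_times[i], "RSS", rss[i])
  })
  # per-second concentration traces: plateau per state, linear ramps
  prop_lvl <- ifelse(states == "unresponsive", 4.0, 2.0)
  remi_lvl <- ifelse(states == "unresponsive", 2.0, 1.0)
  sec <- seq_len(ceiling(duration))
  ep_of <- pmin(((sec - 1) %/% epoch_len) + 1, n_ep)
  in_ep <- (sec - 1) %% epoch_len
  prev <- function(lvl) c(lvl[1], lvl[-length(lvl)])
  frac <- pmin(in_ep / ramp_len, 1)
  ce_prop <- prev(prop_lvl)[ep_of] * (1 - frac) + prop_lvl[ep_of] * frac
  ce_remi <- prev(remi_lvl)[ep_of] * (1 - frac) + remi_lvl[ep_of] * frac
  bis <- ifelse(states[ep_of] == "unresponsive", 45, 80) +
    stats::rnorm(length(sec), 0, 2)
  structure(list(states = states, events = events, ce_prop = ce_prop,
                 ce_remi = ce_remi, bis = bis, duration = duration,
                 epoch_len = epoch_len, ramp_len = ramp_len),
            class = "sedation_profile")
}

# unit-RMS Gaussian noise band-limited to [f_lo, f_hi] by spectral
# truncation
.band_noise <- function(n, fs, f_lo, f_hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a synthetic sedation recording
#'
#' Builds the EEG as a sum of band-limited Gaussian components (delta,
#' theta, alpha, beta, EMG 60-145 Hz and a weak broadband floor) whose
#' gains, regular-oscillation fractions and alpha peak frequency follow
#' the latent state of the profile, plus optional 50/100 Hz mains
#' sinusoids and Poisson-placed high-amplitude peak artifacts.  In the
#' unresponsive state the beta and EMG gains drop, the alpha peak
#' shifts down, the EMG component narrows towards the upper VHF range
#' (more lag-1 predictability, hence a lower VHF first decay: the
#' surrogate of motor-unit synchronisation under deep sedation) and the
#' theta component broadens (shorter correlation time, lower AMIF mean
#' in theta), mirroring deepening sedation.
#'
#' @param cfg A [generator_config()].
#' @param profile A [sedation_profile()] (built from `cfg` when
#'   omitted).
#' @return An [eeg_record()], bit-reproducible given `cfg$seed`.
#' @export
generate_record <- function(cfg, profile = sedation_profile(cfg)) {
  set.seed(cfg$seed + 1L)
  fs <- cfg$fs
  n <- round(profile$duration * fs)
  t <- (seq_len(n) - 1) / fs
  p <- .state_params(cfg$effect_size)
  ep_len <- profile$epoch_len
  n_ep <- length(profile$states)
  ep_of <- pmin(floor(t / ep_len) + 1, n_ep)
  unresp <- profile$states[ep_of] == "unresponsive"
  gain <- function(field) {
    ifelse(unresp, p$unresponsive[[field]], p$responsive[[field]])
  }

  delta <- 10 * gain("delta_gain") * .band_noise(n, fs, 0.5, 4)
  w_th <- gain("theta_narrow")
  theta <- 6 * gain("theta_gain") *
    (sqrt(w_th) * .band_noise(n, fs, 5.5, 6.5) +
       sqrt(1 - w_th) * .band_noise(n, fs, 4, 8))
  a_resp <- .band_noise(n, fs, p$responsive$alpha_peak - 1.5,
                        p$responsive$alpha_peak + 1.5)
  a_unresp <- .band_noise(n, fs, p$unresponsive$alpha_peak - 1.5,
                          p$unresponsive$alpha_peak + 1.5)
  alpha <- a_resp
  alpha[unresp] <- a_unresp[unresp]
  alpha <- 5 * alpha
  beta <- 4 * gain("beta_gain") * .band_noise(n, fs, 12, 30)
  w_em <- gain("emg_narrow")
  emg <- 3 * cfg$emg_gain * gain("emg_gain") *
    (sqrt(w_em) * .band_noise(n, fs, 125, 145) +
       sqrt(1 - w_em) * .band_noise(n, fs, 60, 145))
  floorc <- 0.5 * .band_noise(n, fs, 0.5, 145)
  x <- delta + theta + alpha + beta + emg + floorc
  if (cfg$mains_amp > 0) {
    x <- x + cfg$mains_amp * (sin(2 * pi * 50 * t) +
                                0.5 * sin(2 * pi * 100 * t))
  }
  n_art <- stats::rpois(1, cfg$artifact_rate * profile$duration / 60)
  if (n_art > 0) {
    sd_x <- stats::sd(x)
    centers <- sort(stats::runif(n_art, 1, profile$duration - 1))
    for (tc in centers) {
      idx <- which(abs(t - tc) < 0.05)
      x[idx] <- x[idx] + 20 * sd_x * exp(-((t[idx] - tc) / 0.015)^2)
    }
  }
  eeg_record(x, fs, profile$events, ce_prop = profile$ce_prop,
             ce_remi = profile$ce_remi, bis = profile$bis,
             subject_id = sprintf("synthetic-seed%d", cfg$seed))
}

#' Generate a labeled measure dataset end-to-end
#'
#' Runs the full measurement pipeline on a generated record and labels
#' the resulting feature table under a trial definition: the standard
#' recovery/calibration harness for the evaluation machinery.
#'
#' @param cfg A [generator_config()] (`n_per_class >= 10`).
#' @param trial Trial name for [apply_trial()], default `"trial2"`
#'   (any response vs no response).
#' @param bands,specs,... Passed to [compute_measures()].
#' @return A `labeled_dataset` (see [apply_trial()]) with the feature
#'   table additionally attached as attribute `"measures_table"`.
#' @export
generate_labeled_dataset <- function(cfg, trial = "trial2",
                                     bands = names(canonical_bands()),
                                     specs = default_entropy_specs(),
                                     ...) {
  stopifnot(cfg$n_per_class >= 10L)
  rec <- generate_record(cfg)
  tab <- compute_measures(rec, bands = bands, specs = specs, ...)
  ds <- apply_trial(tab, trial)
  attr(ds, "measures_table") <- tab
  ds
}
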