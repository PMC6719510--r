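#' Default ERP component topographies and time windows
#'
#' Each component is modeled as a half-cosine bump over its time window,
#' scaled per channel by a unitless weight. The bump is normalized so that
#' its mean over the sampled window equals exactly 1; a component with
#' amplitude `a` therefore produces a mean amplitude of exactly `a` uV in
#' the matching measurement window at unit channel weight. The N1 and MMN
#' are frontocentral (largest at Fz/Cz), the P3a and visual P3
#' centro-parietal (largest at Cz/Pz). P9/P10 carry a fraction (default
#' 0.3) of each component so that mastoid rereferencing attenuates, but
#' does not destroy, the measures.
#'
#' @param mastoid_weight Fraction of each component projected onto P9/P10.
#' @return Named list of component specs (`window` in ms, `weights` per
#'   channel).
#' @export
default_components <- function(mastoid_weight = 0.3) {
  w <- function(Fz, Cz, Pz) {
    c(Fz = Fz, Cz = Cz, Pz = Pz, P9 = mastoid_weight, P10 = mastoid_weight,
      Nose = 0)
  }
  list(
    n1        = list(window = c(75, 105),  weights = w(1, 1, 0.4)),
    mmn       = list(window = c(125, 175), weights = w(1, 1, 0.4)),
    p3a       = list(window = c(300, 500), weights = w(0.5, 1, 1)),
    visual_p3 = list(window = c(300, 500), weights = w(0.4, 1, 1))
  )
}

#' Noise model for simulated epochs
#'
#' @param sd Standard deviation of the stationary noise process in uV.
#' @param model `"ar1"` or `"white"`. AR(1) with a coefficient near 1
#'   mimics the low-frequency-dominated EEG spectrum.
#' @param ar_coefficient AR(1) coefficient.
#' @param artifact_rate Proportion of epochs contaminated by a
#'   large-amplitude excursion.
#' @param artifact_amplitude Peak amplitude of artifact excursions in uV.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 3, model = c("ar1", "white"),
                       ar_coefficient = 0.95,
                       artifact_rate = 0.02, artifact_amplitude = 300) {
  model <- match.arg(model)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (artifact_rate < 0 || artifact_rate >= 0.3) {
    stop("`artifact_rate` must lie in [0, 0.3)", call. = FALSE)
  }
  structure(list(sd = sd, model = model, ar_coefficient = ar_coefficient,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude),
            class = "noise_spec")
}

#' Per-subject ground truth
#'
#' True mean amplitudes (uV) per measure and load level, plus the
#' subject's working-memory-capacity score (operation-span partial credit
#' unit, a proportion in \[0, 1\]). `mmn_oddball` is the amplitude added to
#' oddball deviants; the critical tone in the control condition carries
#' `mmn_oddball - mmn_corrected`, so the deviant-minus-critical contrast
#' recovers `mmn_corrected` by construction.
#'
#' @param subject_id Identifier.
#' @param amplitudes Numeric matrix, rows `c("n1", "mmn_oddball",
#'   "mmn_corrected", "p3a", "visual_p3")`, columns `c("low", "high")`.
#' @param wmc_pcu Proportion in \[0, 1\].
#' @return An object of class `subject_truth`.
#' @export
subject_truth <- function(subject_id, amplitudes, wmc_pcu) {
  comps <- c("n1", "mmn_oddball", "mmn_corrected", "p3a", "visual_p3")
  stopifnot(is.matrix(amplitudes),
            setequal(rownames(amplitudes), comps),
            setequal(colnames(amplitudes), c("low", "high")))
  if (wmc_pcu < 0 || wmc_pcu > 1) {
    stop("`wmc_pcu` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(subject_id = subject_id,
                 amplitudes = amplitudes[comps, c("low", "high")],
                 wmc_pcu = wmc_pcu),
            class = "subject_truth")
}

#' Group-level generator defaults
#'
#' Means are the published group means per load level; between-subject
#' dispersions are derived from the published 95% CIs
#' (sd = width / (2 t(.975, 48)) * sqrt(49)). The load-effect sd comes
#' from the load-effect CI; the shared (load-independent) sd is chosen so
#' single-load variances match. Because printed dispersions fold in
#' measurement noise, the generator slightly overdisperses true
#' amplitudes; see the methods vignette.
#'
#' @return List with `means` (measure x load matrix, uV), `sd_effect`,
#'   `sd_shared` (named numeric, uV).
#' @export
default_group_truth <- function() {
  list(
    means = rbind(
      n1            = c(low = -0.49, high = -0.15),
      mmn_oddball   = c(low = -2.13, high = -2.26),
      mmn_corrected = c(low = -1.38, high = -1.26),
      p3a           = c(low = 0.41,  high = -0.18),
      visual_p3     = c(low = 9.29,  high = 2.73)),
    sd_effect = c(n1 = 1.04, mmn_oddball = 2.11, mmn_corrected = 3.03,
                  p3a = 3.50, visual_p3 = 4.37),
    sd_shared = c(n1 = 1.82, mmn_oddball = 1.71, mmn_corrected = 2.24,
                  p3a = 1.84, visual_p3 = 4.43)
  )
}

#' Cohort specification for the synthetic study
#'
#' @param n_subjects Number of subjects (default 49, the study's final
#'   sample size).
#' @param group Group-level truth: list with `means` (matrix measure x
#'   load), `sd_effect` and `sd_shared` (named numeric). Defaults to
#'   published group summaries.
#' @param wmc_mean,wmc_sd Mean and SD of the working-memory PCU score
#'   (truncated to \[0, 1\]).
#' @param wmc_effect_r Correlation between WMC and the subject's N1 load
#'   effect (Gaussian copula on the latent scale).
#' @param n_trials Trials per block (360 as in the study; reduce for
#'   desk-scale simulation).
#' @param fs Sampling rate in Hz.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 49L, group = default_group_truth(),
                        wmc_mean = 0.7, wmc_sd = 0.12, wmc_effect_r = 0.35,
                        n_trials = 360L, fs = 200, noise = noise_spec(),
                        seed = 1L) {
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (any(group$sd_effect < 0) || any(group$sd_shared < 0)) {
    stop("group SDs must be non-negative", call. = FALSE)
  }
  if (abs(wmc_effect_r) > 1) stop("`wmc_effect_r` must be in [-1, 1]",
                                  call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), group = group,
                 wmc_mean = wmc_mean, wmc_sd = wmc_sd,
                 wmc_effect_r = wmc_effect_r, n_trials = as.integer(n_trials),
                 fs = fs, noise = noise, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw per-subject ground truths for a cohort
#'
#' Subject amplitudes are `mean(load) + shared deviation -/+ load
#' deviation / 2` (low/high), with deviations drawn from the group-level
#' normal distributions. The WMC score is correlated with the subject's N1
#' load deviation at `wmc_effect_r` via a Gaussian copula and truncated to
#' \[0, 1\].
#'
#' @param spec A [cohort_spec()].
#' @return List of [subject_truth()] objects.
#' @export
draw_cohort_truths <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$group
  comps <- rownames(g$means)
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      shared <- stats::rnorm(length(comps), 0, g$sd_shared[comps])
      z_eff <- stats::rnorm(length(comps))
      eff <- z_eff * g$sd_effect[comps]
      amps <- cbind(low = g$means[, "low"] + shared - eff / 2,
                    high = g$means[, "high"] + shared + eff / 2)
      rownames(amps) <- comps
      r <- spec$wmc_effect_r
      z_w <- r * z_eff[match("n1", comps)] + sqrt(1 - r^2) * stats::rnorm(1)
      wmc <- min(max(spec$wmc_mean + spec$wmc_sd * z_w, 0), 1)
      subject_truth(i, amps, wmc)
    })
  })
}

## Sampled half-cosine envelope over [a, b] ms, zero elsewhere, normalized
## so the mean over in-window samples is exactly 1.
component_envelope <- function(time_ms, window) {
  env <- numeric(length(time_ms))
  idx <- time_ms >= window[1] & time_ms <= window[2]
  if (!any(idx)) {
    stop("component window contains no samples", call. = FALSE)
  }
  raw <- sin(pi * (time_ms[idx] - window[1]) / diff(window))
  env[idx] <- raw / mean(raw)
  env
}

## Stationary AR(1) (or white) noise, one long chain per channel reshaped
## into epochs; burn-in absorbs the transient.
draw_noise <- function(n_epochs, n_channels, n_samples, noise) {
  out <- array(0, dim = c(n_epochs, n_channels, n_samples))
  if (noise$sd == 0) return(out)
  for (ch in seq_len(n_channels)) {
    if (noise$model == "white") {
      x <- stats::rnorm(n_epochs * n_samples, 0, noise$sd)
    } else {
      phi <- noise$ar_coefficient
      burn <- 200L
      innov <- stats::rnorm(n_epochs * n_samples + burn,
                            0, noise$sd * sqrt(1 - phi^2))
      x <- stats::filter(innov, phi, method = "recursive")
      x <- as.numeric(x)[-seq_len(burn)]
    }
    out[, ch, ] <- matrix(x, nrow = n_epochs, byrow = TRUE)
  }
  out
}

#' Simulate epoched EEG for one subject
#'
#' Builds nose-referenced epochs of −100 to 500 ms around every tone onset
#' in the session. Each epoch is the sum of the active components (N1 on
#' every tone; the MMN contribution on oddball deviants and control
#' critical tones; P3a on oddball deviants; the visual P3 on target
#' trials in all tone conditions, so it cancels in tone difference waves),
#' scaled by the subject's true amplitudes and the component channel
#' weights, plus noise. A random subset of epochs at `noise$artifact_rate`
#' receives a large slow excursion on all scalp channels. The virtual nose
#' channel is identically zero (the data are nose-referenced by
#' construction).
#'
#' @param session Output of [compose_session()].
#' @param truth A [subject_truth()].
#' @param noise A [noise_spec()].
#' @param fs Sampling rate in Hz; 200 Hz puts every analysis window edge
#'   exactly on the 5-ms sample grid.
#' @param seed Integer seed.
#' @param components Component specs from [default_components()].
#' @return An object of class `epoch_matrix`: list with `data` (array
#'   epochs x channels x samples, uV), `channels`, `fs`, `time_ms`,
#'   `events` (one row per epoch), `reference`.
#' @export
simulate_subject <- function(session, truth, noise = noise_spec(), fs = 200,
                             seed = 1L, components = default_components()) {
  stopifnot(inherits(truth, "subject_truth"), inherits(noise, "noise_spec"))
  if (fs < 128) stop("`fs` must be at least 128 Hz", call. = FALSE)
  step <- 1000 / fs
  time_ms <- seq(-100, 500, by = step)
  for (cp in components) {
    if (cp$window[1] < -100 || cp$window[2] > 500) {
      stop("component window outside the epoch range [-100, 500] ms",
           call. = FALSE)
    }
  }

  events <- do.call(rbind, lapply(seq_along(session), function(b) {
    blk <- session[[b]]
    te <- blk$tones$events
    ve <- blk$visual$events
    data.frame(block = b, load = blk$design$load,
               tone_condition = blk$design$tone_condition,
               tone_role = te$role, tone_freq = te$frequency,
               is_target = ve$is_target, is_warmup = te$is_warmup,
               trial = te$index, stringsAsFactors = FALSE)
  }))
  n_epochs <- nrow(events)
  n_ch <- length(EEG_CHANNELS)
  n_sp <- length(time_ms)

  env <- lapply(components, function(cp) component_envelope(time_ms, cp$window))

  ## per-epoch component amplitudes from the ground truth
  amp <- truth$amplitudes
  a_of <- function(comp) amp[comp, events$load]
  comp_amp <- cbind(
    n1 = a_of("n1"),
    mmn = ifelse(events$tone_role == "deviant", a_of("mmn_oddball"),
          ifelse(events$tone_role == "critical",
                 a_of("mmn_oddball") - a_of("mmn_corrected"), 0)),
    p3a = ifelse(events$tone_role == "deviant", a_of("p3a"), 0),
    visual_p3 = ifelse(events$is_target, a_of("visual_p3"), 0))

  data <- with_seed(seed, {
    x <- draw_noise(n_epochs, n_ch, n_sp, noise)
    if (noise$artifact_rate > 0) {
      hit <- stats::runif(n_epochs) < noise$artifact_rate
      if (any(hit)) {
        bump <- sin(pi * seq(0, 1, length.out = n_sp))
        sgn <- sample(c(-1, 1), sum(hit), replace = TRUE)
        scalp <- which(EEG_CHANNELS != "Nose")
        for (k in seq_along(which(hit))) {
          e <- which(hit)[k]
          for (ch in scalp) {
            x[e, ch, ] <- x[e, ch, ] + sgn[k] * noise$artifact_amplitude * bump
          }
        }
      }
    }
    x[, EEG_CHANNELS == "Nose", ] <- 0
    x
  })

  for (cn in names(components)) {
    a <- comp_amp[, cn]
    active <- which(a != 0)
    if (!length(active)) next
    wts <- components[[cn]]$weights[EEG_CHANNELS]
    ## outer product added into the active epochs: a x (weights o envelope)
    block3 <- outer(a[active], outer(wts, env[[cn]]))
    data[active, , ] <- data[active, , , drop = FALSE] + block3
  }

  structure(list(data = data, channels = EEG_CHANNELS, fs = fs,
                 time_ms = time_ms, events = events, reference = "nose"),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("<epoch_matrix> %d epochs x %d channels x %d samples @ %g Hz (%s reference)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$reference))
  invisible(x)
}

#' Simulate a full cohort
#'
#' Draws per-subject ground truths from the group-level distributions and
#' simulates each subject's epoched EEG. Fully seeded: identical
#' specifications give bit-identical cohorts. For large cohorts prefer
#' [run_study()], which streams subjects instead of holding all epochs in
#' memory.
#'
#' @param spec A [cohort_spec()].
#' @return List of `list(epochs, truth)` per subject.
#' @export
simulate_cohort <- function(spec) {
  truths <- draw_cohort_truths(spec)
  seeds <- derive_seeds(spec$seed + 2L, 2L * spec$n_subjects)
  lapply(seq_len(spec$n_subjects), function(i) {
    session <- compose_session(seeds[2L * i - 1L], n_trials = spec$n_trials)
    epochs <- simulate_subject(session, truths[[i]], noise = spec$noise,
                               fs = spec$fs, seed = seeds[2L * i])
    list(epochs = epochs, truth = truths[[i]])
  })
}
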