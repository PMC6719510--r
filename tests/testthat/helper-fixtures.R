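# Shared fixtures and independent oracles used across the test files.

# Ground-truth amplitude matrix in the layout subject_truth() expects.
truth_matrix <- function(n1 = c(-0.49, -0.15),
                         mmn_oddball = c(-2.13, -2.26),
                         mmn_corrected = c(-1.38, -1.26),
                         p3a = c(0.41, -0.18),
                         visual_p3 = c(9.29, 2.73)) {
  m <- rbind(n1 = n1, mmn_oddball = mmn_oddball,
             mmn_corrected = mmn_corrected, p3a = p3a,
             visual_p3 = visual_p3)
  colnames(m) <- c("low", "high")
  m
}

make_truth <- function(..., wmc = 0.7, id = 1) {
  subject_truth(id, truth_matrix(...), wmc)
}

quiet_noise <- function(sd = 0) noise_spec(sd = sd, artifact_rate = 0)

# One noise-free reduced subject (40-trial blocks) for pipeline tests.
noise_free_subject <- function(seed = 11, n_trials = 40, fs = 200, ...) {
  session <- compose_session(seed, n_trials = n_trials)
  simulate_subject(session, make_truth(...), quiet_noise(), fs = fs,
                   seed = seed + 1)
}

# Hand-built epoch matrix for unit tests of the pipeline primitives.
# `data` is epochs x channels x samples on the package montage.
manual_epochs <- function(data, fs = 200,
                          time_ms = seq(-100, 500, by = 1000 / fs),
                          load = "low", tone_condition = "oddball",
                          tone_role = "standard", is_target = FALSE,
                          is_warmup = FALSE) {
  n <- dim(data)[1]
  ev <- data.frame(block = 1L, load = rep_len(load, n),
                   tone_condition = rep_len(tone_condition, n),
                   tone_role = rep_len(tone_role, n),
                   tone_freq = 550, is_target = rep_len(is_target, n),
                   is_warmup = rep_len(is_warmup, n),
                   trial = seq_len(n) - 1L, stringsAsFactors = FALSE)
  structure(list(data = data, channels = c("Fz", "Cz", "Pz", "P9", "P10",
                                           "Nose"),
                 fs = fs, time_ms = time_ms, events = ev, reference = "nose"),
            class = "epoch_matrix")
}

const_epochs <- function(values, ...) {
  # one constant level per epoch across all channels/samples
  n_sp <- length(seq(-100, 500, by = 5))
  data <- array(rep(values, times = 6 * n_sp), dim = c(length(values), 6, n_sp))
  manual_epochs(data, ...)
}

# --- independent oracles -------------------------------------------------

# Brute-force Riemann-sum Bayes factor with a uniform prior and scaled-t
# likelihood (midpoint rule, 1e6 points).
riemann_bf10 <- function(m, se, df, lower, upper, n_points = 1e6) {
  delta <- seq(lower, upper, length.out = n_points + 1)
  delta <- (delta[-1] + delta[-length(delta)]) / 2
  lik <- dt((m - delta) / se, df) / se
  marg1 <- mean(lik)
  marg1 / (dt(m / se, df) / se)
}

# Dense-grid correlation Bayes factor using its own hypergeometric series.
grid_correlation_bf10 <- function(r, n, n_grid = 2e5) {
  hyp2f1 <- function(a, b, cc, z) {
    term <- 1; s <- 1
    for (k in 1:100000) {
      term <- term * (a + k - 1) * (b + k - 1) / (cc + k - 1) / k * z
      s <- s + term
      if (abs(term) < abs(s) * 1e-16) break
    }
    s
  }
  dens <- function(rho) {
    exp((n - 1) / 2 * log(1 - rho^2) - (n - 1.5) * log(1 - rho * r)) *
      hyp2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
  }
  rho <- seq(-1, 1, length.out = n_grid + 1)
  rho <- (rho[-1] + rho[-length(rho)]) / 2
  mean(vapply(rho, dens, 0)) / dens(0)
}

# Variance of the mean over sample-index set `idx` minus the mean over
# `base_idx`, for stationary AR(1) noise with marginal sd `sd` and
# coefficient `phi` (indices in samples).
ar1_contrast_var <- function(sd, phi, idx, base_idx) {
  cov_sets <- function(a, b) {
    sd^2 * mean(phi^abs(outer(a, b, `-`)))
  }
  cov_sets(idx, idx) + cov_sets(base_idx, base_idx) -
    2 * cov_sets(idx, base_idx)
}
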