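test_that("baseline correction removes constants, is idempotent, and matches the ramp integral", {
  em <- const_epochs(c(5, -3, 0))
  bc <- baseline_correct(em)
  expect_equal(max(abs(bc$data)), 0)
  expect_equal(baseline_correct(bc)$data, bc$data)

  # linear ramp from -1 uV at -100 ms to +5 uV at +500 ms on every channel
  t_ms <- seq(-100, 500, by = 5)
  ramp <- -1 + (t_ms + 100) / 600 * 6
  em2 <- manual_epochs(array(rep(ramp, each = 6), dim = c(1, 6, length(t_ms))))
  bc2 <- baseline_correct(em2)
  pre_mean <- mean(ramp[t_ms >= -100 & t_ms < 0])
  expect_equal(bc2$data[1, 1, which(t_ms == 0)], ramp[t_ms == 0] - pre_mean)

  em3 <- em
  em3$time_ms <- em3$time_ms + 200 # no pre-stimulus samples left
  expect_error(baseline_correct(em3), "pre-stimulus")
})

test_that("rereferencing obeys its defining identities", {
  t_ms <- seq(-100, 500, by = 5)
  set.seed(8)
  data <- array(rnorm(4 * 6 * length(t_ms)), dim = c(4, 6, length(t_ms)))
  data[, 6, ] <- 0 # nose channel
  em <- manual_epochs(data)

  # P9 = P10 = 0 makes mastoid rereferencing the identity
  em0 <- em
  em0$data[, 4:5, ] <- 0
  expect_equal(rereference(em0, "mastoid_mean")$data, em0$data)

  # after mastoid rereferencing the mastoid mean is zero everywhere
  rr <- rereference(em, "mastoid_mean")
  expect_equal(max(abs((rr$data[, 4, ] + rr$data[, 5, ]) / 2)), 0)

  # difference waves are invariant to a common signal added to all
  # channels once mastoid-referenced
  common <- array(rep(sin(t_ms / 50), each = 4 * 6),
                  dim = c(4, 6, length(t_ms)))
  em_shift <- em
  em_shift$data <- em$data + aperm(common, c(1, 2, 3))
  w <- function(e, idx) {
    average_erp(e, seq_len(4) %in% idx)
  }
  d1 <- difference_wave(w(rereference(em, "mastoid_mean"), 1:2),
                        w(rereference(em, "mastoid_mean"), 3:4))
  d2 <- difference_wave(w(rereference(em_shift, "mastoid_mean"), 1:2),
                        w(rereference(em_shift, "mastoid_mean"), 3:4))
  expect_equal(d1$amp, d2$amp, tolerance = 1e-12)
})

test_that("epoch rejection removes exactly the high-range epochs and is condition-blind", {
  em <- const_epochs(rep(0, 10),
                     tone_role = rep(c("deviant", "standard"), 5))
  # inject a 500 uV artifact into epochs 3 and 7
  em$data[3, 1, 50] <- 500
  em$data[7, 2, 60] <- -500
  out <- reject_epochs(em, cutoff = 200)
  expect_equal(dim(out$epochs$data)[1], 8)
  # epochs 3 and 7 carry trial ids 2 and 6 (0-based)
  expect_false(any(c(2L, 6L) %in% out$epochs$events$trial))

  # all epochs within +-10 uV survive a 100 uV cutoff
  set.seed(2)
  em2 <- const_epochs(runif(10, -10, 10))
  expect_equal(dim(reject_epochs(em2, cutoff = 100)$epochs$data)[1], 10)

  # rejection decisions ignore condition labels
  em3 <- em
  em3$events$tone_role <- sample(em3$events$tone_role)
  out3 <- reject_epochs(em3, cutoff = 200)
  expect_equal(out3$epochs$events$trial, out$epochs$events$trial)

  # with nonzero ranges everywhere, a vanishing cutoff rejects everything
  set.seed(5)
  t_ms <- seq(-100, 500, by = 5)
  em4 <- manual_epochs(array(rnorm(3 * 6 * length(t_ms)),
                             dim = c(3, 6, length(t_ms))))
  expect_error(reject_epochs(em4, cutoff = 1e-9), "removed all")
})

test_that("retention accounting enforces the 70% rule per primary cell", {
  session <- compose_session(61, n_trials = 40)
  em <- simulate_subject(session, make_truth(),
                         noise_spec(sd = 3, artifact_rate = 0.05,
                                    artifact_amplitude = 400),
                         fs = 200, seed = 62)
  ms <- extract_measures(em)
  rep <- attr(ms, "retention")
  expect_true(all(rep$retention > 0.7)) # 5% artifacts leave ample retention
  expect_false(attr(ms, "excluded"))
  expect_true(all(rep$n_retained <= rep$n_total))
})

test_that("averaging and difference waves are linear", {
  em <- const_epochs(c(1, -1))
  w <- average_erp(em, c(TRUE, TRUE))
  expect_equal(max(abs(w$amp)), 0)
  expect_equal(w$n_epochs, 2)

  single <- average_erp(em, c(TRUE, FALSE))
  expect_equal(max(abs(single$amp - 1)), 0)

  expect_error(average_erp(em, c(FALSE, FALSE), label = "empty cell"),
               "empty cell")

  set.seed(3)
  t_ms <- seq(-100, 500, by = 5)
  a <- manual_epochs(array(rnorm(6 * length(t_ms)),
                           dim = c(1, 6, length(t_ms))))
  b <- manual_epochs(array(rnorm(6 * length(t_ms)),
                           dim = c(1, 6, length(t_ms))))
  wa <- average_erp(a, TRUE)
  wb <- average_erp(b, TRUE)
  d <- difference_wave(wa, wb)
  expect_equal(mean_amplitude(d, c("Fz", "Cz"), c(100, 200)),
               mean_amplitude(wa, c("Fz", "Cz"), c(100, 200)) -
                 mean_amplitude(wb, c("Fz", "Cz"), c(100, 200)),
               tolerance = 1e-12)
  expect_equal(max(abs(difference_wave(wa, wa)$amp)), 0)

  wa_bad <- wa
  wa_bad$time_ms <- wa$time_ms + 5
  expect_error(difference_wave(wa_bad, wb), "mismatch")
})

test_that("mean amplitude averages samples then electrodes, inclusively", {
  t_ms <- seq(-100, 500, by = 5)
  data <- array(0, dim = c(1, 6, length(t_ms)))
  data[1, 1, ] <- 1 # Fz
  data[1, 2, ] <- 3 # Cz
  w <- average_erp(manual_epochs(data), TRUE)
  expect_equal(mean_amplitude(w, c("Fz", "Cz"), c(75, 105)), 2)
  expect_equal(mean_amplitude(w, "Cz", c(0, 500)), 3)

  # linear ramp: window mean equals the midpoint value on a uniform grid
  data2 <- array(rep(t_ms, each = 6), dim = c(1, 6, length(t_ms)))
  w2 <- average_erp(manual_epochs(data2), TRUE)
  expect_equal(mean_amplitude(w2, "Fz", c(100, 200)), 150)
  expect_error(mean_amplitude(w2, "Fz", c(501, 502)), "no samples")
  expect_error(mean_amplitude(w2, "F3", c(0, 100)), "not present")
})

test_that("visual P3 contamination cancels in tone difference waves", {
  base <- noise_free_subject(seed = 71, visual_p3 = c(0, 0))
  big <- noise_free_subject(seed = 71, visual_p3 = c(12, 12))
  ms_base <- extract_measures(base)
  ms_big <- extract_measures(big)
  for (comp in c("mmn_oddball", "mmn_corrected", "p3a")) {
    expect_equal(ms_big$value[ms_big$component == comp],
                 ms_base$value[ms_base$component == comp],
                 tolerance = 1e-10)
  }
  expect_equal(ms_big$value[ms_big$component == "visual_p3"], c(12, 12),
               tolerance = 1e-10)
})

test_that("load effects are high-minus-low and anti-symmetric", {
  em <- noise_free_subject(seed = 81)
  ms <- extract_measures(em)
  eff <- load_effect(ms)
  expect_equal(eff[["n1"]], 0.34, tolerance = 1e-10)
  expect_equal(eff[["mmn_oddball"]], -0.13, tolerance = 1e-10)
  expect_equal(eff[["visual_p3"]], -6.56, tolerance = 1e-10)

  swapped <- ms
  swapped$load <- ifelse(ms$load == "low", "high", "low")
  expect_equal(load_effect(swapped), -eff[names(load_effect(swapped))],
               tolerance = 1e-12)

  equal_ms <- ms
  equal_ms$value <- rep(ms$value[ms$load == "low"], 2)
  expect_true(all(abs(load_effect(equal_ms)) < 1e-12))
})

test_that("extract_measures names a missing block type", {
  em <- noise_free_subject(seed = 91)
  only_odd <- em
  keep <- em$events$tone_condition == "oddball"
  only_odd$data <- em$data[keep, , , drop = FALSE]
  only_odd$events <- em$events[keep, ]
  expect_error(extract_measures(only_odd), "missing block type")
})
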