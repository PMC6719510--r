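test_that("oddball blocks have exact counts, warm-up standards, and are seed-deterministic", {
  d <- block_design("low", "oddball")
  b <- generate_oddball_block(d, seed = 101)
  main <- b$events[!b$events$is_warmup, ]
  expect_equal(sum(main$role == "deviant"), 45)
  expect_equal(sum(main$role == "standard"), 315)
  expect_true(all(main$frequency[main$role == "deviant"] == 500))
  expect_true(all(main$frequency[main$role == "standard"] == 550))
  warm <- b$events[b$events$is_warmup, ]
  expect_equal(nrow(warm), 7)
  expect_true(all(warm$frequency == 550))
  expect_identical(generate_oddball_block(d, seed = 101)$events, b$events)
  expect_false(identical(generate_oddball_block(d, seed = 102)$events,
                         b$events))
  expect_equal(b$events$onset_ms, b$events$index * 500)
})

test_that("oddball generation matches brute-force enumeration of feasible placements", {
  # 16 trials at 12.5% gives 2 deviants with >= 3 standards between them;
  # enumerate every feasible placement directly
  d <- block_design("low", "oddball", n_trials = 16, target_rate = 0.25)
  feasible <- do.call(rbind, lapply(1:16, function(i) {
    js <- seq_len(16)[seq_len(16) - i >= 4]
    if (length(js)) cbind(i, js)
  }))
  seen <- matrix(0L, 16, 16)
  for (s in 1:1000) {
    b <- generate_oddball_block(d, seed = s)
    pos <- which(b$events$role[!b$events$is_warmup] == "deviant")
    expect_equal(nrow(validate_block(b)), 0)
    expect_true(pos[2] - pos[1] >= 4)
    seen[pos[1], pos[2]] <- seen[pos[1], pos[2]] + 1L
  }
  # only feasible placements are generated, and every feasible deviant
  # position is reachable
  gen_pairs <- which(seen > 0, arr.ind = TRUE)
  expect_true(all(gen_pairs[, 2] - gen_pairs[, 1] >= 4))
  expect_setequal(unique(c(feasible)), unique(c(gen_pairs)))
})

test_that("infeasible oddball constraints raise a configuration error", {
  d <- block_design("low", "oddball", n_trials = 16, target_rate = 0.25)
  expect_error(generate_oddball_block(d, seed = 1, min_gap = 20),
               "infeasible")
})

test_that("control blocks are sets of permutations with no cross-boundary repeats", {
  d <- block_design("high", "control")
  b <- generate_control_block(d, seed = 55)
  main <- b$events[!b$events$is_warmup, ]
  expect_equal(as.vector(table(main$frequency)), rep(45, 8))
  expect_true(all(diff(main$frequency) != 0))
  for (s in 1:45) {
    expect_setequal(main$frequency[((s - 1) * 8 + 1):(s * 8)],
                    c(500, 550, 605, 666, 732, 805, 886, 974))
  }
  warm <- b$events[b$events$is_warmup, ]
  expect_setequal(warm$frequency, c(550, 605, 666, 732, 805, 886, 974))
  expect_equal(nrow(validate_block(b)), 0)
  expect_error(generate_control_block(d, frequencies = 500, seed = 1),
               "at least 2")
})

test_that("control set redraws match the rejection-sampling law at set boundaries", {
  # 2 sets of 8: the first tone of set 2 should be uniform over the 7
  # frequencies different from the last tone of set 1 (prob 1/56 per
  # ordered boundary pair), which is exactly what unconstrained rejection
  # sampling produces
  d <- block_design("low", "control", n_trials = 16, target_rate = 0.25)
  n_draw <- 4000
  pair <- character(n_draw)
  for (s in seq_len(n_draw)) {
    b <- generate_control_block(d, seed = s)
    f <- b$events$frequency[!b$events$is_warmup]
    expect_true(f[9] != f[8])
    pair[s] <- paste(f[8], f[9])
  }
  freqs <- c(500, 550, 605, 666, 732, 805, 886, 974)
  cells <- outer(freqs, freqs, paste)[lower.tri(diag(8)) | upper.tri(diag(8))]
  counts <- table(factor(pair, levels = cells))
  chi <- sum((counts - n_draw / 56)^2 / (n_draw / 56))
  expect_lt(chi, qchisq(1 - 1e-4, df = 55))
})

test_that("visual blocks satisfy target counts, gap bounds, and combination balance", {
  for (load in c("low", "high")) {
    d <- block_design(load, "oddball")
    b <- generate_visual_block(d, seed = 7)
    main <- b$events[!b$events$is_warmup, ]
    expect_equal(sum(main$is_target), 72)
    expect_equal(sum(!main$is_target), 288)
    gaps <- diff(c(0, which(main$is_target))) - 1
    expect_true(all(gaps >= 2 & gaps <= 6))
    lab <- paste(main$color, main$orientation, sep = "_")
    expect_equal(as.vector(table(lab[main$is_target])), rep(36, 2))
    expect_equal(as.vector(table(lab[!main$is_target])), rep(36, 8))
    expect_false(any(b$events$is_target[b$events$is_warmup]))
    expect_equal(nrow(validate_block(b)), 0)
  }
  expect_error(generate_visual_block(block_design("low", "oddball",
                                                  n_trials = 80),
                                     seed = 1, gap_min = 5, gap_max = 6),
               "infeasible")
})

test_that("gap compositions are sampled uniformly (exhaustive enumeration oracle)", {
  # toy block: 6 targets, 24 non-targets, gaps in [2, 6]
  enumerate <- function(k, total, lo, hi) {
    if (k == 1) {
      if (total >= lo && total <= hi) return(matrix(total, 1, 1))
      return(NULL)
    }
    do.call(rbind, lapply(lo:hi, function(g) {
      rest <- enumerate(k - 1, total - g, lo, hi)
      if (!is.null(rest)) cbind(g, rest)
    }))
  }
  all_comp <- enumerate(6, 24, 2, 6)
  first_gap_exact <- table(factor(all_comp[, 1], levels = 2:6)) /
    nrow(all_comp)
  d <- block_design("low", "oddball", n_trials = 30, deviant_rate = 0.1)
  n_draw <- 3000
  first <- integer(n_draw)
  for (s in seq_len(n_draw)) {
    b <- generate_visual_block(d, seed = s)
    first[s] <- which(b$events$is_target[!b$events$is_warmup])[1] - 1
  }
  counts <- table(factor(first, levels = 2:6))
  expected <- n_draw * as.vector(first_gap_exact)
  chi <- sum((counts - expected)^2 / expected)
  expect_lt(chi, qchisq(1 - 1e-4, df = 4))
})

test_that("targets are stratified across tone classes when a tone sequence is given", {
  d <- block_design("low", "oddball")
  tones <- generate_oddball_block(d, seed = 3)
  vis <- generate_visual_block(d, seed = 4, tones = tones)
  is500 <- tones$events$frequency[!tones$events$is_warmup] == 500
  tar <- vis$events$is_target[!vis$events$is_warmup]
  expect_equal(sum(tar[is500]), 9)   # 20% of 45 deviants
  expect_equal(sum(tar[!is500]), 63) # 20% of 315 standards
})

test_that("composed sessions present each condition twice, once per half", {
  for (seed in c(1, 99)) {
    session <- compose_session(seed, n_trials = 40)
    conds <- sapply(session, function(b) {
      paste(b$design$load, b$design$tone_condition)
    })
    expect_true(all(table(conds) == 2))
    expect_equal(length(unique(conds[1:4])), 4)
    expect_equal(length(unique(conds[5:8])), 4)
    expect_equal(nrow(validate_session(session)), 0)
  }
  s1 <- compose_session(5, n_trials = 40)
  s2 <- compose_session(5, n_trials = 40)
  expect_identical(s1, s2)
})

test_that("validate_block reports constructed violations with their indices", {
  d <- block_design("low", "oddball", n_trials = 16, target_rate = 0.25)
  b <- generate_oddball_block(d, seed = 1)
  # force two deviants with only 2 standards between them
  main_idx <- which(!b$events$is_warmup)
  b$events$role[main_idx] <- "standard"
  b$events$frequency[main_idx] <- 550
  b$events$role[main_idx[c(2, 5)]] <- "deviant"
  b$events$frequency[main_idx[c(2, 5)]] <- 500
  rep <- validate_block(b)
  expect_true("min_gap" %in% rep$constraint)
  expect_equal(rep$index[rep$constraint == "min_gap"],
               b$events$index[main_idx[5]])

  dc <- block_design("low", "control", n_trials = 16, target_rate = 0.25)
  cb <- generate_control_block(dc, seed = 1)
  mi <- which(!cb$events$is_warmup)
  cb$events$frequency[mi[9]] <- cb$events$frequency[mi[8]]
  expect_true("boundary_repeat" %in% validate_block(cb)$constraint)

  vb <- generate_visual_block(block_design("low", "oddball"), seed = 1)
  tar_rows <- which(vb$events$is_target)
  vb$events$is_target[tar_rows[1]] <- FALSE # breaks count and combo balance
  rep_v <- validate_block(vb)
  expect_true("target_count" %in% rep_v$constraint)
})

test_that("sequence TSV serialization round-trips the event structure", {
  d <- block_design("low", "oddball", n_trials = 40)
  tones <- generate_oddball_block(d, seed = 2)
  vis <- generate_visual_block(d, seed = 3, tones = tones)
  path <- tempfile(fileext = ".tsv")
  write_sequence_tsv(tones, vis, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 2 * nrow(tones$events))
  tone_rows <- tab[tab$stream == "tone", ]
  expect_equal(as.numeric(tone_rows$value[order(tone_rows$index)]),
               tones$events$frequency)
  expect_equal(sum(tab$is_target, na.rm = TRUE), 8)
})
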