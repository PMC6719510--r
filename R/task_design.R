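#' Block design for one stimulus block
#'
#' A block pairs a visual search stream (crosses, 20% targets) with a
#' simultaneous tone stream, either an oddball sequence (500-Hz deviant at
#' 12.5% among 550-Hz standards) or an equiprobable control sequence
#' (eight tones at 12.5% each). Trials last 500 ms with 100-ms stimuli;
#' seven warm-up trials precede each block and are excluded from analysis.
#'
#' @param load Visual load level, `"low"` or `"high"`. Under low load
#'   targets are red crosses of either orientation; under high load targets
#'   are upright-yellow and inverted-green crosses.
#' @param tone_condition `"oddball"` or `"control"`.
#' @param n_trials Number of analysed trials per block (default 360).
#' @param trial_period_ms Trial onset asynchrony in ms.
#' @param stim_duration_ms Stimulus duration in ms.
#' @param warmup_count Number of warm-up trials prepended to the block.
#' @param deviant_rate Proportion of deviants in oddball blocks.
#' @param target_rate Proportion of visual targets.
#' @return An object of class `block_design`.
#' @export
block_design <- function(load = c("low", "high"),
                         tone_condition = c("oddball", "control"),
                         n_trials = 360L,
                         trial_period_ms = 500,
                         stim_duration_ms = 100,
                         warmup_count = 7L,
                         deviant_rate = 0.125,
                         target_rate = 0.20) {
  load <- match.arg(load)
  tone_condition <- match.arg(tone_condition)
  n_trials <- as.integer(n_trials)
  if (n_trials < 8L) stop("`n_trials` must be at least 8", call. = FALSE)
  n_dev <- n_trials * deviant_rate
  n_tar <- n_trials * target_rate
  if (abs(n_dev - round(n_dev)) > 1e-9 || abs(n_tar - round(n_tar)) > 1e-9) {
    stop("n_trials x deviant_rate and n_trials x target_rate must be integers",
         call. = FALSE)
  }
  structure(
    list(load = load, tone_condition = tone_condition, n_trials = n_trials,
         trial_period_ms = trial_period_ms, stim_duration_ms = stim_duration_ms,
         warmup_count = as.integer(warmup_count),
         deviant_rate = deviant_rate, target_rate = target_rate),
    class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> %s load, %s tones, %d trials (+%d warm-up)\n",
              x$load, x$tone_condition, x$n_trials, x$warmup_count))
  invisible(x)
}

new_tone_sequence <- function(design, events) {
  events$index <- seq_len(nrow(events)) - 1L
  events$onset_ms <- events$index * design$trial_period_ms
  structure(list(design = design, events = events), class = "tone_sequence")
}

new_visual_sequence <- function(design, events) {
  events$index <- seq_len(nrow(events)) - 1L
  events$onset_ms <- events$index * design$trial_period_ms
  structure(list(design = design, events = events), class = "visual_sequence")
}

#' Generate an oddball tone block
#'
#' Places `n_trials * deviant_rate` deviants among standards so that every
#' pair of consecutive deviants is separated by at least `min_gap`
#' standards, sampling uniformly over all placements that satisfy the
#' constraint. Uniformity follows from the standard bijection between
#' min-gap placements and unconstrained combinations: a uniform sorted
#' `k`-subset of `1:(n - (k-1)*min_gap)` shifted by `min_gap * (i-1)` is a
#' uniform min-gap placement. Seven warm-up standards precede the block.
#'
#' @param design A `block_design` with `tone_condition = "oddball"`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param min_gap Minimum number of standards between consecutive deviants.
#' @return A `tone_sequence` whose `events` data frame has columns
#'   `index`, `onset_ms`, `frequency`, `role`, `is_warmup`.
#' @export
generate_oddball_block <- function(design, seed, min_gap = 3L) {
  stopifnot(inherits(design, "block_design"))
  if (design$tone_condition != "oddball") {
    stop("`design` must have tone_condition = 'oddball'", call. = FALSE)
  }
  n <- design$n_trials
  k <- as.integer(round(n * design$deviant_rate))
  m <- n - (k - 1L) * min_gap
  if (k < 1L || m < k) {
    stop(sprintf(
      "infeasible oddball constraint: %d deviants with min gap %d in %d trials",
      k, min_gap, n), call. = FALSE)
  }
  pos <- with_seed(seed, sort(sample.int(m, k)) + min_gap * (seq_len(k) - 1L))
  role <- rep("standard", n)
  role[pos] <- "deviant"
  freq <- ifelse(role == "deviant", ODDBALL_DEVIANT_HZ, ODDBALL_STANDARD_HZ)
  wu <- design$warmup_count
  events <- data.frame(
    frequency = c(rep(ODDBALL_STANDARD_HZ, wu), freq),
    role = c(rep("warmup", wu), role),
    is_warmup = c(rep(TRUE, wu), rep(FALSE, n)),
    stringsAsFactors = FALSE)
  new_tone_sequence(design, events)
}

#' Generate an equiprobable control tone block
#'
#' The block consists of consecutive sets in which each frequency occurs
#' exactly once; set order is randomized with the restriction that the
#' same tone is never presented twice in a row across a set boundary
#' (violating permutations are redrawn). Warm-up trials present the
#' non-critical frequencies once each in random order.
#'
#' @param design A `block_design` with `tone_condition = "control"`.
#' @param frequencies Tone frequencies in Hz; the 500-Hz tone is the
#'   critical tone (physically identical to the oddball deviant).
#' @param seed Integer seed.
#' @return A `tone_sequence`; roles are `"critical"` for the 500-Hz tone
#'   and `"control"` otherwise.
#' @export
generate_control_block <- function(design, frequencies = CONTROL_FREQUENCIES_HZ,
                                   seed) {
  stopifnot(inherits(design, "block_design"))
  if (design$tone_condition != "control") {
    stop("`design` must have tone_condition = 'control'", call. = FALSE)
  }
  nf <- length(frequencies)
  if (nf < 2L) stop("need at least 2 control frequencies", call. = FALSE)
  if (design$n_trials %% nf != 0L) {
    stop("`n_trials` must be divisible by the number of frequencies",
         call. = FALSE)
  }
  n_sets <- design$n_trials %/% nf
  warm_pool <- setdiff(frequencies, ODDBALL_DEVIANT_HZ)
  seq_freq <- with_seed(seed, {
    warm <- sample(warm_pool)
    out <- numeric(0)
    last <- warm[length(warm)]
    for (s in seq_len(n_sets)) {
      repeat {
        perm <- sample(frequencies)
        if (perm[1L] != last) break
      }
      out <- c(out, perm)
      last <- perm[nf]
    }
    list(warm = warm, main = out)
  })
  role <- ifelse(seq_freq$main == ODDBALL_DEVIANT_HZ, "critical", "control")
  events <- data.frame(
    frequency = c(seq_freq$warm, seq_freq$main),
    role = c(rep("warmup", length(seq_freq$warm)), role),
    is_warmup = c(rep(TRUE, length(seq_freq$warm)),
                  rep(FALSE, design$n_trials)),
    stringsAsFactors = FALSE)
  new_tone_sequence(design, events)
}

## Count table for compositions of `total` into `k` parts in [lo, hi]:
## counts[j + 1, s + 1] = number of ways to write s with j parts.
## Tables are memoized per (k, total, lo, hi).
.gap_table_cache <- new.env(parent = emptyenv())

gap_count_table <- function(k, total, lo, hi) {
  key <- paste(k, total, lo, hi, sep = "_")
  hit <- .gap_table_cache[[key]]
  if (!is.null(hit)) return(hit)
  counts <- matrix(0, nrow = k + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (j in seq_len(k)) {
    for (s in 0:total) {
      parts <- lo:hi
      parts <- parts[parts <= s]
      if (length(parts)) {
        counts[j + 1L, s + 1L] <- sum(counts[j, s - parts + 1L])
      }
    }
  }
  .gap_table_cache[[key]] <- counts
  counts
}

## Sample one composition uniformly via the count table (sequential
## conditional sampling with exact remaining counts).
sample_gap_composition <- function(k, total, lo, hi, counts = NULL) {
  if (is.null(counts)) counts <- gap_count_table(k, total, lo, hi)
  if (counts[k + 1L, total + 1L] <= 0) {
    stop(sprintf("infeasible gap composition: %d parts in [%d, %d] summing to %d",
                 k, lo, hi, total), call. = FALSE)
  }
  gaps <- integer(k)
  s <- total
  for (j in k:1) {
    vals <- lo:hi
    vals <- vals[vals <= s]
    w <- counts[j, s - vals + 1L]
    g <- vals[sample.int(length(vals), 1L, prob = w)]
    gaps[k - j + 1L] <- g
    s <- s - g
  }
  gaps
}

#' Generate a visual search block
#'
#' Produces `n_trials * target_rate` targets among non-targets such that
#' the number of non-targets preceding each target lies in `[gap_min,
#' gap_max]`, with the gap composition sampled uniformly over all valid
#' compositions by dynamic programming. Color-by-orientation combinations
#' occur equally often within targets and within non-targets. If a tone
#' sequence is supplied, target positions are additionally constrained so
#' that exactly `target_rate` of the 500-Hz tones (and of the remaining
#' tones) coincide with targets, so tone frequency does not predict visual
#' targets; this is enforced by redrawing the gap composition until the
#' stratification holds, which preserves the uniform composition law
#' conditional on the constraint.
#'
#' @param design A `block_design`.
#' @param seed Integer seed.
#' @param tones Optional `tone_sequence` from the same block, used to
#'   stratify targets across tone classes.
#' @param gap_min,gap_max Bounds on the number of non-targets between
#'   consecutive targets.
#' @return A `visual_sequence` whose `events` data frame has columns
#'   `index`, `onset_ms`, `color`, `orientation`, `is_target`, `role`,
#'   `is_warmup`.
#' @export
generate_visual_block <- function(design, seed, tones = NULL,
                                  gap_min = 2L, gap_max = 6L) {
  stopifnot(inherits(design, "block_design"))
  n <- design$n_trials
  n_tar <- as.integer(round(n * design$target_rate))
  n_non <- n - n_tar
  if (n_tar * gap_min > n_non || n_tar * gap_max < n_non) {
    stop(sprintf(
      "infeasible visual constraint: %d gaps in [%d, %d] cannot sum to %d",
      n_tar, gap_min, gap_max, n_non), call. = FALSE)
  }
  combos <- target_combinations(design$load)
  counts <- gap_count_table(n_tar, n_non, gap_min, gap_max)

  crit500 <- NULL
  n_tar_500 <- 0L
  if (!is.null(tones)) {
    main <- tones$events[!tones$events$is_warmup, ]
    stopifnot(nrow(main) == n)
    crit500 <- main$frequency == ODDBALL_DEVIANT_HZ
    n_tar_500 <- as.integer(round(sum(crit500) * design$target_rate))
  }

  res <- with_seed(seed, {
    for (attempt in seq_len(100000L)) {
      gaps <- sample_gap_composition(n_tar, n_non, gap_min, gap_max, counts)
      target_pos <- cumsum(gaps + 1L)
      if (is.null(crit500) || sum(crit500[target_pos]) == n_tar_500) break
      if (attempt == 100000L) {
        stop("could not satisfy tone-target stratification", call. = FALSE)
      }
    }
    is_target <- rep(FALSE, n)
    is_target[target_pos] <- TRUE
    tar_lab <- sample(rep(combos$target, length.out = n_tar))
    non_lab <- sample(rep(combos$nontarget, length.out = n_non))
    warm_lab <- sample(combos$nontarget, design$warmup_count, replace = TRUE)
    list(is_target = is_target, tar = tar_lab, non = non_lab, warm = warm_lab)
  })

  lab <- character(n)
  lab[res$is_target] <- res$tar
  lab[!res$is_target] <- res$non
  all_lab <- c(res$warm, lab)
  parts <- strsplit(all_lab, "_", fixed = TRUE)
  wu <- design$warmup_count
  events <- data.frame(
    color = vapply(parts, `[`, "", 1L),
    orientation = vapply(parts, `[`, "", 2L),
    is_target = c(rep(FALSE, wu), res$is_target),
    role = c(rep("warmup", wu), rep("main", n)),
    is_warmup = c(rep(TRUE, wu), rep(FALSE, n)),
    stringsAsFactors = FALSE)
  new_visual_sequence(design, events)
}

## Target and non-target color-orientation combinations per load level.
## Low load: targets are red crosses irrespective of orientation.
## High load: targets are upright yellow and inverted green crosses.
target_combinations <- function(load) {
  all_combos <- as.vector(outer(CROSS_COLORS, CROSS_ORIENTATIONS, paste,
                                sep = "_"))
  tar <- if (load == "low") {
    c("red_upright", "red_inverted")
  } else {
    c("yellow_upright", "green_inverted")
  }
  list(target = tar, nontarget = setdiff(all_combos, tar))
}

#' Compose a full session of eight blocks
#'
#' The four load-by-tone conditions are presented twice; blocks 1-4 and
#' 5-8 are each an independent random permutation of the four conditions.
#' Each block carries a paired tone and visual sequence with targets
#' stratified across tone classes.
#'
#' @param seed Integer seed for the whole session.
#' @param n_trials Trials per block.
#' @param ... Further arguments passed to [block_design()].
#' @return A list of eight elements, each
#'   `list(design, tones, visual)`.
#' @export
compose_session <- function(seed, n_trials = 360L, ...) {
  conditions <- expand.grid(load = c("low", "high"),
                            tone_condition = c("oddball", "control"),
                            stringsAsFactors = FALSE)
  ord <- with_seed(seed, c(sample.int(4L), sample.int(4L)))
  seeds <- derive_seeds(seed + 1L, 16L)
  blocks <- vector("list", 8L)
  for (b in seq_len(8L)) {
    cond <- conditions[ord[b], ]
    design <- block_design(load = cond$load, tone_condition = cond$tone_condition,
                           n_trials = n_trials, ...)
    tones <- if (cond$tone_condition == "oddball") {
      generate_oddball_block(design, seed = seeds[2L * b - 1L])
    } else {
      generate_control_block(design, seed = seeds[2L * b - 1L])
    }
    visual <- generate_visual_block(design, seed = seeds[2L * b], tones = tones)
    blocks[[b]] <- list(design = design, tones = tones, visual = visual)
  }
  blocks
}

add_violation <- function(report, constraint, index, detail) {
  rbind(report, data.frame(constraint = constraint, index = index,
                           detail = detail, stringsAsFactors = FALSE))
}

#' Validate a generated sequence against its design constraints
#'
#' Never raises on bad content; every violated constraint is returned with
#' the offending (0-based) index. An empty report means the sequence
#' satisfies all invariants.
#'
#' @param seq A `tone_sequence` or `visual_sequence`.
#' @return A data frame with columns `constraint`, `index`, `detail`
#'   (zero rows if valid).
#' @export
validate_block <- function(seq) {
  report <- data.frame(constraint = character(), index = integer(),
                       detail = character(), stringsAsFactors = FALSE)
  design <- seq$design
  ev <- seq$events
  main <- ev[!ev$is_warmup, ]

  if (inherits(seq, "tone_sequence") && design$tone_condition == "oddball") {
    n_dev <- sum(main$role == "deviant")
    want <- round(design$n_trials * design$deviant_rate)
    if (n_dev != want) {
      report <- add_violation(report, "deviant_count", NA_integer_,
                              sprintf("%d deviants, expected %d", n_dev, want))
    }
    bad <- main$role == "deviant" & main$frequency != ODDBALL_DEVIANT_HZ
    for (i in which(bad)) {
      report <- add_violation(report, "deviant_frequency", main$index[i],
                              sprintf("deviant at %d Hz", main$frequency[i]))
    }
    if (!all(main$frequency %in% c(ODDBALL_DEVIANT_HZ, ODDBALL_STANDARD_HZ))) {
      report <- add_violation(report, "oddball_frequencies", NA_integer_,
                              "frequency outside {500, 550}")
    }
    dev_pos <- which(main$role == "deviant")
    if (length(dev_pos) > 1L) {
      gaps <- diff(dev_pos) - 1L
      for (i in which(gaps < 3L)) {
        report <- add_violation(report, "min_gap", main$index[dev_pos[i + 1L]],
                                sprintf("only %d standards before this deviant",
                                        gaps[i]))
      }
    }
  }

  if (inherits(seq, "tone_sequence") && design$tone_condition == "control") {
    freqs <- sort(unique(main$frequency))
    nf <- length(freqs)
    n_sets <- nrow(main) %/% nf
    for (s in seq_len(n_sets)) {
      set <- main$frequency[((s - 1L) * nf + 1L):(s * nf)]
      if (!setequal(set, freqs) || anyDuplicated(set)) {
        report <- add_violation(report, "set_permutation",
                                main$index[(s - 1L) * nf + 1L],
                                sprintf("set %d is not a permutation", s))
      }
    }
    rep_at <- which(diff(main$frequency) == 0)
    for (i in rep_at) {
      report <- add_violation(report, "boundary_repeat", main$index[i + 1L],
                              sprintf("%d Hz repeated", main$frequency[i]))
    }
    tab <- table(main$frequency)
    if (length(unique(as.integer(tab))) > 1L) {
      report <- add_violation(report, "frequency_counts", NA_integer_,
                              "unequal frequency counts")
    }
  }

  if (inherits(seq, "visual_sequence")) {
    n_tar <- sum(main$is_target)
    want <- round(design$n_trials * design$target_rate)
    if (n_tar != want) {
      report <- add_violation(report, "target_count", NA_integer_,
                              sprintf("%d targets, expected %d", n_tar, want))
    }
    tar_pos <- which(main$is_target)
    gaps <- diff(c(0L, tar_pos)) - 1L
    for (i in which(gaps < 2L | gaps > 6L)) {
      report <- add_violation(report, "target_gap", main$index[tar_pos[i]],
                              sprintf("gap of %d non-targets", gaps[i]))
    }
    combos <- target_combinations(design$load)
    lab <- paste(main$color, main$orientation, sep = "_")
    if (any(main$is_target & !lab %in% combos$target) ||
        any(!main$is_target & !lab %in% combos$nontarget)) {
      report <- add_violation(report, "target_rule", NA_integer_,
                              "target flag inconsistent with load rule")
    }
    tt <- table(lab[main$is_target])
    nt <- table(lab[!main$is_target])
    if (length(tt) != length(combos$target) ||
        length(unique(as.integer(tt))) > 1L) {
      report <- add_violation(report, "target_combo_balance", NA_integer_,
                              "target combinations not equally frequent")
    }
    if (length(nt) != length(combos$nontarget) ||
        length(unique(as.integer(nt))) > 1L) {
      report <- add_violation(report, "nontarget_combo_balance", NA_integer_,
                              "non-target combinations not equally frequent")
    }
    warm <- ev[ev$is_warmup, ]
    if (any(warm$is_target)) {
      report <- add_violation(report, "warmup_target",
                              warm$index[warm$is_target][1L],
                              "warm-up trial flagged as target")
    }
  }
  report
}

#' Validate a composed session
#'
#' Checks every block with [validate_block()], the condition counts across
#' the eight blocks, and the tone-target independence constraint (the
#' target rate among 500-Hz tones equals the nominal target rate exactly).
#'
#' @param session Output of [compose_session()].
#' @return A data frame of violations (zero rows if valid).
#' @export
validate_session <- function(session) {
  report <- data.frame(constraint = character(), index = integer(),
                       detail = character(), stringsAsFactors = FALSE)
  conds <- vapply(session, function(b) {
    paste(b$design$load, b$design$tone_condition)
  }, "")
  for (half in list(1:4, 5:8)) {
    if (length(unique(conds[half])) != 4L) {
      report <- add_violation(report, "condition_permutation", half[1L] - 1L,
                              "four conditions not all present in half-session")
    }
  }
  for (b in seq_along(session)) {
    blk <- session[[b]]
    rep_b <- rbind(validate_block(blk$tones), validate_block(blk$visual))
    if (nrow(rep_b)) {
      rep_b$detail <- paste0("block ", b, ": ", rep_b$detail)
      report <- rbind(report, rep_b)
    }
    tm <- blk$tones$events[!blk$tones$events$is_warmup, ]
    vm <- blk$visual$events[!blk$visual$events$is_warmup, ]
    is500 <- tm$frequency == ODDBALL_DEVIANT_HZ
    r500 <- mean(vm$is_target[is500])
    rrest <- mean(vm$is_target[!is500])
    if (abs(r500 - blk$design$target_rate) > 1e-12 ||
        abs(rrest - blk$design$target_rate) > 1e-12) {
      report <- add_violation(report, "tone_target_independence", NA_integer_,
                              sprintf("block %d: target rate %.3f on 500 Hz, %.3f elsewhere",
                                      b, r500, rrest))
    }
  }
  report
}

#' Serialize paired tone and visual sequences to TSV
#'
#' One row per event with columns `index`, `onset_ms`, `stream`
#' (tone/visual), `value` (frequency in Hz or `color_orientation`),
#' `role`, `is_target`, `is_warmup`.
#'
#' @param tones A `tone_sequence`.
#' @param visual A `visual_sequence`.
#' @param path Output file path.
#' @export
write_sequence_tsv <- function(tones, visual, path) {
  te <- tones$events
  ve <- visual$events
  out <- rbind(
    data.frame(index = te$index, onset_ms = te$onset_ms, stream = "tone",
               value = as.character(te$frequency), role = te$role,
               is_target = NA, is_warmup = te$is_warmup,
               stringsAsFactors = FALSE),
    data.frame(index = ve$index, onset_ms = ve$onset_ms, stream = "visual",
               value = paste(ve$color, ve$orientation, sep = "_"),
               role = ve$role, is_target = ve$is_target,
               is_warmup = ve$is_warmup, stringsAsFactors = FALSE))
  out <- out[order(out$index, out$stream), ]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
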