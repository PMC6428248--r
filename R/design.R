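#' Canonical duration sets of the two paradigms
#'
#' `exp1_durations()` returns the four first-stimulus (S1) durations of the
#' jittered event-related paradigm. `exp2_pairs()` returns the ten
#' standard/comparison duration pairs of the cyclic paradigm (comparison =
#' 1.5 x standard), and `exp2_durations()` the 17 unique durations their
#' union produces.
#'
#' @return numeric vector of seconds, or for `exp2_pairs()` a data frame
#'   with columns `pair_id`, `standard`, `comparison`.
#' @export
exp1_durations <- function() c(0.2, 0.4, 0.6, 1.0)

#' @rdname exp1_durations
#' @export
exp2_pairs <- function() {
  std <- seq(0.2, 2.0, by = 0.2)
  data.frame(pair_id = 1:10, standard = round(std, 9),
             comparison = round(1.5 * std, 9))
}

#' @rdname exp1_durations
#' @export
exp2_durations <- function() {
  p <- exp2_pairs()
  sort(unique(round(c(p$standard, p$comparison), 9)))
}

# Orientations of the Gabor patch used for S1; combined with the four
# durations they give the 16 S1 stimulus types presented once per run.
exp1_orientations <- function() c(36, 72, 108, 144)

#' Build the jittered pair-comparison design (Exp 1)
#'
#' Each run holds 16 trials, one per (S1 duration, S1 orientation)
#' combination: S1 (0.2/0.4/0.6/1 s), a variable interstimulus interval of
#' 4-5.2 s in 0.08-s steps, S2 longer or shorter than S1 by a Weber ratio
#' of 0.4, and a 2-s response cue. Trial order is shuffled per run. The
#' scan grid is 169 volumes at an effective sampling interval of 1.368 s.
#'
#' A 1-s lead-in precedes the first trial and a fixed 4.5-s inter-trial
#' interval follows each response cue, chosen so that the longest possible
#' event sequence still ends before the run does.
#'
#' @param n_runs number of runs (>= 1).
#' @param seed integer seed; the per-run shuffles and draws derive from it.
#' @return list of runs, each `list(events = event_table, scan = scan_grid)`.
#' @export
build_exp1_design <- function(n_runs, seed = 1L) {
  stopifnot(n_runs >= 1)
  isi_grid <- seq(4.00, 5.20, by = 0.08)
  types <- expand.grid(duration = exp1_durations(),
                       orientation = exp1_orientations())
  rng <- local_rng(seed)
  lapply(seq_len(n_runs), function(run) {
    ord <- rng$sample(nrow(types))
    isi <- rng$sample_from(isi_grid, nrow(types), replace = TRUE)
    longer <- rng$sample_from(c(TRUE, FALSE), nrow(types), replace = TRUE)
    t <- 1.0                               # lead-in
    rows <- vector("list", nrow(types))
    for (i in seq_len(nrow(types))) {
      d1 <- types$duration[ord[i]]
      d2 <- d1 * (1 + if (longer[i]) 0.4 else -0.4)
      s1_on <- t
      s2_on <- s1_on + d1 + isi[i]
      cue_on <- s2_on + d2
      rows[[i]] <- data.frame(
        onset = c(s1_on, s2_on, cue_on),
        duration = c(d1, d2, 2.0),
        duration_label = c(d1, d2, 2.0),
        role = c("S1", "S2", "response_cue"),
        trial_index = i - 1L,
        orientation = c(types$orientation[ord[i]], NA, NA))
      t <- cue_on + 2.0 + 4.5              # response cue + inter-trial gap
    }
    rows <- do.call(rbind, rows)
    ev <- event_table(rows$onset, rows$duration, rows$duration_label,
                      rows$role, rows$trial_index)
    ev$orientation <- rows$orientation[order(rows$onset)]
    scan <- scan_grid(tr = 1.368, n_volumes = 169L, run_id = run)
    if (max(ev$onset + ev$duration) > run_length(scan))
      stop("events extend past run end")              # cannot happen by design
    list(events = ev, scan = scan)
  })
}

#' Build the cyclic design (Exp 2)
#'
#' One cycle holds the ten duration pairs (standard T = 0.2...2 s,
#' comparison 1.5 T), ordered short-to-long (`ascending`) or long-to-short
#' (`descending`). Within a trial, standard-first versus comparison-first
#' is randomized and counterbalanced (5/5 per cycle); S1 is followed
#' immediately by S2 and then by a 1.37-s vertical-orientation interval.
#' Cycles are separated by a 2.03-s vertical interval and padded with
#' vertical orientation to exactly 44 s (22 volumes at TR 2 s).
#'
#' @param direction `"ascending"` or `"descending"`.
#' @param n_cycles number of cycles (>= 1).
#' @param seed integer seed for the standard/comparison order; the same
#'   seed produces a descending run that is the trial-by-trial reverse of
#'   the ascending one.
#' @return `list(events = event_table, scan = scan_grid)`.
#' @export
build_exp2_design <- function(direction = c("ascending", "descending"),
                              n_cycles = 10L, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(n_cycles >= 1)
  pairs <- exp2_pairs()
  cycle_len <- 44
  vertical_iti <- 1.37
  inter_cycle <- 2.03
  rng <- local_rng(seed)
  # standard-first patterns: 5/5 within every cycle, and consecutive
  # cycles complement each other so every pair occurs in both orders
  # (hence S1 visits all 17 durations); drawn on the ascending pair order
  # so ascending/descending runs share them trial-by-trial
  sf <- matrix(NA, n_cycles, 10)
  for (cyc in seq_len(n_cycles)) {
    sf[cyc, ] <- if (cyc %% 2 == 0) !sf[cyc - 1, ]
    else rng$sample_from(rep(c(TRUE, FALSE), 5), 10)
  }
  rows <- list()
  for (cyc in seq_len(n_cycles)) {
    std_first <- sf[cyc, ]
    ord <- if (direction == "ascending") 1:10 else 10:1
    t <- (cyc - 1) * cycle_len
    for (k in seq_along(ord)) {
      p <- ord[k]
      d_std <- pairs$standard[p]; d_cmp <- pairs$comparison[p]
      d1 <- if (std_first[p]) d_std else d_cmp
      d2 <- if (std_first[p]) d_cmp else d_std
      rows[[length(rows) + 1L]] <- data.frame(
        onset = c(t, t + d1, t + d1 + d2),
        duration = c(d1, d2, vertical_iti),
        duration_label = c(d1, d2, vertical_iti),
        role = c("S1", "S2", "vertical"),
        trial_index = (cyc - 1L) * 10L + k - 1L,
        cycle_index = cyc - 1L,
        pair_id = pairs$pair_id[p])
      t <- t + d1 + d2 + vertical_iti
    }
    # inter-cycle interval plus tail padding to a 44-s cycle
    pad <- cyc * cycle_len - t
    stopifnot(pad >= inter_cycle - 1e-9)
    rows[[length(rows) + 1L]] <- data.frame(
      onset = t, duration = pad, duration_label = pad,
      role = "vertical", trial_index = NA_integer_,
      cycle_index = cyc - 1L, pair_id = NA_integer_)
  }
  rows <- do.call(rbind, rows)
  ev <- event_table(rows$onset, rows$duration, rows$duration_label,
                    rows$role, rows$trial_index, rows$cycle_index,
                    rows$pair_id)
  scan <- scan_grid(tr = 2.0, n_volumes = 22L * n_cycles,
                    direction = direction)
  list(events = ev, scan = scan)
}

# Deterministic RNG scoped to the design builders: draws come from an
# isolated stream so callers' RNG state is untouched.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample = function(n) with_state(function() sample.int(n)),
    sample_from = function(x, size, replace = FALSE)
      with_state(function() x[sample.int(length(x), size, replace = replace)]),
    runif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd))
  )
}
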