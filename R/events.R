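#' Construct a stimulus event table
#'
#' An event table is an ordinary data frame with one row per stimulus event
#' on a run clock that starts at 0 s. It is the shared currency between the
#' design builders, the BOLD simulator and every analysis stage.
#'
#' @param onset numeric, seconds from run start.
#' @param duration numeric, event duration in seconds (> 0).
#' @param duration_label numeric, the nominal S1/S2 duration in seconds that
#'   the event instantiates (equals `duration` for S1/S2 events; for cue and
#'   vertical events it is the fixed event length).
#' @param role character, one of `"S1"`, `"S2"`, `"response_cue"`,
#'   `"vertical"`.
#' @param trial_index integer trial counter within the run (0-based).
#' @param cycle_index integer cycle counter (0-based) or `NA` when the
#'   paradigm has no cycles.
#' @param pair_id integer duration-pair identifier (1-10) or `NA`.
#' @return A `data.frame` of class `event_table`, sorted by onset.
#' @export
event_table <- function(onset, duration, duration_label, role,
                        trial_index, cycle_index = NA_integer_,
                        pair_id = NA_integer_) {
  ev <- data.frame(
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    duration_label = as.numeric(duration_label),
    role = as.character(role),
    trial_index = as.integer(trial_index),
    cycle_index = as.integer(cycle_index),
    pair_id = as.integer(pair_id),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  validate_event_table(ev)
  ev
}

validate_event_table <- function(ev) {
  stopifnot(all(c("onset", "duration", "duration_label", "role") %in%
                  names(ev)))
  if (any(ev$onset < 0)) stop("event onsets must be >= 0")
  if (any(ev$duration <= 0)) stop("event durations must be > 0")
  bad <- !ev$role %in% c("S1", "S2", "response_cue", "vertical")
  if (any(bad)) stop("unknown event role: ", paste(unique(ev$role[bad]),
                                                   collapse = ", "))
  off <- ev$onset + ev$duration
  if (nrow(ev) > 1 && any(ev$onset[-1] < off[-nrow(ev)] - 1e-9))
    stop("events overlap within the run")
  invisible(ev)
}

#' Construct a scan grid
#'
#' Describes the sampling of one fMRI run: the repetition time (the
#' effective volume acquisition interval) and the number of volumes.
#'
#' @param tr seconds per volume (> 0).
#' @param n_volumes number of volumes (> 0).
#' @param run_id integer run identifier.
#' @param direction `"ascending"`, `"descending"` or `"none"` (cycle order
#'   for cyclic paradigms).
#' @return A list of class `scan_grid`.
#' @export
scan_grid <- function(tr, n_volumes, run_id = 1L,
                      direction = c("none", "ascending", "descending")) {
  direction <- match.arg(direction)
  stopifnot(tr > 0, n_volumes > 0)
  structure(list(tr = tr, n_volumes = as.integer(n_volumes),
                 run_id = as.integer(run_id), direction = direction),
            class = "scan_grid")
}

#' Run length of a scan grid in seconds
#' @param scan a `scan_grid`.
#' @return seconds.
#' @export
run_length <- function(scan) scan$tr * scan$n_volumes

#' Volume index containing a time point
#'
#' Event times are continuous seconds; the mapping to volumes is
#' `floor(time / tr)` on a 0-based volume clock. `one_based = TRUE` returns
#' the corresponding R index.
#'
#' @param time seconds from run start.
#' @param tr seconds per volume.
#' @param one_based return 1-based indices (default `FALSE`).
#' @return integer volume indices.
#' @export
volume_index <- function(time, tr, one_based = FALSE) {
  # guard against 10.0 / 2 landing one volume late through float error
  v <- as.integer(floor(time / tr + 1e-9))
  if (one_based) v + 1L else v
}

#' Unique presented S1 durations of a design
#'
#' Returns the sorted set of nominal S1 durations (standards and
#' comparisons pooled), the duration bins over which offset-locked analyses
#' operate.
#'
#' @param design an `event_table` (or list of them, pooled).
#' @return sorted numeric vector of seconds.
#' @export
enumerate_s1_durations <- function(design) {
  if (is.data.frame(design)) design <- list(design)
  labs <- unlist(lapply(design, function(ev) ev$duration_label[ev$role == "S1"]))
  if (length(labs) == 0) stop("design contains no S1 events")
  sort(unique(round(labs, 9)))
}

#' Write / read an event table as tab-separated text
#'
#' The on-disk dialect has columns `onset`, `duration`, `trial_type`,
#' `role`, `pair_id`, `cycle` (seconds on a 0-based run clock);
#' `trial_type` carries the nominal duration label.
#'
#' @param ev an `event_table`.
#' @param path file path.
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns an `event_table`.
#' @export
write_events_tsv <- function(ev, path) {
  out <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$duration_label, role = ev$role,
                    pair_id = ev$pair_id, cycle = ev$cycle_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  event_table(onset = x$onset, duration = x$duration,
              duration_label = x$trial_type, role = x$role,
              trial_index = seq_len(nrow(x)) - 1L,
              cycle_index = x$cycle, pair_id = x$pair_id)
}
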