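# --- reconciling single-bit markers with the presentation log ---------------
#
# Acquisition chains with single-bit trigger lines record an undifferentiated
# pulse train; condition identity lives in the presentation log. Some pulses
# may be lost. match_events aligns the recorded train to the log monotonely
# using inter-onset intervals and transfers the log labels.

#' Match recorded markers against a presentation log
#'
#' Greedy, order-preserving alignment: walking the log and marker train in
#' parallel, a marker is matched to the next log row whose predicted time
#' (log onset plus the current clock offset) agrees within `tolerance_ms`;
#' log rows with no matching marker are reported as lost triggers. The
#' clock offset is estimated from the first marker and re-anchored at every
#' match, which absorbs slow drift. Markers are never reordered.
#'
#' @param rec An [eeg_recording()] whose `markers` are the recorded pulses.
#' @param log A presentation-log data frame
#'   (`trial_index`, `label`, `onset_ms`, `code`), see
#'   [read_presentation_log()].
#' @param tolerance_ms Matching tolerance in ms.
#' @param dp Use a dynamic-programming alignment instead of the greedy pass
#'   (robust to pathological loss patterns; slower).
#' @return An [event_sequence] of the matched events (onsets from the
#'   recording clock, labels from the log), with attributes `lost_triggers`
#'   (count of unmatched log rows), `lost_rows` (their `trial_index`), and
#'   `matched_log_rows`.
#' @export
match_events <- function(rec, log, tolerance_ms = 20, dp = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  mk <- rec$markers
  if (nrow(mk) > 1 && is.unsorted(mk$sample)) {
    stop_invalid("recorded markers must be monotone")
  }
  marker_ms <- mk$sample / rec$rate_hz * 1000
  log_ms <- log$onset_ms
  n_log <- length(log_ms); n_mk <- length(marker_ms)
  if (n_log == 0) {
    return(structure(new_event_sequence(empty_events(), "unknown", 0),
                     lost_triggers = 0L, lost_rows = integer(0),
                     matched_log_rows = integer(0)))
  }

  assign_idx <- if (dp) {
    match_events_dp(marker_ms, log_ms, tolerance_ms)
  } else {
    match_events_greedy(marker_ms, log_ms, tolerance_ms)
  }
  matched <- which(!is.na(assign_idx))           # marker indices with a row
  rows <- assign_idx[matched]
  lost_rows <- setdiff(seq_len(n_log), rows)
  if (length(lost_rows) > n_log / 2) {
    stop_invalid("alignment failure: %d of %d log rows unmatched",
                 length(lost_rows), n_log)
  }
  if (length(matched) == 0) {
    ev <- empty_events()
  } else {
    ev <- data.frame(onset_s = marker_ms[matched] / 1000,
                     code = log$code[rows],
                     label = log$label[rows],
                     duration_s = 0, stringsAsFactors = FALSE)
  }
  total <- if (nrow(ev) > 0) max(ev$onset_s) else 0
  total <- max(total, n_samples(rec) / rec$rate_hz)
  out <- new_event_sequence(ev, task_guess(log$label), total)
  attr(out, "lost_triggers") <- length(lost_rows)
  attr(out, "lost_rows") <- log$trial_index[lost_rows]
  attr(out, "matched_log_rows") <- log$trial_index[rows]
  out
}

task_guess <- function(labels) {
  u <- unique(labels)
  if (all(u %in% c("EO", "EC"))) return("resting")
  if (all(grepl("Hz$", u))) return("ssvep")
  if (all(u %in% c("face", "texture"))) return("face")
  if (all(u %in% c("standard", "deviant"))) return("active_oddball")
  "unknown"
}

# greedy inter-onset-interval matching: anchor the clock offset on the
# first marker, then advance through the log, matching each marker to the
# earliest compatible pending row. Because the first trigger itself may
# have been lost, several initial anchors are tried and the one matching
# the most markers wins.
match_events_greedy <- function(marker_ms, log_ms, tol) {
  n_mk <- length(marker_ms)
  if (n_mk == 0) return(rep(NA_integer_, n_mk))
  n_log <- length(log_ms)
  best <- rep(NA_integer_, n_mk)
  for (start_row in seq_len(min(8L, n_log))) {
    cand <- greedy_pass(marker_ms, log_ms, tol, start_row)
    if (sum(!is.na(cand)) > sum(!is.na(best))) best <- cand
    if (sum(!is.na(best)) == n_mk) break
  }
  best
}

greedy_pass <- function(marker_ms, log_ms, tol, start_row) {
  n_mk <- length(marker_ms); n_log <- length(log_ms)
  assign_idx <- rep(NA_integer_, n_mk)
  offset <- marker_ms[1] - log_ms[start_row]
  row <- start_row
  for (i in seq_len(n_mk)) {
    while (row <= n_log &&
           marker_ms[i] - (log_ms[row] + offset) > tol) {
      row <- row + 1L  # log row skipped: its trigger was lost
    }
    if (row > n_log) break
    if (abs(marker_ms[i] - (log_ms[row] + offset)) <= tol) {
      assign_idx[i] <- row
      offset <- marker_ms[i] - log_ms[row]  # re-anchor (drift absorption)
      row <- row + 1L
    }
    # else: marker arrives before the predicted row time (spurious pulse);
    # leave unmatched and keep the row pending
  }
  assign_idx
}

# dynamic-programming fallback: monotone alignment minimizing the total
# inter-onset-interval discrepancy, with a fixed penalty per skipped row
match_events_dp <- function(marker_ms, log_ms, tol) {
  n_mk <- length(marker_ms); n_log <- length(log_ms)
  assign_idx <- rep(NA_integer_, n_mk)
  if (n_mk == 0) return(assign_idx)
  if (n_mk > n_log) return(match_events_greedy(marker_ms, log_ms, tol))
  dm <- diff(marker_ms)
  skip_cost <- tol
  # cost[i, j]: best cost matching marker i to row j
  big <- Inf
  cost <- matrix(big, n_mk, n_log)
  back <- matrix(0L, n_mk, n_log)
  cost[1, ] <- (seq_len(n_log) - 1) * skip_cost
  for (i in 2:max(2, n_mk)) {
    if (i > n_mk) break
    for (j in i:n_log) {
      prev <- (i - 1):(j - 1)
      cand <- cost[i - 1, prev] +
        abs(dm[i - 1] - (log_ms[j] - log_ms[prev])) +
        (j - prev - 1) * skip_cost
      b <- which.min(cand)
      cost[i, j] <- cand[b]
      back[i, j] <- prev[b]
    }
  }
  j <- which.min(cost[n_mk, ])
  if (!is.finite(cost[n_mk, j])) return(assign_idx)
  for (i in n_mk:1) {
    assign_idx[i] <- j
    if (i > 1) j <- back[i, j]
  }
  assign_idx
}
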