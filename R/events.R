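#' Event sequences for the five benchmark paradigms
#'
#' An `event_sequence` holds ordered stimulus markers (onset, small integer
#' code, condition label, stimulus duration) for one task, plus optional
#' block metadata for the continuous paradigms (resting state, SSVEP).
#'
#' @name event_sequence
NULL

TASKS <- c("resting", "ssvep", "face", "active_oddball", "passive_oddball")

task_vocabulary <- function(task, freqs_hz = NULL) {
  switch(task,
    resting = c(EO = 1L, EC = 2L),
    ssvep = stats::setNames(seq_along(freqs_hz), sprintf("%gHz", freqs_hz)),
    face = c(face = 1L, texture = 2L),
    active_oddball = c(standard = 1L, deviant = 2L),
    passive_oddball = c(standard = 1L, deviant = 2L),
    stop_invalid("unknown task '%s'", task)
  )
}

new_event_sequence <- function(events, task, total_duration_s, blocks = NULL) {
  stopifnot(is.data.frame(events),
            all(c("onset_s", "code", "label", "duration_s") %in% names(events)))
  if (nrow(events) > 1 && any(diff(events$onset_s) <= 0)) {
    stop_invalid("event onsets must be strictly increasing")
  }
  if (nrow(events) > 0) {
    last_end <- events$onset_s[nrow(events)] + events$duration_s[nrow(events)]
    if (total_duration_s < last_end - 1e-9) {
      stop_invalid("total_duration_s (%.3f) shorter than last stimulus end (%.3f)",
                   total_duration_s, last_end)
    }
  }
  structure(
    list(events = events, task = task,
         total_duration_s = total_duration_s, blocks = blocks),
    class = "event_sequence"
  )
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence> task=%s, %d events, %.1f s\n",
              x$task, nrow(x$events), x$total_duration_s))
  if (nrow(x$events) > 0) print(utils::head(table(x$events$label)))
  invisible(x)
}

#' Number of events in a sequence
#' @param seq An `event_sequence`.
#' @return Integer count.
#' @export
n_events <- function(seq) nrow(seq$events)

empty_events <- function() {
  data.frame(onset_s = numeric(0), code = integer(0),
             label = character(0), duration_s = numeric(0),
             stringsAsFactors = FALSE)
}

#' Generate a resting-state block sequence
#'
#' Blocks alternate between eyes-open (EO) and eyes-closed (EC), starting
#' with EO. Defaults give four 1-min blocks (4 min total).
#'
#' @param block_len_s Block length in seconds.
#' @param n_blocks Number of blocks; must be even so conditions balance.
#' @param seed Unused (the design is deterministic); kept for interface
#'   symmetry with the other generators.
#' @return An `event_sequence` with one marker per block onset and a
#'   `blocks` table giving each block's condition and time span.
#' @export
gen_resting_events <- function(block_len_s = 60, n_blocks = 4, seed = NULL) {
  if (n_blocks %% 2 != 0 || n_blocks < 0) {
    stop_invalid("n_blocks must be even and non-negative (got %s)", n_blocks)
  }
  if (n_blocks > 0 && block_len_s <= 0) stop_invalid("block_len_s must be > 0")
  if (n_blocks == 0) {
    return(new_event_sequence(empty_events(), "resting", 0,
                              blocks = data.frame(label = character(0),
                                                  start_s = numeric(0),
                                                  end_s = numeric(0))))
  }
  vocab <- task_vocabulary("resting")
  labels <- rep(c("EO", "EC"), length.out = n_blocks)
  onsets <- (seq_len(n_blocks) - 1) * block_len_s
  events <- data.frame(onset_s = onsets, code = unname(vocab[labels]),
                       label = labels, duration_s = block_len_s,
                       stringsAsFactors = FALSE)
  blocks <- data.frame(label = labels, start_s = onsets,
                       end_s = onsets + block_len_s, stringsAsFactors = FALSE)
  new_event_sequence(events, "resting", n_blocks * block_len_s, blocks)
}

#' Generate an SSVEP flicker sequence
#'
#' Blocks of periodic flashes at the requested frequencies, in an order
#' randomized by `seed`. Each block starts with a fixation lead, then one
#' flash-onset marker per cycle; the flash on-duration is half the cycle
#' (equal on/off phases), i.e. 83.3 ms at 6 Hz, 50 ms at 10 Hz and 33.3 ms
#' at 15 Hz.
#'
#' @param freqs_hz Flicker frequencies (Hz).
#' @param blocks_per_freq Blocks per frequency.
#' @param block_len_s Flicker duration of one block (s), excluding the lead.
#' @param fixation_lead_s Fixation period before the first flash (s).
#' @param seed Integer seed controlling block order.
#' @param refresh_hz Display refresh rate used only to warn when a flash
#'   on-phase is shorter than one frame.
#' @return An `event_sequence` with per-flash markers and a `blocks` table
#'   (frequency, flicker start/end) used for condition segmentation.
#' @export
gen_ssvep_events <- function(freqs_hz = c(6, 10, 15), blocks_per_freq = 2,
                             block_len_s = 30, fixation_lead_s = 2,
                             seed = 1, refresh_hz = 60) {
  if (length(freqs_hz) == 0) stop_invalid("freqs_hz must be non-empty")
  if (any(freqs_hz <= 0)) stop_invalid("frequencies must be positive")
  short <- freqs_hz[1 / (2 * freqs_hz) < 1 / refresh_hz]
  if (length(short) > 0) {
    warning(sprintf("flash on-phase shorter than one %g Hz frame for: %s Hz",
                    refresh_hz, paste(short, collapse = ", ")))
  }
  vocab <- task_vocabulary("ssvep", freqs_hz = sort(freqs_hz))
  pool <- rep(freqs_hz, each = blocks_per_freq)
  order_freqs <- with_seed(seed, pool[sample.int(length(pool))])
  block_span <- fixation_lead_s + block_len_s
  ev <- list(); blk <- list()
  for (b in seq_along(order_freqs)) {
    f <- order_freqs[b]
    t0 <- (b - 1) * block_span + fixation_lead_s
    n_flash <- floor(block_len_s * f + 1e-9)
    onsets <- t0 + (seq_len(n_flash) - 1) / f
    lab <- sprintf("%gHz", f)
    ev[[b]] <- data.frame(onset_s = onsets, code = unname(vocab[lab]),
                          label = lab, duration_s = 1 / (2 * f),
                          stringsAsFactors = FALSE)
    blk[[b]] <- data.frame(label = lab, freq_hz = f, start_s = t0,
                           end_s = t0 + block_len_s, stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, ev)
  blocks <- do.call(rbind, blk)
  new_event_sequence(events, "ssvep", length(order_freqs) * block_span, blocks)
}

# cumulative quartile boundaries: floor(n * q / 4), matching the floor rule
# used by pack reduction so first-75%/50% subsets keep proportional counts
quartile_bounds <- function(n) floor(n * (0:4) / 4)

#' Generate a face/texture discrimination sequence
#'
#' Half the trials are faces and half textures, shuffled within each
#' quartile of the sequence so that any leading fraction keeps the 50/50
#' ratio (first half of 300 trials contains exactly 75 faces).
#'
#' @param n_trials Total trial count (even).
#' @param stim_ms Stimulus duration (ms).
#' @param fix_ms Fixation duration after the stimulus (ms); stimulus onset
#'   asynchrony is `stim_ms + fix_ms`.
#' @param seed Integer seed for the within-quartile shuffles.
#' @return An `event_sequence`.
#' @export
gen_face_events <- function(n_trials = 300, stim_ms = 300, fix_ms = 1000,
                            seed = 1) {
  if (n_trials %% 2 != 0 || n_trials < 0) {
    stop_invalid("n_trials must be even and non-negative (got %s)", n_trials)
  }
  if (n_trials == 0) return(new_event_sequence(empty_events(), "face", 0))
  vocab <- task_vocabulary("face")
  qb <- quartile_bounds(n_trials)
  fb <- quartile_bounds(n_trials / 2)  # cumulative face counts per quartile
  labels <- with_seed(seed, {
    unlist(lapply(1:4, function(q) {
      len <- qb[q + 1] - qb[q]
      n_face <- fb[q + 1] - fb[q]
      sample(c(rep("face", n_face), rep("texture", len - n_face)))
    }))
  })
  soa_s <- (stim_ms + fix_ms) / 1000
  events <- data.frame(onset_s = (seq_len(n_trials) - 1) * soa_s,
                       code = unname(vocab[labels]), label = labels,
                       duration_s = stim_ms / 1000, stringsAsFactors = FALSE)
  new_event_sequence(events, "face", n_trials * soa_s)
}

# sample k deviant slots among n trials with >= gap standards between
# successive deviants and >= lead standards before the first; uniform over
# feasible placements via the standard stars-and-bars shift
sample_gapped_positions <- function(n, k, gap, lead) {
  if (k == 0) return(integer(0))
  slack <- n - lead - k - gap * (k - 1)
  if (slack < 0) stop_invalid("gap constraint unsatisfiable: n=%d k=%d gap=%d lead=%d",
                              n, k, gap, lead)
  base <- sort(sample.int(slack + k, k))
  lead + base + (seq_len(k) - 1) * gap
}

gen_oddball_labels <- function(n_trials, n_dev, gap, lead) {
  qb <- quartile_bounds(n_trials)
  db <- quartile_bounds(n_dev)
  labels <- rep("standard", n_trials)
  # place deviants quartile by quartile so leading subsets keep proportional
  # counts; the gap constraint is enforced across quartile boundaries by
  # carrying the distance to the previous deviant into the next quartile
  prev_dev <- -Inf
  for (q in 1:4) {
    len <- qb[q + 1] - qb[q]
    k <- db[q + 1] - db[q]
    if (k == 0) next
    need_lead <- if (q == 1) lead else max(0, gap - (qb[q] - prev_dev) + 1)
    pos <- sample_gapped_positions(len, k, gap, need_lead) + qb[q]
    labels[pos] <- "deviant"
    prev_dev <- max(pos)
  }
  labels
}

#' Generate an active auditory oddball sequence
#'
#' Standards and deviants (default 400 trials, 20% deviants) with at least
#' one standard between two deviants and at least four leading standards.
#' Deviants are balanced across sequence quartiles so leading subsets keep
#' proportional deviant counts.
#'
#' @param n_trials Trial count.
#' @param p_deviant Deviant probability; `p_deviant * n_trials` must be
#'   integral.
#' @param sound_ms Sound duration (ms).
#' @param isi_ms Silent interval after each sound (ms).
#' @param seed Integer seed.
#' @param min_lead Number of standards required at the start.
#' @return An `event_sequence`.
#' @export
gen_active_oddball_events <- function(n_trials = 400, p_deviant = 0.2,
                                      sound_ms = 320, isi_ms = 1000,
                                      seed = 1, min_lead = 4) {
  n_dev <- p_deviant * n_trials
  if (abs(n_dev - round(n_dev)) > 1e-9) {
    stop_invalid("p_deviant * n_trials must be an integer (got %.3f)", n_dev)
  }
  n_dev <- as.integer(round(n_dev))
  if (n_trials == 0) {
    return(new_event_sequence(empty_events(), "active_oddball", 0))
  }
  vocab <- task_vocabulary("active_oddball")
  labels <- with_seed(seed, gen_oddball_labels(n_trials, n_dev, gap = 1,
                                               lead = min_lead))
  soa_s <- (sound_ms + isi_ms) / 1000
  events <- data.frame(onset_s = (seq_len(n_trials) - 1) * soa_s,
                       code = unname(vocab[labels]), label = labels,
                       duration_s = sound_ms / 1000, stringsAsFactors = FALSE)
  new_event_sequence(events, "active_oddball", n_trials * soa_s)
}

#' Generate a passive auditory oddball (MMN) sequence
#'
#' Pure-tone stream (default 562 standards + 112 deviants = 674 tones of
#' 70 ms) with at least `min_gap` standards between deviants, jittered
#' inter-trial intervals, and quartile-balanced deviant placement so the
#' first 75%/50% of trials hold proportional deviant counts.
#'
#' @param n_std Number of standard tones.
#' @param n_dev Number of deviant tones.
#' @param tone_ms Tone duration (ms).
#' @param iti_range_ms Length-2 range (ms) of the silent interval between a
#'   tone's offset and the next onset, drawn uniformly.
#' @param min_gap Minimum number of standards between two deviants (and
#'   before the first deviant).
#' @param seed Integer seed.
#' @return An `event_sequence`.
#' @export
gen_passive_oddball_events <- function(n_std = 562, n_dev = 112, tone_ms = 70,
                                       iti_range_ms = c(550, 650),
                                       min_gap = 2, seed = 1) {
  if (n_std < min_gap * n_dev) {
    stop_invalid("need at least min_gap*n_dev standards (%d < %d)",
                 n_std, min_gap * n_dev)
  }
  n_trials <- n_std + n_dev
  if (n_trials == 0) {
    return(new_event_sequence(empty_events(), "passive_oddball", 0))
  }
  vocab <- task_vocabulary("passive_oddball")
  res <- with_seed(seed, {
    labels <- gen_oddball_labels(n_trials, n_dev, gap = min_gap, lead = min_gap)
    itis <- stats::runif(n_trials, iti_range_ms[1], iti_range_ms[2]) / 1000
    list(labels = labels, itis = itis)
  })
  soa <- tone_ms / 1000 + res$itis
  onsets <- cumsum(c(0, soa[-n_trials]))
  events <- data.frame(onset_s = onsets, code = unname(vocab[res$labels]),
                       label = res$labels, duration_s = tone_ms / 1000,
                       stringsAsFactors = FALSE)
  new_event_sequence(events, "passive_oddball",
                     onsets[n_trials] + soa[n_trials], NULL)
}

#' Write a presentation log for an event sequence
#'
#' Tab-separated log with columns `trial_index`, `label`, `onset_ms`,
#' `code` — the dialect consumed by [match_events()].
#'
#' @param seq An `event_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presentation_log <- function(seq, path) {
  df <- data.frame(trial_index = seq_len(n_events(seq)),
                   label = seq$events$label,
                   onset_ms = seq$events$onset_s * 1000,
                   code = seq$events$code)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a presentation log
#'
#' @param path Path to a tab-separated log written by
#'   [write_presentation_log()].
#' @return A data frame with columns `trial_index`, `label`, `onset_ms`,
#'   `code`.
#' @export
read_presentation_log <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("trial_index", "label", "onset_ms", "code")
  if (!all(need %in% names(df))) {
    stop_invalid("presentation log %s lacks columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (anyDuplicated(df$trial_index)) stop_invalid("duplicate trial_index in %s", path)
  if (is.unsorted(df$onset_ms)) stop_invalid("onsets must be nondecreasing in %s", path)
  df
}
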