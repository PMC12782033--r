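# --- full within-subject benchmark orchestration ----------------------------
#
# N virtual participants x 3 system profiles x 5 tasks x packs, from event
# generation through simulation, preprocessing, measurement and statistics.
# Continuous tasks (resting, SSVEP) are measured at the equalized 128 Hz
# rate with time-fraction reduction for the 75/50 packs; ERP tasks use
# trial-fraction packs at native rate (plus the equalized 100a pack). The
# 100b pack is skipped for systems already sampling at 128 Hz.

#' Benchmark configuration
#'
#' Defaults reproduce the benchmark's study conditions: 19 participants,
#' the three system presets, the full paradigm sizes (4x60 s resting
#' blocks, 6x30 s flicker blocks, 300 face trials, 400 active-oddball
#' trials, 562+112 passive tones). Tests and examples pass smaller sizes.
#'
#' @param n_participants Number of virtual participants.
#' @param profiles Named list of [system_profile()]s.
#' @param truth A [ground_truth()].
#' @param packs Pack names to analyze.
#' @param tasks Tasks to run.
#' @param master_seed Master seed; all per-participant/system/task seeds
#'   derive from it.
#' @param resting_block_s,resting_n_blocks Resting-state design.
#' @param ssvep_freqs,ssvep_blocks_per_freq,ssvep_block_s,ssvep_fix_s
#'   SSVEP design.
#' @param face_trials,active_trials Trial counts.
#' @param passive_std,passive_dev Passive-oddball tone counts.
#' @return A `bench_config` list.
#' @export
bench_config <- function(n_participants = 19,
                         profiles = system_presets(),
                         truth = ground_truth(),
                         packs = c("100a", "100b", "75", "50"),
                         tasks = TASKS,
                         master_seed = 1,
                         resting_block_s = 60, resting_n_blocks = 4,
                         ssvep_freqs = c(6, 10, 15),
                         ssvep_blocks_per_freq = 2, ssvep_block_s = 30,
                         ssvep_fix_s = 2,
                         face_trials = 300, active_trials = 400,
                         passive_std = 562, passive_dev = 112) {
  structure(as.list(environment()), class = "bench_config")
}

task_events <- function(cfg, task, seed) {
  switch(task,
    resting = gen_resting_events(cfg$resting_block_s, cfg$resting_n_blocks),
    ssvep = gen_ssvep_events(cfg$ssvep_freqs, cfg$ssvep_blocks_per_freq,
                             cfg$ssvep_block_s, cfg$ssvep_fix_s, seed = seed),
    face = gen_face_events(cfg$face_trials, seed = seed),
    active_oddball = gen_active_oddball_events(cfg$active_trials, seed = seed),
    # one fixed tone sequence shared by all participants
    passive_oddball = gen_passive_oddball_events(cfg$passive_std,
                                                 cfg$passive_dev,
                                                 seed = derive_seed(cfg$master_seed, 999)),
    stop_invalid("unknown task '%s'", task)
  )
}

erp_task_components <- function(task) {
  switch(task,
    face = c("P100", "N170"),
    active_oddball = c("N200", "P300"),
    passive_oddball = "MMN",
    character(0))
}

erp_task_electrodes <- function(task) {
  switch(task,
    face = c("P7", "P8"),
    active_oddball = c("Fz", "Cz", "Pz"),
    passive_oddball = c("Fz", "Cz", "Pz"),
    character(0))
}

measure_row <- function(participant, system, pack, task, condition,
                        electrode, measure, value) {
  data.frame(participant = participant, system = system, pack = pack,
             task = task, condition = condition, electrode = electrode,
             measure = measure, value = value, stringsAsFactors = FALSE)
}

# per-participant measures for the continuous tasks at a duration fraction;
# faulty occipital electrodes are excluded, and the measure is NA (the
# participant drops out listwise) when none remain
measure_continuous <- function(task, rec, blocks, fraction, cfg,
                               retained = rec$channel_names) {
  occ <- intersect(c("O1", "Oz", "O2"), retained)
  if (task == "resting") {
    val <- if (length(occ) == 0) NA_real_ else {
      # a band-focused wavelet grid: identical alpha-band power at a
      # fraction of the full 1-40 Hz grid's cost
      fr <- seq(8, 13, by = 0.5)
      eo <- condition_alpha_power(rec, blocks, "EO", electrodes = occ,
                                  freqs_hz = fr, fraction = fraction)
      ec <- condition_alpha_power(rec, blocks, "EC", electrodes = occ,
                                  freqs_hz = fr, fraction = fraction)
      berger_effect(ec, eo)
    }
    return(data.frame(condition = "EC-EO", electrode = "O1/Oz/O2",
                      measure = "alpha_diff", value = val))
  }
  rows <- lapply(cfg$ssvep_freqs, function(f0) {
    val <- if (length(occ) == 0) NA_real_ else {
      as.numeric(ssvep_condition_snr(rec, blocks, f0, electrodes = occ,
                                     fraction = fraction))
    }
    data.frame(condition = sprintf("%gHz", f0), electrode = "O1/Oz/O2",
               measure = "pooled_snr", value = val)
  })
  do.call(rbind, rows)
}

# per-participant ERP measures from a preprocessed epoch set; measures at
# faulty (removed) electrodes come back NA so the participant drops out of
# the per-electrode statistics. For the MMN the AUC window must come from
# the grand average, so the difference waveform is returned alongside.
measure_erp <- function(task, ep, system, retained = ep$channel_names) {
  waves <- list()
  rows <- list()
  peak_or_na <- function(w, el, comp, pol) {
    if (!(el %in% retained)) {
      return(list(amplitude_uv = NA_real_, latency_ms = NA_real_))
    }
    find_peak(w, el, component_window(comp, system), pol)
  }
  if (task == "face") {
    for (cond in c("face", "texture")) {
      w <- average_condition(ep, cond)
      waves[[cond]] <- w
      for (el in c("P7", "P8")) {
        p100 <- peak_or_na(w, el, "P100", "positive")
        n170 <- peak_or_na(w, el, "N170", "negative")
        p2p <- if (is.na(n170$amplitude_uv)) NA_real_ else {
          p100$amplitude_uv - n170$amplitude_uv
        }
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, electrode = el,
          measure = c("p2p_amplitude", "n170_latency"),
          value = c(p2p, n170$latency_ms))
      }
    }
  } else if (task == "active_oddball") {
    dev <- average_condition(ep, "deviant")
    std <- average_condition(ep, "standard",
                             exclude_post_deviant_standards = TRUE)
    dw <- difference_wave(dev, std)
    waves[["difference"]] <- dw
    for (el in c("Fz", "Cz", "Pz")) {
      n200 <- peak_or_na(dw, el, "N200", "negative")
      p300 <- peak_or_na(dw, el, "P300", "positive")
      rows[[length(rows) + 1]] <- data.frame(
        condition = "deviant-standard", electrode = el,
        measure = c("n200_amplitude", "n200_latency",
                    "p300_amplitude", "p300_latency"),
        value = c(n200$amplitude_uv, n200$latency_ms,
                  p300$amplitude_uv, p300$latency_ms))
    }
  } else if (task == "passive_oddball") {
    dev <- average_condition(ep, "deviant")
    std <- average_condition(ep, "standard", standards_pre_deviant_only = TRUE)
    dw <- difference_wave(dev, std)
    waves[["difference"]] <- dw
    for (el in c("Fz", "Cz", "Pz")) {
      pk <- peak_or_na(dw, el, "MMN", "negative")
      rows[[length(rows) + 1]] <- data.frame(
        condition = "deviant-standard", electrode = el,
        measure = c("mmn_amplitude", "mmn_latency"),
        value = c(pk$amplitude_uv, pk$latency_ms))
    }
  }
  list(rows = do.call(rbind, rows), waves = waves)
}

#' Run the full benchmark
#'
#' Simulates every participant under every system profile, preprocesses
#' per task and pack, extracts the spectral and ERP measures, and
#' aggregates signal quality, the per-measure table, effect sizes, and
#' statistics.
#'
#' @param cfg A [bench_config()].
#' @param verbose Print per-stage progress lines.
#' @return A `bench_report`: list with `measures` (long data frame),
#'   `quality` (per participant/system/task), `effect_sizes`
#'   (task x pack x system Cohen's d), `mmn_windows` (per system/pack AUC
#'   windows), and `config`.
#' @export
run_benchmark <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "bench_config"))
  systems <- names(cfg$profiles)
  measures <- list()
  quality <- list()
  mmn_store <- list()  # difference waves for grand-average MMN windows

  for (pi in seq_len(cfg$n_participants)) {
    for (si in seq_along(systems)) {
      sys <- systems[si]
      prof <- cfg$profiles[[sys]]
      for (ti in seq_along(cfg$tasks)) {
        task <- cfg$tasks[ti]
        seed_ev <- derive_seed(cfg$master_seed, pi, si, ti, 1)
        seed_rec <- derive_seed(cfg$master_seed, pi, si, ti, 2)
        events <- task_events_cached(cfg, task, seed_ev)
        rec <- synthesize_recording(events, prof, cfg$truth, seed = seed_rec)
        if (verbose) {
          message(sprintf("participant %d system %s task %s", pi, sys, task))
        }
        if (task %in% c("resting", "ssvep")) {
          prep <- preprocess_task(rec, events, pack = "100a")
          for (pk in intersect(cfg$packs, c("100a", "75", "50"))) {
            frac <- pack_spec(pk)$fraction
            rows <- measure_continuous(task, prep$recording, events$blocks,
                                       frac, cfg, retained = prep$retained)
            measures[[length(measures) + 1]] <-
              cbind(participant = pi, system = sys, pack = pk, task = task,
                    rows)
          }
          quality[[length(quality) + 1]] <- data.frame(
            participant = pi, system = sys, task = task,
            lost_triggers = attr(rec, "lost_triggers"),
            faulty_electrodes = length(prep$removed),
            rejection_pct = NA_real_)
        } else {
          # reconcile recorded markers with the presentation log
          log <- data.frame(trial_index = seq_len(n_events(events)),
                            label = events$events$label,
                            onset_ms = events$events$onset_s * 1000,
                            code = events$events$code)
          matched <- match_events(rec, log)
          matched$task <- task  # label vocabularies overlap across oddballs
          packs <- intersect(cfg$packs, c("100a", "100b", "75", "50"))
          if (prof$rate_hz <= 128) packs <- setdiff(packs, "100b")
          rej <- NA_real_; n_faulty <- NA_integer_
          for (pk in packs) {
            prep <- preprocess_task(rec, matched, pack = pk)
            out <- measure_erp(task, prep$epochs, sys,
                               retained = prep$retained)
            measures[[length(measures) + 1]] <-
              cbind(participant = pi, system = sys, pack = pk, task = task,
                    out$rows)
            if (task == "passive_oddball") {
              mmn_store[[sprintf("%s.%s.%d", sys, pk, pi)]] <-
                list(system = sys, pack = pk, participant = pi,
                     wave = out$waves$difference,
                     retained = prep$retained)
            }
            if (pk %in% c("100a", "100b")) {
              rej <- prep$rejection_fraction * 100
              n_faulty <- length(prep$removed)
            }
          }
          quality[[length(quality) + 1]] <- data.frame(
            participant = pi, system = sys, task = task,
            lost_triggers = attr(matched, "lost_triggers"),
            faulty_electrodes = n_faulty, rejection_pct = rej)
        }
      }
    }
  }
  measures <- do.call(rbind, measures)
  quality <- do.call(rbind, quality)

  # MMN AUC: 50-ms window centered on the grand-average Fz/Cz peak,
  # per system and pack, then per-participant trapezoidal areas
  mmn_rows <- list()
  mmn_windows <- list()
  if (length(mmn_store) > 0) {
    keys <- unique(vapply(mmn_store, function(x)
      paste(x$system, x$pack, sep = "."), ""))
    for (key in keys) {
      items <- Filter(function(x) paste(x$system, x$pack, sep = ".") == key,
                      mmn_store)
      sys <- items[[1]]$system; pk <- items[[1]]$pack
      # participants with a faulty fronto-central electrode are excluded
      # from the grand average and receive no AUC (listwise exclusion)
      items <- Filter(function(x) all(c("Fz", "Cz") %in% x$retained), items)
      if (length(items) == 0) next
      ga <- grand_average(lapply(items, `[[`, "wave"))
      win <- component_window("MMN", sys)
      lat_fz <- find_peak(ga, "Fz", win, "negative")$latency_ms
      lat_cz <- find_peak(ga, "Cz", win, "negative")$latency_ms
      wnd <- mmn_window(lat_fz, lat_cz)
      mmn_windows[[key]] <- data.frame(system = sys, pack = pk,
                                       lat_fz = lat_fz, lat_cz = lat_cz,
                                       center = wnd["center"],
                                       start = wnd["start"], end = wnd["end"])
      for (it in items) {
        for (el in c("Fz", "Cz", "Pz")) {
          mmn_rows[[length(mmn_rows) + 1]] <- measure_row(
            it$participant, sys, pk, "passive_oddball", "deviant-standard",
            el, "mmn_auc", erp_auc(it$wave, el, c(wnd["start"], wnd["end"])))
        }
      }
    }
    measures <- rbind(measures, do.call(rbind, mmn_rows))
  }

  structure(list(measures = measures, quality = quality,
                 effect_sizes = effect_size_grid(measures),
                 mmn_windows = if (length(mmn_windows) > 0) {
                   do.call(rbind, mmn_windows)
                 } else NULL,
                 config = cfg),
            class = "bench_report")
}

# event sequences are deterministic per (task, seed); cache within a run
task_events_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(cfg, task, seed) {
    key <- sprintf("%s.%d.%d", task, seed, cfg$master_seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (length(ls(cache)) > 64) rm(list = ls(cache), envir = cache)
    cache[[key]] <- task_events(cfg, task, seed)
    cache[[key]]
  }
})

# headline measure per task for the effect-size grid
grid_measure <- function(task) {
  switch(task,
    resting = "alpha_diff", ssvep = "pooled_snr", face = "p2p_amplitude",
    active_oddball = c("n200_amplitude", "p300_amplitude"),
    passive_oddball = "mmn_auc")
}

#' Effect sizes (Cohen's d vs zero) per task, pack and system
#'
#' For each cell: one-sample t of the per-participant headline measure
#' against zero, d averaged over electrodes/conditions the way the
#' benchmark reports them (face condition at P7/P8 for the N170; the
#' three midline electrodes for N200/P300/MMN; the three flicker
#' conditions for SSVEP). Negative components enter via |d|.
#'
#' @param measures Long measure table from [run_benchmark()].
#' @return Data frame `task`, `measure`, `pack`, `system`, `d`, `n`.
#' @export
effect_size_grid <- function(measures) {
  out <- list()
  for (task in unique(measures$task)) {
    for (ms in grid_measure(task)) {
      sub <- measures[measures$task == task & measures$measure == ms, ]
      if (task == "face") sub <- sub[sub$condition == "face", ]
      if (nrow(sub) == 0) next
      for (pk in unique(sub$pack)) {
        for (sys in unique(sub$system)) {
          cell <- sub[sub$pack == pk & sub$system == sys, ]
          ds <- vapply(unique(cell$electrode), function(el) {
            if (task == "ssvep") {
              # d per condition, then averaged
              mean(vapply(unique(cell$condition), function(cd) {
                vv <- cell$value[cell$electrode == el & cell$condition == cd]
                vv <- vv[!is.na(vv)]
                if (length(vv) < 2) return(NA_real_)
                abs(mean(vv)) / stats::sd(vv)
              }, 0), na.rm = TRUE)
            } else {
              v <- cell$value[cell$electrode == el]
              v <- v[!is.na(v)]
              if (length(v) < 2) return(NA_real_)
              abs(mean(v)) / stats::sd(v)
            }
          }, 0)
          out[[length(out) + 1]] <- data.frame(
            task = task, measure = ms, pack = pk, system = sys,
            d = mean(ds, na.rm = TRUE),
            n = length(unique(cell$participant)))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Signal-quality summary (lost triggers, faulty electrodes, rejection %)
#'
#' Mean, standard error and range per system, pooled over participants;
#' rejection percentage additionally split per ERP task.
#'
#' @param quality Quality table from [run_benchmark()].
#' @return Data frame with one row per system x metric (x task for
#'   rejection).
#' @export
quality_summary <- function(quality) {
  summarize <- function(v) {
    v <- v[!is.na(v)]
    data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
               min = min(v), max = max(v))
  }
  out <- list()
  for (sys in unique(quality$system)) {
    qs <- quality[quality$system == sys, ]
    per_part <- tapply(qs$lost_triggers, qs$participant, sum, na.rm = TRUE)
    out[[length(out) + 1]] <- cbind(system = sys, metric = "lost_triggers",
                                    task = "all", summarize(as.numeric(per_part)))
    per_part <- tapply(qs$faulty_electrodes, qs$participant, max, na.rm = TRUE)
    per_part <- per_part[is.finite(per_part)]
    if (length(per_part) > 0) {
      out[[length(out) + 1]] <- cbind(system = sys,
                                      metric = "faulty_electrodes",
                                      task = "all",
                                      summarize(as.numeric(per_part)))
    }
    for (task in unique(qs$task[!is.na(qs$rejection_pct)])) {
      out[[length(out) + 1]] <- cbind(
        system = sys, metric = "rejection_pct", task = task,
        summarize(qs$rejection_pct[qs$task == task]))
    }
  }
  do.call(rbind, out)
}

#' Effect-size overview grid with trial-count headers
#'
#' Arranges the effect sizes as packs x systems x tasks, with each pack's
#' header describing the dataset size the generators produce (e.g. "505
#' trials (84 deviants)" for the passive oddball at the 75% pack).
#'
#' @param report A `bench_report`.
#' @return List with `headers` (pack x task description strings) and `grid`
#'   (the effect-size data frame augmented with the header text).
#' @export
make_table13 <- function(report) {
  cfg <- report$config
  frac <- c(`100a` = 1, `100b` = 1, `75` = 0.75, `50` = 0.5)
  packs <- intersect(names(frac), unique(report$effect_sizes$pack))
  hdr <- list()
  for (pk in packs) {
    f <- frac[[pk]]
    n_face <- floor(f * cfg$face_trials)
    n_act <- floor(f * cfg$active_trials)
    n_pas <- floor(f * (cfg$passive_std + cfg$passive_dev))
    hdr[[pk]] <- c(
      resting = sprintf("%g s", cfg$resting_block_s * f),
      ssvep = sprintf("%g s", cfg$ssvep_block_s * f),
      face = sprintf("%d trials (%d faces)", n_face,
                     floor(f * cfg$face_trials / 2)),
      active_oddball = sprintf("%d trials (%d deviants)", n_act,
                               floor(f * cfg$active_trials * 0.2)),
      passive_oddball = sprintf("%d trials (%d deviants)", n_pas,
                                floor(f * cfg$passive_dev)))
  }
  grid <- report$effect_sizes
  grid$header <- vapply(seq_len(nrow(grid)), function(i) {
    hdr[[grid$pack[i]]][[grid$task[i]]]
  }, "")
  list(headers = hdr, grid = grid)
}
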