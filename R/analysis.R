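# Response measures: rates, latencies, electrical thresholds, F-I curves,
# ISI statistics, and degeneration sweeps.

# Restrict a spike table to a window and a cell selection.
spike_subset <- function(spikes, window = NULL, ids = NULL) {
  if (!is.null(window))
    spikes <- spikes[spikes$t_ms >= window[1] & spikes$t_ms < window[2], ,
                     drop = FALSE]
  if (!is.null(ids))
    spikes <- spikes[spikes$id %in% ids, , drop = FALSE]
  spikes
}

#' Spontaneous / mean firing rates
#'
#' Counts spikes per RGC over a time window and summarizes per cell class.
#' A pure function of the spike record (re-runnable on saved spike CSVs).
#'
#' @param sim A `ret_sim`, or a spike data.frame (`id, cell_type, t_ms`)
#'   together with `cells`.
#' @param window `c(start, end)` in ms; default discards the configured
#'   settling transient.
#' @param cells Cell table (`id, cell_type`); taken from `sim` if omitted.
#' @return List: `per_cell` (data.frame `id, cell_type, rate_hz`),
#'   `by_class` (mean, sd, n per RGC class), `mean_hz` (population mean
#'   over all RGCs).
#' @export
spontaneous_rate <- function(sim, window = NULL, cells = NULL) {
  if (inherits(sim, "ret_sim")) {
    if (is.null(window))
      window <- c(sim$config$transient_ms, sim$duration)
    spikes <- sim$spikes
    cells <- sim$cells
  } else spikes <- sim
  if (is.null(window) || diff(window) <= 0)
    stop("rate window must have positive length")
  dur_s <- diff(window) / 1000
  rgc <- cells[cells$cell_type %in% rgc_types(), , drop = FALSE]
  sp <- spike_subset(spikes, window, rgc$id)
  counts <- table(factor(sp$id, levels = rgc$id))
  per_cell <- data.frame(id = rgc$id, cell_type = rgc$cell_type,
                         rate_hz = as.numeric(counts) / dur_s,
                         stringsAsFactors = FALSE)
  by_class <- do.call(rbind, lapply(split(per_cell, per_cell$cell_type),
    function(d) data.frame(cell_type = d$cell_type[1],
                           mean = mean(d$rate_hz), sd = stats::sd(d$rate_hz),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(by_class) <- NULL
  list(per_cell = per_cell, by_class = by_class,
       mean_hz = mean(per_cell$rate_hz))
}

#' Median first-spike latency after a stimulus onset
#'
#' @param sim A `ret_sim` (or spike data.frame).
#' @param onset_ms Stimulus onset time (ms).
#' @param ids Cell ids to analyze (e.g. the RGCs of one class under the
#'   stimulus).
#' @param window_ms Analysis window after onset (ms).
#' @return List: `per_cell` (id, latency_ms; non-spiking cells dropped),
#'   `median_ms` (NA if no selected cell spiked), `n_responding`.
#' @export
first_spike_latency <- function(sim, onset_ms, ids, window_ms = 150) {
  spikes <- if (inherits(sim, "ret_sim")) sim$spikes else sim
  sp <- spike_subset(spikes, c(onset_ms, onset_ms + window_ms), ids)
  if (!nrow(sp))
    return(list(per_cell = data.frame(id = integer(0),
                                      latency_ms = numeric(0)),
                median_ms = NA_real_, n_responding = 0L))
  lat <- vapply(split(sp$t_ms, sp$id), min, 0) - onset_ms
  per_cell <- data.frame(id = as.integer(names(lat)), latency_ms = unname(lat))
  list(per_cell = per_cell, median_ms = stats::median(lat),
       n_responding = nrow(per_cell))
}

# Response criterion for one threshold trial: at least one spike within
# `resp_window_ms` after any pulse onset.
trial_response <- function(spikes, train, resp_window_ms = 10) {
  period <- 1000 / train$frequency_hz
  onsets <- train$onset_ms + seq(0, by = period,
                                 length.out = train$frequency_hz *
                                   train$duration_s)
  function(ids) {
    vapply(ids, function(i) {
      tt <- spikes$t_ms[spikes$id == i]
      if (!length(tt)) return(FALSE)
      any(vapply(onsets, function(o) any(tt > o & tt <= o + resp_window_ms),
                 TRUE))
    }, TRUE)
  }
}

#' Electrical activation thresholds
#'
#' For every RGC under the electrode (lateral distance within the disk
#' radius), finds the smallest pulse-train amplitude that elicits a
#' stimulus-locked spike (within `resp_window_ms` of a pulse onset) on at
#' least `criterion` of `n_trials` repeated trials; trials differ only in
#' their initial-voltage seeds.  Cells already meeting the criterion with
#' no stimulus have threshold 0 (spontaneously active cells); cells never
#' meeting it at the largest amplitude are marked non-responsive and are
#' excluded from the population mean (their count is reported).
#'
#' @param network A `ret_network`.
#' @param electrode A [disk_electrode()].
#' @param amplitudes Strictly increasing amplitude grid (uA).
#' @param n_trials Trials per amplitude.
#' @param criterion Response-probability criterion (default 0.5).
#' @param settle_ms Settling time before the train (ms).
#' @param light Background light stimulus (default uniform 0.5).
#' @param train_args List of [biphasic_train()] arguments other than
#'   amplitude.
#' @param resp_window_ms Stimulus-locked response window per pulse (ms).
#' @param refine_iter Bisection refinement iterations between bracketing
#'   grid points (0 = grid resolution).
#' @param i_const Optional constant holding currents (data.frame
#'   `id, pa`) applied throughout, e.g. to probe isolated cells.
#' @param config Base [sim_config()]; seeds are derived per trial.
#' @return A `threshold_result`: list with `per_cell` (id, cell_type,
#'   threshold_ua, responsive), `by_class` (mean, sd, n, n_nonresponsive),
#'   and the protocol settings.
#' @export
threshold_search <- function(network, electrode, amplitudes = c(0, 2, 4, 8,
                                                                16, 32, 64,
                                                                128),
                             n_trials = 20, criterion = 0.5,
                             settle_ms = 300, light = light_full_field(0.5),
                             train_args = list(), resp_window_ms = 10,
                             refine_iter = 0, i_const = NULL,
                             config = sim_config()) {
  stopifnot(all(diff(amplitudes) > 0))
  cells <- network$layout$cells
  lat_r <- sqrt((cells$x - electrode$center[1])^2 +
                  (cells$y - electrode$center[2])^2)
  sel <- cells[cells$cell_type %in% rgc_types() &
                 lat_r <= electrode$diameter / 2, , drop = FALSE]
  if (!nrow(sel)) stop("no RGC under the electrode")
  prob_at <- function(amp) {
    hits <- numeric(nrow(sel))
    for (trial in seq_len(n_trials)) {
      tr <- do.call(biphasic_train,
                    c(list(amplitude_ua = amp, onset_ms = settle_ms),
                      train_args))
      cfg <- config
      cfg$duration <- settle_ms + tr$duration_s * 1000 + resp_window_ms
      cfg$seed <- config$seed + 1000L * trial
      sim <- run_simulation(network, light = light,
                            electrical = electrical_stimulus(electrode, tr),
                            config = cfg, i_const = i_const)
      hits <- hits + trial_response(sim$spikes, tr,
                                    resp_window_ms)(sel$id)
    }
    hits / n_trials
  }
  thr <- rep(NA_real_, nrow(sel))
  lower <- rep(0, nrow(sel))        # largest amplitude known sub-threshold
  for (amp in amplitudes) {
    open <- is.na(thr)
    if (!any(open)) break
    p <- prob_at(amp)
    newly <- open & p >= criterion
    thr[newly] <- amp
    lower[open & p < criterion] <- amp
  }
  if (refine_iter > 0) {
    for (it in seq_len(refine_iter)) {
      mids <- unique(signif((thr + lower) / 2, 3))
      mids <- mids[!is.na(mids) & mids > 0]
      for (m in sort(mids)) {
        active <- which(!is.na(thr) & lower < m & thr > m)
        if (!length(active)) next
        p <- prob_at(m)
        hit <- p[active] >= criterion
        thr[active[hit]] <- m
        lower[active[!hit]] <- pmax(lower[active[!hit]], m)
      }
    }
  }
  per_cell <- data.frame(id = sel$id, cell_type = sel$cell_type,
                         threshold_ua = thr, responsive = !is.na(thr),
                         stringsAsFactors = FALSE)
  by_class <- do.call(rbind, lapply(split(per_cell, per_cell$cell_type),
    function(d) {
      ok <- d$responsive
      data.frame(cell_type = d$cell_type[1],
                 mean = if (any(ok)) mean(d$threshold_ua[ok]) else NA_real_,
                 sd = if (sum(ok) > 1) stats::sd(d$threshold_ua[ok]) else NA_real_,
                 n = sum(ok), n_nonresponsive = sum(!ok),
                 stringsAsFactors = FALSE)
    }))
  rownames(by_class) <- NULL
  structure(list(per_cell = per_cell, by_class = by_class,
                 amplitudes = amplitudes, n_trials = n_trials,
                 criterion = criterion, electrode = electrode),
            class = "threshold_result")
}

#' Thresholds relative to a healthy reference
#'
#' @param stage,healthy `threshold_result` objects from the same protocol.
#' @return data.frame per class: stage mean, healthy mean, and
#'   `relative_pct` = 100 * stage / healthy.  Invariant to the uA-to-V0
#'   conversion constant.
#' @export
relative_thresholds <- function(stage, healthy) {
  m <- merge(stage$by_class[, c("cell_type", "mean")],
             healthy$by_class[, c("cell_type", "mean")],
             by = "cell_type", suffixes = c("_stage", "_healthy"))
  m$relative_pct <- 100 * m$mean_stage / m$mean_healthy
  m
}

#' Frequency-input (F-I) curves
#'
#' Mean RGC firing rate versus input amplitude for three stimulation
#' modes: somatic current injection (pA), or epiretinal / subretinal
#' pulse-train stimulation (uA).
#'
#' @param network A `ret_network`.
#' @param mode `"injected"`, `"epiretinal"` or `"subretinal"`.
#' @param amplitudes Amplitude grid (pA for injected, uA otherwise).
#' @param duration_ms Measurement window (ms) after the transient.
#' @param light Background light (default uniform 0.5).
#' @param config Base [sim_config()].
#' @return data.frame: amplitude, cell_type, mean_hz, sd_hz, n.
#' @export
fi_curve <- function(network, mode = c("injected", "epiretinal",
                                       "subretinal"),
                     amplitudes = c(0, 10, 20, 40, 80),
                     duration_ms = 1000, light = light_full_field(0.5),
                     config = sim_config()) {
  mode <- match.arg(mode)
  cells <- network$layout$cells
  rgc_ids <- cells$id[cells$cell_type %in% rgc_types()]
  t0 <- config$transient_ms
  out <- lapply(amplitudes, function(a) {
    cfg <- config
    cfg$duration <- t0 + duration_ms
    if (mode == "injected") {
      sim <- run_simulation(network, light = light, config = cfg,
                            i_const = data.frame(id = rgc_ids, pa = a))
    } else {
      el <- disk_electrode(mode)
      tr <- biphasic_train(amplitude_ua = a, onset_ms = t0,
                           duration_s = duration_ms / 1000)
      sim <- run_simulation(network, light = light,
                            electrical = electrical_stimulus(el, tr),
                            config = cfg)
    }
    r <- spontaneous_rate(sim, window = c(t0, t0 + duration_ms))
    cbind(amplitude = a, r$by_class)
  })
  res <- do.call(rbind, out)
  names(res)[names(res) == "mean"] <- "mean_hz"
  names(res)[names(res) == "sd"] <- "sd_hz"
  res
}

#' Inter-spike-interval statistics
#'
#' @param spike_times Numeric vector of spike times (ms) of one cell or a
#'   pooled population train.
#' @return List: `isi_ms`, `cv` (SD/mean of ISIs), `rate_hz` (1/mean ISI),
#'   `exp_ks_p` (Kolmogorov-Smirnov p-value against the fitted
#'   exponential).  ISI count < 2 returns NA statistics.
#' @export
isi_statistics <- function(spike_times) {
  st <- sort(spike_times)
  if (length(st) < 2)
    return(list(isi_ms = numeric(0), cv = NA_real_, rate_hz = NA_real_,
                exp_ks_p = NA_real_))
  isi <- diff(st)
  cv <- stats::sd(isi) / mean(isi)
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 1 / mean(isi)))
  list(isi_ms = isi, cv = cv, rate_hz = 1000 / mean(isi),
       exp_ks_p = ks$p.value)
}

#' Power-spectrum oscillation check for a population spike train
#'
#' Bins the pooled spike train and computes its periodogram; reports the
#' largest spectral peak relative to the median power, a simple indicator
#' of network oscillations.
#'
#' @param spike_times Pooled spike times (ms).
#' @param duration_ms Record duration (ms).
#' @param bin_ms Histogram bin (ms).
#' @return List: `freq_hz`, `power`, `peak_ratio` (max power / median
#'   power over 5-100 Hz).
#' @export
spike_spectrum <- function(spike_times, duration_ms, bin_ms = 5) {
  br <- seq(0, duration_ms, by = bin_ms)
  counts <- graphics::hist(spike_times, breaks = br, plot = FALSE)$counts
  spec <- stats::spec.pgram(counts - mean(counts), plot = FALSE, taper = 0)
  freq <- spec$freq * 1000 / bin_ms
  band <- freq >= 5 & freq <= 100
  list(freq_hz = freq, power = spec$spec,
       peak_ratio = max(spec$spec[band]) / stats::median(spec$spec[band]))
}

#' Sweep a measurement over the disease course
#'
#' Builds the degenerated network at each stage of a normalized
#' disease-time grid and applies a measurement function, returning a tidy
#' per-stage table.  Deterministic under fixed seeds; death sets are
#' nested across stages.
#'
#' @param network Healthy `ret_network`.
#' @param u Vector of disease times in `[0, 2]` (see
#'   [progression_schedule()]).
#' @param measure `function(network, stage_u)` returning a data.frame.
#' @param seed Seed for degeneration draws.
#' @return Row-bound data.frame with a `u` column.
#' @export
degeneration_sweep <- function(network, u, measure,
                               seed = network$layout$seed) {
  out <- lapply(u, function(uu) {
    st <- progression_schedule(uu)
    d <- degenerate(network, st, seed = seed)
    cbind(u = uu, measure(d, uu))
  })
  do.call(rbind, out)
}

#' Spontaneous-rate measurement for [degeneration_sweep()]
#'
#' @param duration_ms Simulated time (settling transient is prepended).
#' @param config Base [sim_config()].
#' @return A measure closure returning per-class mean/sd rates.
#' @export
measure_spontaneous <- function(duration_ms = 2500, config = sim_config()) {
  function(network, u) {
    cfg <- config
    cfg$duration <- cfg$transient_ms + duration_ms
    sim <- run_simulation(network, light = light_full_field(0.5),
                          config = cfg)
    spontaneous_rate(sim)$by_class
  }
}
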