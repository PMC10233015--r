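# Network assembly and the simulation front-end.

#' Assemble a simulable network
#'
#' Bundles a layout, its connectome and the membrane/synapse parameter sets
#' into a `ret_network`.  Degeneration transforms operate on this object.
#'
#' @param layout A `retina_layout`; default the full 300 x 300 um patch.
#' @param connectome Optional pre-built `ret_connectome` (built from the
#'   layout if omitted).
#' @param membrane Membrane parameters, default [default_membrane_params()].
#' @param synapses Projection table, default [default_synapse_specs()].
#' @return A `ret_network`.
#' @export
build_network <- function(layout = build_layout(), connectome = NULL,
                          membrane = default_membrane_params(),
                          synapses = default_synapse_specs()) {
  if (is.null(connectome)) connectome <- build_connectome(layout, synapses)
  structure(list(layout = layout, connectome = connectome,
                 membrane = membrane, synapses = synapses,
                 glight_scale = 1, deg = list(s = 0, t = 0),
                 n_healthy = nrow(layout$cells),
                 healthy_ids = split(layout$cells$id,
                                     layout$cells$cell_type)),
            class = "ret_network")
}

#' @export
print.ret_network <- function(x, ...) {
  cat(sprintf("<ret_network> %d cells (s = %.2f, t = %.2f), G_light scale %.2f\n",
              nrow(x$layout$cells), x$deg$s, x$deg$t, x$glight_scale))
  invisible(x)
}

#' Simulation settings
#'
#' @param dt Integration step (ms); default 0.025 (stable and convergent
#'   for the RGC spike dynamics).
#' @param duration Simulated time (ms).
#' @param seed Seed for the random initial membrane voltages.
#' @param record Cell ids to record voltage traces for, `"all"`, or `NULL`.
#' @param trace_dt Trace sampling interval (ms).
#' @param syn_update_ms Interval at which graded synaptic pooling and the
#'   delay buffers are refreshed (ms); presynaptic membranes have time
#'   constants of 8 ms and above, so the default 0.25 ms is lossless in
#'   practice (see the convergence tests).
#' @param init_sd SD (mV) of the normally distributed initial voltages
#'   about each type's resting potential.
#' @param transient_ms Settling time discarded by rate analyses (ms).
#' @param n_pairs Antipodal sample pairs for electrode-soma coupling.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.025, duration = 1000, seed = 1L,
                       record = NULL, trace_dt = 1,
                       syn_update_ms = 0.25, init_sd = 2,
                       transient_ms = 200, n_pairs = 500) {
  stopifnot(dt > 0, duration >= 0)
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 record = record, trace_dt = trace_dt,
                 syn_update_ms = syn_update_ms, init_sd = init_sd,
                 transient_ms = transient_ms, n_pairs = n_pairs),
            class = "sim_config")
}

#' Electrical stimulus: electrode plus pulse train
#'
#' @param electrode A [disk_electrode()].
#' @param train A [biphasic_train()].
#' @param v0_per_ua Conversion from pulse amplitude (uA) to disk potential
#'   (mV); default the package calibration constant.  Relative thresholds
#'   do not depend on it.
#' @return An `electrical_stimulus` object.
#' @export
electrical_stimulus <- function(electrode, train, v0_per_ua = V0_PER_UA) {
  structure(list(electrode = electrode, train = train,
                 v0_per_ua = v0_per_ua), class = "electrical_stimulus")
}

# Assemble the per-cell arrays the compiled engine needs.
engine_inputs <- function(network, config) {
  cells <- network$layout$cells
  n <- nrow(cells)
  mem <- network$membrane
  ty <- cells$cell_type
  type_idx <- match(ty, cell_types()) - 1L
  model <- ifelse(ty == "PR", 1L, ifelse(ty %in% rgc_types(), 2L, 0L))
  getp <- function(field, default = 0)
    vapply(ty, function(tt) {
      val <- mem[[tt]][[field]]
      if (is.null(val)) default else val
    }, 0, USE.NAMES = FALSE)
  Cm <- getp("C_m")
  Erest <- getp("E_rest")
  Gm <- numeric(n)
  is_rgc <- model == 2L
  Gm[!is_rgc] <- getp("G_m")[!is_rgc]
  for (rt in rgc_types()) {
    sel <- ty == rt
    Gm[sel] <- density_to_nS(mem[[rt]]$G_m, mem[[rt]]$soma_diameter)
  }
  Glight <- ifelse(ty == "PR", mem$PR$G_light * network$glight_scale, 0)
  rgc_class <- ifelse(ty == "RGC_ON", 0L, ifelse(ty == "RGC_OFF", 1L, -1L))
  gnames <- c("G_Na", "G_Ca", "G_K", "G_KA", "G_KCa", "G_h", "G_CaT")
  rgc_g <- t(vapply(rgc_types(), function(rt)
    density_to_nS(unlist(mem[[rt]][gnames]), mem[[rt]]$soma_diameter),
    numeric(7)))
  rgc_e <- t(vapply(rgc_types(), function(rt)
    unlist(mem[[rt]][c("E_Na", "E_K", "E_h")]), numeric(3)))
  # per-type local index of every cell (cells are id-ordered)
  local_of <- integer(max(cells$id))
  for (tt in unique(ty)) {
    ids <- cells$id[ty == tt]
    local_of[ids] <- seq_along(ids) - 1L
  }
  id_row <- integer(max(cells$id))
  id_row[cells$id] <- seq_len(n)
  projections <- lapply(network$connectome$sets, function(s) {
    list(pre_type = match(s$spec$pre, cell_types()) - 1L,
         tau = s$spec$tau, E_syn = s$spec$E_syn,
         G_min = s$spec$G_min, G_max = s$spec$G_max,
         V50 = s$spec$V50, beta = s$spec$beta, kind = s$spec$kind,
         post = id_row[s$post_id] - 1L,
         ptr = as.integer(s$ptr),
         pre_local = local_of[s$pre_id],
         w = s$w)
  })
  rv <- seq(-120, 60, by = 0.05)
  list(type_idx = type_idx, model = model, Cm = Cm, Gm = Gm,
       Erest = Erest, Glight = Glight, rgc_class = rgc_class,
       rgc_g = rgc_g, rgc_e = rgc_e, ca = ca_constants(26),
       rate_table = rgc_rate_table(rv), rate_v = rv, E_light = E_LIGHT,
       projections = unname(projections), cells = cells)
}

#' Run a network simulation
#'
#' Advances the whole network under the given light and/or electrical
#' stimulus, recording RGC spike times (upward crossings of -10 mV with a
#' 1 ms lockout) and optional voltage traces.  Deterministic given
#' `(network, stimuli, config)`.
#'
#' @param network A `ret_network`.
#' @param light A `light_stimulus`, or `NULL` (phototransduction
#'   conductance shut, as under saturating light).
#' @param electrical An [electrical_stimulus()], or `NULL`.
#' @param config A [sim_config()].
#' @param i_const Optional data.frame `(id, pa)` of constant injected
#'   currents per cell.
#' @return A `ret_sim`: list with `spikes` (data.frame `id, cell_type,
#'   t_ms`), `traces` (matrix cells x samples, or `NULL`), `trace_t`,
#'   `cells`, `config`.
#' @export
run_simulation <- function(network, light = NULL, electrical = NULL,
                           config = sim_config(), i_const = NULL) {
  inp <- engine_inputs(network, config)
  cells <- inp$cells
  n <- nrow(cells)
  dur <- config$duration
  # light rasterized onto the cones as piecewise-constant segments
  pr_sel <- which(inp$model == 1L)
  if (!is.null(light)) {
    br <- light_breaks(light, dur)
    mids <- (br[-1] + br[-length(br)]) / 2
    L <- vapply(mids, function(tm)
      light_at(light, cells$x[pr_sel], cells$y[pr_sel], tm),
      numeric(length(pr_sel)))
    L <- matrix(L, nrow = length(pr_sel))
  } else {
    br <- c(0, dur)
    L <- matrix(1, nrow = length(pr_sel), ncol = 1)  # conductance shut
  }
  light_in <- list(pr_cells = pr_sel - 1L, L = L, breaks = br)
  # electrode coupling gains and waveform
  ext_gain <- numeric(n)
  elec_in <- list(breaks = c(0, dur), v0 = numeric(0))
  if (!is.null(electrical)) {
    G_ext <- vapply(cells$cell_type, function(tt)
      network$layout$specs[[tt]]$G_ext, 0, USE.NAMES = FALSE)
    soma_d <- vapply(cells$cell_type, function(tt)
      network$layout$specs[[tt]]$soma_diameter, 0, USE.NAMES = FALSE)
    ext_gain <- soma_coupling_gains(
      electrical$electrode, cbind(cells$x, cells$y, cells$z),
      soma_d, G_ext, n_pairs = config$n_pairs, seed = config$seed)
    seg <- train_segments(electrical$train, dur)
    # the sphere-averaged coupling magnitude is signed by the instantaneous
    # disk polarity: cathodic phases (V0 < 0) hyperpolarize, anodic phases
    # depolarize.  A cathodic-first biphasic pulse therefore excites
    # through its anodic phase (on the heels of the cathodic prime), which
    # requires cells near threshold -- the network's pacemaking background
    # provides exactly that
    elec_in <- list(breaks = seg$breaks,
                    v0 = seg$value * electrical$train$amplitude_ua *
                      electrical$v0_per_ua)
  }
  ic <- numeric(n)
  if (!is.null(i_const)) {
    row <- match(i_const$id, cells$id)
    stopifnot(!anyNA(row))
    ic[row] <- i_const$pa
  }
  v_init <- with_seed(config$seed,
                      stats::rnorm(n, inp$Erest, config$init_sd))
  rec <- config$record
  trace_cells <- if (is.null(rec)) integer(0)
                 else if (identical(rec, "all")) seq_len(n) - 1L
                 else match(rec, cells$id) - 1L
  cfg <- list(dt = config$dt, n_steps = as.integer(round(dur / config$dt)),
              syn_stride = max(1L, as.integer(round(config$syn_update_ms /
                                                      config$dt))),
              spike_v = -10, lockout_ms = 1,
              trace_cells = as.integer(trace_cells),
              trace_stride = max(1L, as.integer(round(config$trace_dt /
                                                        config$dt))))
  net_in <- c(inp[c("type_idx", "model", "Cm", "Gm", "Erest", "Glight",
                    "rgc_class", "rgc_g", "rgc_e", "ca", "rate_table",
                    "rate_v", "E_light", "projections")],
              list(ext_gain = ext_gain, i_const = ic, v_init = v_init))
  out <- .run_network_cpp(net_in, light_in, elec_in, cfg)
  spikes <- data.frame(id = cells$id[out$spike_cell],
                       cell_type = cells$cell_type[out$spike_cell],
                       t_ms = out$spike_t, stringsAsFactors = FALSE)
  traces <- NULL
  if (length(trace_cells)) {
    traces <- out$traces
    rownames(traces) <- cells$id[trace_cells + 1L]
  }
  structure(list(spikes = spikes, traces = traces, trace_t = out$trace_t,
                 cells = cells, config = config,
                 duration = dur), class = "ret_sim")
}

#' @export
print.ret_sim <- function(x, ...) {
  cat(sprintf("<ret_sim> %.0f ms, %d cells, %d spikes\n",
              x$duration, nrow(x$cells), nrow(x$spikes)))
  invisible(x)
}

#' Per-cell voltages and spike flags at one time point
#'
#' Extracts the network state nearest to time `t` from a simulation run
#' with voltage recording, for layer-map style visualization.
#'
#' @param sim A `ret_sim` run with `record = "all"` (or covering the cells
#'   of interest).
#' @param t Time (ms) within the simulation.
#' @param spike_window Width (ms) of the window before `t` in which a
#'   spike flags the cell.
#' @return data.frame `id, cell_type, x, y, z, v_m, spiked`.
#' @export
snapshot <- function(sim, t, spike_window = 5) {
  if (is.null(sim$traces)) stop("simulation was run without voltage recording")
  if (t < 0 || t > sim$duration) stop("'t' outside the simulation")
  col <- which.min(abs(sim$trace_t - t))
  ids <- as.integer(rownames(sim$traces))
  row <- match(ids, sim$cells$id)
  spiked <- ids %in% sim$spikes$id[sim$spikes$t_ms > t - spike_window &
                                     sim$spikes$t_ms <= t + 1e-9]
  data.frame(id = ids, cell_type = sim$cells$cell_type[row],
             x = sim$cells$x[row], y = sim$cells$y[row],
             z = sim$cells$z[row], v_m = sim$traces[, col],
             spiked = spiked, stringsAsFactors = FALSE)
}

#' Write spikes to CSV
#'
#' @param sim A `ret_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(sim, path) {
  utils::write.csv(sim$spikes, path, row.names = FALSE)
  invisible(path)
}
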