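# Reduced-patch fixtures, run configuration, and figure-reproduction
# drivers.

#' Reduced-patch network fixture
#'
#' Builds a network on a `(300 * scale)`-um square patch with the default
#' specs; used by the test suite so no test needs the full patch.  Counts
#' scale with patch area (lattice rounding aside).
#'
#' @param scale Linear patch scale in `(0, 1]`.
#' @param seed Layout seed.
#' @param membrane Membrane parameters.
#' @return A `ret_network`.
#' @export
make_fixture <- function(scale = 1 / 3, seed = 1L,
                         membrane = default_membrane_params()) {
  stopifnot(scale > 0, scale <= 1)
  side <- 300 * scale
  lay <- build_layout(patch = c(side, side), seed = seed)
  empty <- names(which(layout_census(lay) == 0))
  if (length(empty))
    stop("patch too small: no cells of type ", paste(empty, collapse = ", "))
  net <- suppressWarnings(build_network(lay, membrane = membrane))
  net
}

#' Time-resolved firing-rate map
#'
#' Per-cell mean rates over a window, optionally with Gaussian-smoothed
#' time-resolved rates (default 50 ms kernel).
#'
#' @param sim A `ret_sim`.
#' @param window `c(start, end)` ms.
#' @param smooth_sd_ms Gaussian kernel SD for the time-resolved rates, or
#'   `NULL` for means only.
#' @param dt_ms Sampling step of the time-resolved rates.
#' @return List: `per_cell` (id, cell_type, rate_hz), and if requested
#'   `t_ms` plus `rates_hz` (cells x time matrix, Hz).
#' @export
rate_map <- function(sim, window = NULL, smooth_sd_ms = 50, dt_ms = 10) {
  base <- spontaneous_rate(sim, window = window)
  out <- list(per_cell = base$per_cell)
  if (!is.null(smooth_sd_ms)) {
    if (is.null(window)) window <- c(sim$config$transient_ms, sim$duration)
    tg <- seq(window[1], window[2], by = dt_ms)
    rgc <- base$per_cell$id
    sp <- spike_subset(sim$spikes, window, rgc)
    rates <- matrix(0, length(rgc), length(tg),
                    dimnames = list(rgc, NULL))
    for (i in seq_along(rgc)) {
      tt <- sp$t_ms[sp$id == rgc[i]]
      if (length(tt))
        rates[i, ] <- rowSums(outer(tg, tt, function(a, b)
          stats::dnorm(a - b, sd = smooth_sd_ms))) * 1000
    }
    out$t_ms <- tg
    out$rates_hz <- rates
  }
  out
}

#' Read and validate a run configuration
#'
#' YAML (or JSON) run descriptions: patch geometry, degeneration stage,
#' simulation settings and master seed.  Unknown keys are rejected.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return Validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else if (requireNamespace("yaml", quietly = TRUE))
           yaml::read_yaml(path)
         else stop("reading YAML configs requires the 'yaml' package")
  allowed <- c("patch", "seed", "degeneration", "simulation", "output_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- list(patch = c(300, 300), seed = 1L,
              degeneration = list(s = 0, t = 0),
              simulation = list(dt = 0.025, duration = 1000),
              output_dir = ".")
  for (nm in names(cfg)) {
    if (is.list(out[[nm]]))
      out[[nm]] <- utils::modifyList(out[[nm]], as.list(cfg[[nm]]))
    else out[[nm]] <- unlist(cfg[[nm]], use.names = FALSE)
  }
  out$patch <- as.numeric(rep_len(unlist(out$patch), 2))
  out$seed <- as.integer(unlist(out$seed)[1])
  degeneration_state(out$degeneration$s, out$degeneration$t)  # validates
  out
}

#' Write a run manifest
#'
#' Records the full configuration, seed and package version next to run
#' artifacts so every output is reproducible from its manifest alone.
#'
#' @param path Output JSON path.
#' @param config Arbitrary configuration list.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config) {
  config$package_version <- as.character(utils::packageVersion("retisim"))
  config$r_version <- R.version.string
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reproduce the headline experiments at a configurable scale
#'
#' Drivers for the main result figures, writing tidy CSVs (and PNG plots
#' when ggplot2 is installed) into `out_dir`:
#' * `"light_response"`: layer-resolved snapshot 110 ms after onset of the
#'   bright-disk stimulus.
#' * `"spontaneous_course"`: per-class spontaneous rate across the disease
#'   course.
#' * `"light_course"`: disk/annulus-driven rates across the course.
#' * `"receptive_fields"`: GLM filters for a healthy center cell of each
#'   class.
#' * `"thresholds"`: relative epiretinal and subretinal thresholds across
#'   degeneration.
#' * `"fi_curves"`: F-I curves for the three stimulation modes.
#'
#' @param which Experiment name (above).
#' @param out_dir Output directory (created if missing).
#' @param scale Linear patch scale (1 = full 300 um patch).
#' @param seed Master seed.
#' @return Invisibly, the paths written.
#' @export
reproduce <- function(which = c("light_response", "spontaneous_course",
                                "light_course", "receptive_fields",
                                "thresholds", "fi_curves"),
                      out_dir = ".", scale = 0.5, seed = 1L) {
  which <- match.arg(which)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_fixture(scale, seed)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  plot_png <- function(p, name) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible())
    f <- file.path(out_dir, paste0(name, ".png"))
    ggplot2::ggsave(f, p, width = 7, height = 5, dpi = 120)
    paths <<- c(paths, f)
  }
  switch(which,
    light_response = {
      onset <- 500
      sim <- run_simulation(net, light_disk(onset_ms = onset),
                            config = sim_config(duration = onset + 150,
                                                seed = seed,
                                                record = "all",
                                                trace_dt = 5))
      snap <- snapshot(sim, onset + 110)
      emit(snap, "light_response_snapshot")
      if (requireNamespace("ggplot2", quietly = TRUE)) {
        gg <- ggplot2::ggplot(snap, ggplot2::aes(x, y, colour = v_m)) +
          ggplot2::geom_point(size = 0.8) +
          ggplot2::facet_wrap(~cell_type) +
          ggplot2::scale_colour_viridis_c() +
          ggplot2::labs(title = "Membrane potential 110 ms after disk onset",
                        colour = "mV")
        plot_png(gg, "light_response_snapshot")
      }
    },
    spontaneous_course = {
      u <- seq(0, 2, by = 0.25)
      res <- degeneration_sweep(net, u, measure_spontaneous(
        duration_ms = 2000, config = sim_config(seed = seed)))
      emit(res, "spontaneous_course")
      if (requireNamespace("ggplot2", quietly = TRUE)) {
        gg <- ggplot2::ggplot(res, ggplot2::aes(u, mean,
                                                colour = cell_type)) +
          ggplot2::geom_line() + ggplot2::geom_point() +
          ggplot2::labs(x = "disease progression", y = "rate (Hz)")
        plot_png(gg, "spontaneous_course")
      }
    },
    light_course = {
      u <- seq(0, 2, by = 0.25)
      stim <- light_disk(radius = 40, intensity = 1, ring = c(40, 80),
                         ring_intensity = 0)
      meas <- function(network, uu) {
        cfg <- sim_config(duration = 1200, seed = seed)
        sim <- run_simulation(network, stim, config = cfg)
        spontaneous_rate(sim, window = c(200, 1200))$by_class
      }
      res <- degeneration_sweep(net, u, meas)
      emit(res, "light_course")
    },
    receptive_fields = {
      side <- 300 * scale
      cloud <- light_cloud(duration_s = 100, patch = c(side, side),
                           seed = seed)
      sim <- run_simulation(net, cloud,
                            config = sim_config(duration = cloud$duration_ms,
                                                seed = seed))
      cells <- net$layout$cells
      r <- sqrt(cells$x^2 + cells$y^2)
      for (cls in rgc_types()) {
        cid <- cells$id[cells$cell_type == cls][which.min(r[cells$cell_type ==
                                                              cls])]
        counts <- bin_spikes(sim$spikes$t_ms[sim$spikes$id == cid],
                             cloud$duration_ms)
        fit <- fit_glm(cloud$frames, counts,
                       config = glm_config(epochs = 1500))
        df <- do.call(rbind, lapply(seq_len(dim(fit$k)[3]), function(l)
          data.frame(lag_ms = -(l - 1) * 50,
                     px = rep(seq_len(dim(fit$k)[1]), dim(fit$k)[2]),
                     py = rep(seq_len(dim(fit$k)[2]),
                              each = dim(fit$k)[1]),
                     weight = as.vector(fit$k[, , l]))))
        emit(df, paste0("receptive_field_", tolower(cls)))
      }
    },
    thresholds = {
      amps <- c(0, 4, 8, 16, 32, 64, 128)
      res <- list()
      for (placement in c("epiretinal", "subretinal")) {
        el <- disk_electrode(placement)
        healthy <- threshold_search(net, el, amps, n_trials = 5,
                                    config = sim_config(seed = seed))
        for (uu in c(0.5, 1, 1.5)) {
          d <- degenerate(net, progression_schedule(uu))
          st <- threshold_search(d, el, amps, n_trials = 5,
                                 config = sim_config(seed = seed))
          rel <- relative_thresholds(st, healthy)
          res[[length(res) + 1]] <- cbind(placement = placement, u = uu, rel)
        }
      }
      emit(do.call(rbind, res), "thresholds_course")
    },
    fi_curves = {
      res <- list()
      for (mode in c("injected", "epiretinal", "subretinal")) {
        amps <- if (mode == "injected") c(0, 20, 40, 80, 160) else
          c(0, 8, 16, 32, 64)
        for (uu in c(0, 0.5, 1)) {
          d <- degenerate(net, progression_schedule(uu))
          fc <- fi_curve(d, mode, amps, config = sim_config(seed = seed))
          res[[length(res) + 1]] <- cbind(mode = mode, u = uu, fc)
        }
      }
      emit(do.call(rbind, res), "fi_curves")
    })
  write_manifest(file.path(out_dir, paste0(which, "_manifest.json")),
                 list(experiment = which, scale = scale, seed = seed))
  invisible(paths)
}
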