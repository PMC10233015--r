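# Staged retinal-degeneration transforms: outer-segment truncation and
# cone death (Phase I/II), then inner-retinal cell death and migration
# (Phase III).

#' Degeneration stage descriptor
#'
#' `s` is the Phase I/II progress (joint cone death and outer-segment
#' truncation), `t` the Phase III progress (inner-retinal death and
#' migration); both in `[0, 1]`, and Phase III only starts after Phase
#' I/II completes.
#'
#' @param s Phase I/II progress.
#' @param t Phase III progress.
#' @return A `degeneration_state` list with derived quantities
#'   (`cone_survival`, `G_light_scale`, `inner_survival`,
#'   `migration_fraction`).
#' @export
degeneration_state <- function(s = 0, t = 0) {
  if (s < 0 || s > 1 || t < 0 || t > 1)
    stop("'s' and 't' must lie in [0, 1]")
  if (t > 0 && s < 1)
    stop("Phase III ('t' > 0) requires completed Phase I/II (s = 1)")
  structure(list(s = s, t = t, cone_survival = 1 - s, G_light_scale = 1 - s,
                 inner_survival = 1 - t, migration_fraction = 0.5 * t),
            class = "degeneration_state")
}

#' Map normalized disease time onto the two phases
#'
#' Disease time `u` runs linearly from 0 (healthy) through 1 (end of Phase
#' I/II, complete cone loss) to 2 (end of Phase III): constant rates of
#' outer-segment shortening and cell loss in Phase I/II, and of
#' inner-retinal death (survival 1 -> 0) and migration (0 -> 50 %) in
#' Phase III.
#'
#' @param u Normalized disease time in `[0, 2]`.
#' @return A [degeneration_state()].
#' @export
progression_schedule <- function(u) {
  if (u < 0 || u > 2) stop("'u' must lie in [0, 2]")
  if (u <= 1) degeneration_state(s = u, t = 0)
  else degeneration_state(s = 1, t = u - 1)
}

# Per-cell degeneration draws, a pure function of (seed, healthy cell id):
# columns death12, death3, migrate, dest, z.  Nested stage transforms all
# threshold these fixed uniforms, so survivor sets at higher progress are
# subsets of those at lower progress under the same seed.
deg_draws <- function(n, seed) {
  with_seed((as.integer(seed) %% 1000003L) * 31L + 11L, {
    matrix(stats::runif(5L * n), ncol = 5,
           dimnames = list(NULL, c("death12", "death3", "migrate", "dest",
                                   "z")))
  })
}

# Ids of the round(frac * n) cells of `ids` with the smallest draws
# (rank-based so the removed count is exact and nested in frac).
rank_select <- function(ids, u, frac) {
  k <- round(frac * length(ids))
  if (k <= 0) return(integer(0))
  ids[order(u[ids])[seq_len(k)]]
}

#' Phase I/II: cone death and outer-segment truncation
#'
#' Removes a nested random subset of `round(s * N)` cones and scales every
#' surviving cone's light-gated conductance ceiling by `(1 - s)`.
#' Synaptic weights are renormalized over the surviving presynaptic pools;
#' delays are unaffected.  Applying increasing `s` to the same network is
#' cumulative (the survivor set at `s2 > s1` is a subset of that at `s1`).
#'
#' @param network A `ret_network` (healthy or earlier Phase I/II stage).
#' @param s Phase I/II progress in `[0, 1]`.
#' @param seed Seed for the death draws; defaults to the layout seed so a
#'   stage is fully described by `(s, t, seed)`.
#' @return The transformed `ret_network`.
#' @export
apply_phase12 <- function(network, s, seed = network$layout$seed) {
  if (s < 0 || s > 1) stop("'s' must lie in [0, 1]")
  if (s == 0) return(network)
  draws <- deg_draws(network$n_healthy, seed)
  cells <- network$layout$cells
  # rank over the healthy cone census so stages nest and the removed
  # count is exactly round(s * N_cones)
  dead <- rank_select(network$healthy_ids$PR, draws[, "death12"], s)
  keep <- !(cells$id %in% dead)
  network$layout$cells <- cells[keep, , drop = FALSE]
  network$connectome <- prune_connectome(network$connectome,
                                         network$layout$cells$id)
  network$glight_scale <- 1 - s
  network$deg$s <- s
  network
}

#' End of Phase I/II: removal of all photoreceptors and horizontal cells
#'
#' Models the functional isolation of any remaining cones (glial seal) by
#' removing every PR and HRZ cell; all other populations, weights and
#' delays are left intact.  Idempotent.
#'
#' @param network A `ret_network`.
#' @return The transformed `ret_network` with `s = 1`.
#' @export
end_phase12 <- function(network) {
  cells <- network$layout$cells
  keep <- !(cells$cell_type %in% c("PR", "HRZ"))
  network$layout$cells <- cells[keep, , drop = FALSE]
  network$connectome <- prune_connectome(network$connectome,
                                         network$layout$cells$id)
  network$glight_scale <- 0
  network$deg$s <- 1
  network
}

#' Phase III: inner-retinal cell death and migration
#'
#' Reduces each bipolar and amacrine population to fraction `(1 - t)`
#' (nested random subsets), then migrates a fraction `0.5 * t` of each
#' surviving bipolar, amacrine and RGC population to its destination
#' layers: new depths are drawn uniformly within the destination band,
#' `x`/`y` and all synaptic weights and delays are unchanged.
#'
#' @param network A `ret_network` with Phase I/II completed (no PR/HRZ).
#' @param t Phase III progress in `[0, 1]`.
#' @param seed Seed for death/migration draws (default: layout seed).
#' @return The transformed `ret_network`.
#' @export
apply_phase3 <- function(network, t, seed = network$layout$seed) {
  if (t < 0 || t > 1) stop("'t' must lie in [0, 1]")
  cells <- network$layout$cells
  if (any(cells$cell_type %in% c("PR", "HRZ")))
    stop("Phase III requires completed Phase I/II (run end_phase12 first)")
  if (t == 0) return(network)
  draws <- deg_draws(network$n_healthy, seed)
  rules <- migration_rules()
  dead <- integer(0)
  for (ct in c("BP_ON", "BP_OFF", "AMA_ON_WF", "AMA_OFF_WF", "AMA_ON_NF")) {
    pool <- network$healthy_ids[[ct]]
    dead <- c(dead, rank_select(pool, draws[, "death3"], t))
  }
  keep <- !(cells$id %in% dead)
  cells <- cells[keep, , drop = FALSE]
  # migration of survivors (applies equally to ON and OFF subtypes)
  for (ct in c("BP_ON", "BP_OFF", "AMA_ON_WF", "AMA_OFF_WF", "AMA_ON_NF",
               "RGC_ON", "RGC_OFF")) {
    cls <- .migration_class(ct)
    bands <- rules[[cls]]
    ids <- cells$id[cells$cell_type == ct]
    mig <- rank_select(ids, draws[, "migrate"], 0.5 * t)
    if (!length(mig)) next
    cum <- cumsum(bands[, "prop"])
    band_idx <- findInterval(draws[mig, "dest"], cum, left.open = TRUE) + 1L
    z_new <- bands[band_idx, "z_min"] +
      draws[mig, "z"] * (bands[band_idx, "z_max"] - bands[band_idx, "z_min"])
    cells$z[match(mig, cells$id)] <- z_new
  }
  network$layout$cells <- cells
  network$connectome <- prune_connectome(network$connectome, cells$id)
  network$deg$t <- t
  network
}

#' Build a network at an arbitrary degeneration stage
#'
#' Convenience wrapper: applies [apply_phase12()], [end_phase12()] and
#' [apply_phase3()] as dictated by the stage, starting from a healthy
#' network.
#'
#' @param network A healthy `ret_network`.
#' @param state A [degeneration_state()] (or use `s`/`t` directly).
#' @param s,t Stage parameters, used if `state` is missing.
#' @param seed Seed for all degeneration draws (default: layout seed).
#' @return The degenerated `ret_network`.
#' @export
degenerate <- function(network, state = degeneration_state(s, t), s = 0,
                       t = 0, seed = network$layout$seed) {
  if (network$deg$s > 0 || network$deg$t > 0)
    stop("'degenerate' expects a healthy network")
  net <- apply_phase12(network, state$s, seed = seed)
  if (state$t > 0) {
    net <- end_phase12(net)
    net <- apply_phase3(net, state$t, seed = seed)
  }
  net
}
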