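# Typed, spatially weighted graded synapses between the cell mosaics.

#' Normalized spatial pooling weights for one postsynaptic cell
#'
#' Presynaptic cells within the connection radius contribute with weight
#' proportional to `exp(-D / sigma)`, where `D` is the lateral (x, y)
#' Euclidean distance to the postsynaptic cell; weights are normalized to
#' sum to 1 over the pool.
#'
#' @param post_position Length-2 numeric, (x, y) of the postsynaptic cell
#'   (um).
#' @param pre_positions Matrix (n x 2) of presynaptic (x, y) positions.
#' @param sigma Pooling length (um), > 0.
#' @param cutoff Connection radius (um); default `3 * sigma`.
#' @return Numeric vector of length n: normalized weights, zero outside the
#'   cutoff.  If no presynaptic cell lies within the cutoff, an
#'   orphan-cell warning is raised and all weights are zero (the cell
#'   receives no conductance from this projection).
#' @export
spatial_weights <- function(post_position, pre_positions, sigma,
                            cutoff = 3 * sigma) {
  stopifnot(sigma > 0)
  dx <- pre_positions[, 1] - post_position[1]
  dy <- pre_positions[, 2] - post_position[2]
  d <- sqrt(dx * dx + dy * dy)
  w <- numeric(length(d))
  in_range <- d <= cutoff
  if (!any(in_range)) {
    warning("orphan postsynaptic cell: no presynaptic partner within ",
            cutoff, " um")
    return(w)
  }
  w[in_range] <- exp(-d[in_range] / sigma)
  w / sum(w)
}

#' Presynaptic graded-transmission conductance
#'
#' Sigmoid mapping from the (delayed) presynaptic membrane potential to a
#' synaptic conductance between `G_min` and `G_max`: monotone increasing
#' for kind "I", monotone decreasing for kind "D", centered at `V50` with
#' steepness `beta`.
#'
#' @param v_pre Presynaptic membrane potential(s) at `t - tau` (mV).
#' @param spec A row of [default_synapse_specs()] (list or one-row
#'   data.frame with `G_min`, `G_max`, `V50`, `beta`, `kind`).
#' @return Conductance (nS), same length as `v_pre`.
#' @export
presyn_conductance <- function(v_pre, spec) {
  s <- 1 / (1 + exp((v_pre - spec$V50) / spec$beta))   # decreasing sigmoid
  if (identical(spec$kind, "I")) s <- 1 - s
  spec$G_min + (spec$G_max - spec$G_min) * s
}

#' Ohmic synaptic current
#'
#' @param g_syn Synaptic conductance (nS), >= 0.
#' @param v_post Postsynaptic membrane potential (mV).
#' @param E_syn Synaptic reversal potential (mV).
#' @return Current (pA); positive values depolarize.
#' @export
synaptic_current <- function(g_syn, v_post, E_syn) {
  stopifnot(all(g_syn >= 0))
  -g_syn * (v_post - E_syn)
}

#' Build the wiring of the network
#'
#' Instantiates the twelve typed projections over a layout.  For every
#' postsynaptic cell the presynaptic pool is all cells of the source type
#' within `cutoff_sigma * sigma` lateral distance, weighted by
#' `exp(-D / sigma)` and normalized to sum to one.
#'
#' @param layout A `retina_layout`.
#' @param specs Projection table, default [default_synapse_specs()].
#' @param cutoff_sigma Connection radius in units of `sigma` (default 3).
#' @return A `ret_connectome`: list of synapse sets, each holding the
#'   projection parameters plus a compressed edge list (`post_id`, `ptr`,
#'   `pre_id`, `w`, with `w` normalized per postsynaptic cell).
#' @export
build_connectome <- function(layout, specs = default_synapse_specs(),
                             cutoff_sigma = 3) {
  cells <- layout$cells
  by_type <- split(cells, cells$cell_type)
  sets <- vector("list", nrow(specs))
  n_orphan <- 0L
  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    pre <- by_type[[sp$pre]]
    post <- by_type[[sp$post]]
    if (is.null(pre) || is.null(post))
      stop("missing population for projection ", sp$projection)
    cutoff <- cutoff_sigma * sp$sigma
    ptr <- integer(nrow(post) + 1L)
    pre_id <- vector("list", nrow(post))
    wts <- vector("list", nrow(post))
    # chunked dense distance computation keeps memory bounded
    chunk <- max(1L, floor(4e6 / nrow(pre)))
    for (start in seq(1L, nrow(post), by = chunk)) {
      idx <- start:min(start + chunk - 1L, nrow(post))
      dmat <- sqrt(outer(post$x[idx], pre$x, "-")^2 +
                   outer(post$y[idx], pre$y, "-")^2)
      for (i in seq_along(idx)) {
        sel <- which(dmat[i, ] <= cutoff)
        if (length(sel)) {
          ww <- exp(-dmat[i, sel] / sp$sigma)
          pre_id[[idx[i]]] <- pre$id[sel]
          wts[[idx[i]]] <- ww / sum(ww)
        } else n_orphan <- n_orphan + 1L
        ptr[idx[i] + 1L] <- length(sel)
      }
    }
    sets[[k]] <- list(spec = as.list(sp), post_id = post$id,
                      ptr = cumsum(ptr), pre_id = unlist(pre_id),
                      w = unlist(wts))
  }
  if (n_orphan > 0)
    warning(n_orphan, " orphan postsynaptic cell(s) receive no conductance",
            " from at least one projection")
  names(sets) <- specs$projection
  structure(list(sets = sets, cutoff_sigma = cutoff_sigma), class = "ret_connectome")
}

#' @export
print.ret_connectome <- function(x, ...) {
  n_edge <- sum(vapply(x$sets, function(s) length(s$w), 0))
  cat(sprintf("<ret_connectome> %d projections, %d edges\n",
              length(x$sets), n_edge))
  invisible(x)
}

# Remove dead cells from a connectome.  The pooling normalizer W is kept
# at its healthy-network value (weights are NOT renormalized over the
# survivors): a dead presynaptic cell simply contributes zero conductance,
# so shrinking pools lose drive in proportion to the killed weight.  This
# is what couples cone death to the inner retina -- progressive loss of
# pooled excitation silences ON cells while the fading narrow-field ON
# amacrine pathway disinhibits OFF cells.  Postsynaptic rows of dead cells
# are dropped entirely.  Set `renormalize = TRUE` for the alternative
# reading (normalizer over the current pool), under which cell death
# leaves pooled drive unchanged in expectation.
prune_connectome <- function(connectome, alive_ids, renormalize = FALSE) {
  alive <- rep(FALSE, max(alive_ids))
  alive[alive_ids] <- TRUE
  is_alive <- function(id) id <= length(alive) & alive[id]
  connectome$sets <- lapply(connectome$sets, function(s) {
    n_post <- length(s$post_id)
    keep_post <- is_alive(s$post_id)
    ptr_new <- integer(sum(keep_post) + 1L)
    pre_new <- vector("list", sum(keep_post))
    w_new <- vector("list", sum(keep_post))
    j <- 0L
    for (i in seq_len(n_post)) {
      if (!keep_post[i]) next
      j <- j + 1L
      rng <- if (s$ptr[i + 1L] > s$ptr[i]) (s$ptr[i] + 1L):s$ptr[i + 1L]
             else integer(0)
      pid <- s$pre_id[rng]
      ww <- s$w[rng]
      sel <- is_alive(pid)
      if (any(sel)) {
        pre_new[[j]] <- pid[sel]
        w_new[[j]] <- if (renormalize) ww[sel] / sum(ww[sel]) else ww[sel]
      }
      ptr_new[j + 1L] <- sum(sel)
    }
    list(spec = s$spec, post_id = s$post_id[keep_post],
         ptr = cumsum(ptr_new),
         pre_id = as.integer(unlist(pre_new)),
         w = as.numeric(unlist(w_new)))
  })
  connectome
}

#' Export a connectome as a tidy edge list
#'
#' @param connectome A `ret_connectome`.
#' @param path Optional CSV path; if `NULL` the data.frame is returned.
#' @return data.frame with columns `pre_id`, `post_id`, `projection`,
#'   `weight` (invisibly if written to file).
#' @export
connectome_edges <- function(connectome, path = NULL) {
  dfs <- lapply(connectome$sets, function(s) {
    n_per_post <- diff(s$ptr)
    data.frame(pre_id = as.integer(s$pre_id),
               post_id = rep(s$post_id, n_per_post),
               projection = rep(s$spec$projection, length(s$w)),
               weight = as.numeric(s$w), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(dfs, list(make.row.names = FALSE)))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
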