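# Hexagonal mosaics and 3-D layering of the nine cell types.

# Run `expr` with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic per-type sub-seed derived from the layout master seed.
type_seed <- function(seed, cell_type) {
  (as.integer(seed) %% 1000003L) * 101L + 7L * match(cell_type, cell_types())
}

#' Hexagonal (triangular-lattice) mosaic positions
#'
#' Generates all nodes of a triangular lattice with nearest-neighbour
#' spacing `2 * lambda` (basis vectors `(1, sqrt(3)) * lambda` and
#' `(1, -sqrt(3)) * lambda`), centered on the origin (a node at the patch
#' center), shifted by `offset`, and restricted to the patch rectangle
#' `[-W/2, W/2] x [-H/2, H/2]`.
#'
#' Boundary convention: with `n_target = NULL`, all nodes inside the
#' rectangle are kept.  With an integer `n_target`, nodes are ranked by
#' their overhang beyond the rectangle, `max(|x| - W/2, |y| - H/2)` (ties
#' broken by `y`, then `x`), and exactly the first `n_target` nodes are
#' kept.  Because an ideal rectangular crop admits cell counts only in
#' coarse jumps (whole boundary rows/columns at a time), this quota rule is
#' how the per-type boundary slack is calibrated against a reference
#' census; admitted nodes never overhang the boundary by more than about
#' half a lattice constant in practice.
#'
#' @param lambda Lattice constant (um), > 0; node spacing is `2 * lambda`.
#' @param patch_width,patch_height Patch dimensions W, H (um), > 0.
#' @param offset Length-2 lattice offset (um).
#' @param jitter Optional uniform positional jitter half-width (um) applied
#'   per coordinate with the current RNG stream; default 0 (deterministic).
#' @param n_target Optional integer node quota (see Details).
#' @return Numeric matrix with columns `x`, `y` (um).
#' @export
hex_mosaic <- function(lambda, patch_width, patch_height, offset = c(0, 0),
                       jitter = 0, n_target = NULL) {
  if (!is.finite(lambda) || lambda <= 0)
    stop("'lambda' must be a positive length (um)")
  if (patch_width <= 0 || patch_height <= 0)
    stop("patch dimensions must be positive")
  stopifnot(length(offset) == 2L)
  eps <- 1e-9
  margin <- if (is.null(n_target)) 0 else 2 * lambda
  hw <- patch_width / 2 + eps + margin
  hh <- patch_height / 2 + eps + margin
  # x = u * lambda + ox, y = sqrt(3) * w * lambda + oy, u + w even
  u <- seq.int(ceiling((-hw - offset[1]) / lambda),
               floor((hw - offset[1]) / lambda))
  w <- seq.int(ceiling((-hh - offset[2]) / (sqrt(3) * lambda)),
               floor((hh - offset[2]) / (sqrt(3) * lambda)))
  if (length(u) == 0L || length(w) == 0L) {
    if (!is.null(n_target) && n_target > 0)
      stop("patch too small for the requested node quota")
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  g <- expand.grid(u = u, w = w)
  g <- g[(g$u + g$w) %% 2L == 0L, , drop = FALSE]
  x <- g$u * lambda + offset[1]
  y <- sqrt(3) * g$w * lambda + offset[2]
  if (is.null(n_target)) {
    keep <- seq_along(x)
  } else {
    overhang <- pmax(abs(x) - patch_width / 2, abs(y) - patch_height / 2)
    if (n_target > length(x))
      stop("patch too small for the requested node quota")
    keep <- order(overhang, y, x)[seq_len(n_target)]
  }
  x <- x[keep]; y <- y[keep]
  if (jitter > 0) {
    x <- x + runif(length(x), -jitter, jitter)
    y <- y + runif(length(y), -jitter, jitter)
  }
  ord <- order(y, x)
  cbind(x = x[ord], y = y[ord])
}

#' Assign uniform random depths within a band
#'
#' Draws one depth per position, independently uniform on
#' `[z_min, z_max]`, using the current RNG stream.
#'
#' @param positions Matrix with columns `x`, `y` (um).
#' @param z_min,z_max Depth band (um), `z_min <= z_max`.
#' @return data.frame with columns `x`, `y`, `z`.
#' @export
assign_depths <- function(positions, z_min, z_max) {
  if (z_min > z_max) stop("'z_min' must not exceed 'z_max'")
  n <- nrow(positions)
  data.frame(x = positions[, "x"], y = positions[, "y"],
             z = if (n) runif(n, z_min, z_max) else numeric(0))
}

#' Build the full cell layout of a retinal patch
#'
#' Concatenates the per-type hexagonal mosaics into a single cell table
#' with globally unique ids.  The layout is a pure function of
#' `(specs, patch, seed)`: per-type RNG sub-streams are derived
#' deterministically from `seed`, so changing one type's spec leaves all
#' other types' depth draws unchanged.
#'
#' @param specs Named list of [mosaic_spec()] objects (one per type, no
#'   duplicates); default [default_mosaic_specs()].
#' @param patch Length-2 numeric, patch width and height (um).
#' @param seed Integer master seed.
#' @param jitter Uniform positional jitter half-width (um), default 0.
#' @return A `retina_layout` object: list with `cells` (data.frame
#'   `id, cell_type, x, y, z`), `patch`, `seed`, `specs`.
#' @export
build_layout <- function(specs = default_mosaic_specs(), patch = c(300, 300),
                         seed = 1L, jitter = 0) {
  types <- vapply(specs, function(s) s$cell_type, character(1))
  if (anyDuplicated(types))
    stop("duplicate cell type in 'specs': ", types[duplicated(types)][1])
  stopifnot(length(patch) == 2L, all(patch > 0))
  pieces <- lapply(specs, function(s) {
    n_target <- if (is.null(s$target_count)) NULL else
      as.integer(round(s$target_count * patch[1] * patch[2] / (300 * 300)))
    with_seed(type_seed(seed, s$cell_type), {
      xy <- hex_mosaic(s$lambda, patch[1], patch[2], offset = s$offset,
                       jitter = jitter, n_target = n_target)
      cbind(assign_depths(xy, s$z_min, s$z_max),
            cell_type = rep(s$cell_type, nrow(xy)))
    })
  })
  if (length(pieces)) {
    cells <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  } else {
    cells <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        cell_type = character(0))
  }
  cells <- data.frame(id = seq_len(nrow(cells)),
                      cell_type = cells$cell_type,
                      x = cells$x, y = cells$y, z = cells$z,
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, patch = as.numeric(patch),
                 seed = as.integer(seed), specs = specs),
            class = "retina_layout")
}

#' @export
print.retina_layout <- function(x, ...) {
  cat(sprintf("<retina_layout> %g x %g um patch, %d cells, seed %d\n",
              x$patch[1], x$patch[2], nrow(x$cells), x$seed))
  print(layout_census(x))
  invisible(x)
}

#' Per-type cell counts of a layout
#'
#' @param layout A `retina_layout`.
#' @return Named integer vector over all nine types (zeros included).
#' @export
layout_census <- function(layout) {
  tab <- table(factor(layout$cells$cell_type, levels = cell_types()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Write / read a layout as CSV plus a JSON sidecar
#'
#' The CSV holds `id, cell_type, x_um, y_um, z_um`; the sidecar records the
#' specs, patch and seed so the layout is reproducible from its files.
#'
#' @param layout A `retina_layout`.
#' @param path CSV file path; the sidecar is written to `<path>.json`.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   `retina_layout`.
#' @export
write_layout <- function(layout, path) {
  df <- layout$cells
  names(df) <- c("id", "cell_type", "x_um", "y_um", "z_um")
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(patch = layout$patch, seed = layout$seed,
               specs = lapply(layout$specs, unclass))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  specs <- lapply(meta$specs, function(s)
    mosaic_spec(s$cell_type, s$lambda, s$z_min, s$z_max, s$G_ext,
                s$soma_diameter, unlist(s$offset),
                target_count = s$target_count))
  names(specs) <- vapply(specs, `[[`, "", "cell_type")
  cells <- data.frame(id = df$id, cell_type = df$cell_type,
                      x = df$x_um, y = df$y_um, z = df$z_um,
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, patch = as.numeric(meta$patch),
                 seed = as.integer(meta$seed), specs = specs),
            class = "retina_layout")
}
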