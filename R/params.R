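#' Cell types of the cone-pathway network
#'
#' The nine modeled cell types: cone photoreceptors (`PR`), horizontal cells
#' (`HRZ`), ON/OFF bipolar cells (`BP_ON`, `BP_OFF`), ON/OFF wide-field
#' amacrine cells (`AMA_ON_WF`, `AMA_OFF_WF`), narrow-field ON amacrine cells
#' (`AMA_ON_NF`), and ON/OFF retinal ganglion cells (`RGC_ON`, `RGC_OFF`).
#' RGCs are the only spiking type.
#'
#' @return Character vector of the nine cell-type names, in canonical order.
#' @export
cell_types <- function() {
  c("PR", "HRZ", "BP_ON", "BP_OFF", "AMA_ON_WF", "AMA_OFF_WF",
    "AMA_ON_NF", "RGC_ON", "RGC_OFF")
}

#' @rdname cell_types
#' @export
rgc_types <- function() c("RGC_ON", "RGC_OFF")

# Light-gated conductance reversal potential (mV), shared by all cones.
E_LIGHT <- -8

#' Construct a mosaic specification for one cell type
#'
#' A mosaic spec fixes the hexagonal-lattice constant `lambda` (half the
#' nearest-neighbour spacing, in um), the depth band `[z_min, z_max]` (um)
#' the somas are scattered in, the extracellular coupling conductance
#' `G_ext` (nS) and the soma diameter (um; 26 for RGCs, 7 otherwise).
#' `offset` is a 2-vector (um) shifting the lattice relative to the patch
#' center.  `target_count`, when set, fixes the number of lattice nodes the
#' boundary rule admits for the reference 300 x 300 um patch (scaled by
#' area for other patch sizes); the default specs carry the reference
#' census as targets, which calibrates the boundary convention (see
#' [hex_mosaic()]).
#'
#' @param cell_type One of [cell_types()].
#' @param lambda Lattice constant (um), > 0.
#' @param z_min,z_max Depth band (um), `z_min <= z_max`.
#' @param G_ext Extracellular coupling conductance (nS).
#' @param soma_diameter Soma diameter (um).
#' @param offset Numeric length-2 lattice offset (um).
#' @param target_count Optional integer: node quota for the reference
#'   300 x 300 um patch, or `NULL` for a plain crop at the patch boundary.
#' @return A `mosaic_spec` object (named list).
#' @export
mosaic_spec <- function(cell_type, lambda, z_min, z_max, G_ext,
                        soma_diameter = if (cell_type %in% rgc_types()) 26 else 7,
                        offset = c(0, 0), target_count = NULL) {
  cell_type <- match.arg(cell_type, cell_types())
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (!is.finite(lambda) || lambda <= 0)
    stop("'lambda' must be a positive length (um)")
  if (z_min > z_max) stop("'z_min' must not exceed 'z_max'")
  stopifnot(length(offset) == 2L, is.finite(offset))
  if (!is.null(target_count)) stopifnot(target_count >= 0)
  structure(list(cell_type = cell_type, lambda = lambda,
                 z_min = z_min, z_max = z_max, G_ext = G_ext,
                 soma_diameter = soma_diameter, offset = as.numeric(offset),
                 target_count = target_count),
            class = "mosaic_spec")
}

#' Default spatial-layout specifications
#'
#' Lattice constants, depth bands and extracellular conductances for the
#' nine cell types of the parafoveal cone-pathway patch.
#'
#' @return Named list of [mosaic_spec()] objects, one per cell type.
#' @export
default_mosaic_specs <- function() {
  tab <- list(
    #             lambda z_min z_max G_ext
    PR         = c(2.5,  170,  205,  4.0),
    HRZ        = c(7.0,  100,  128,  2.5),
    BP_ON      = c(3.85, 100,  128,  2.0),
    BP_OFF     = c(3.85, 100,  128,  2.0),
    AMA_ON_WF  = c(8.0,  80,   101,  2.0),
    AMA_OFF_WF = c(8.0,  80,   101,  2.0),
    AMA_ON_NF  = c(6.0,  80,   101,  2.0),
    RGC_ON     = c(6.0,  25,   39,   2.0),
    RGC_OFF    = c(6.0,  25,   39,   2.0)
  )
  census <- reference_census()
  out <- lapply(names(tab), function(ct) {
    p <- tab[[ct]]
    mosaic_spec(ct, lambda = p[1], z_min = p[2], z_max = p[3], G_ext = p[4],
                target_count = census[[ct]])
  })
  names(out) <- names(tab)
  out
}

#' Reference per-type census for the default 300 x 300 um patch
#'
#' @return Named integer vector of cell counts per type (total 11,138).
#' @export
reference_census <- function() {
  c(PR = 4149L, HRZ = 537L, BP_ON = 1754L, BP_OFF = 1754L,
    AMA_ON_WF = 390L, AMA_OFF_WF = 389L, AMA_ON_NF = 723L,
    RGC_ON = 721L, RGC_OFF = 721L)
}

#' Default membrane parameters per cell type
#'
#' Graded (non-spiking) cells are leaky integrators with capacitance `C_m`
#' (pF), leak conductance `G_m` (nS) and resting potential `E_rest` (mV).
#' Cones additionally carry a light-gated conductance with ceiling
#' `G_light` (nS) and reversal potential -8 mV.  RGCs are seven-channel
#' Hodgkin-Huxley somas; their conductances are densities (mS cm^-2)
#' referred to the spherical soma surface (diameter 26 um).
#'
#' `rgc_leak_scale` is the calibration multiplier on the RGC leak density
#' (one value per RGC class, recycled if scalar), tuned once so each class
#' of the healthy network fires spontaneously at about 2 Hz under uniform
#' 0.5 light (see the methods vignette); all other values are fixed model
#' constants.
#'
#' @param rgc_leak_scale Multiplier(s) on the RGC leak-conductance density
#'   for (ON, OFF), recycled if length 1 (default calibrated values).
#' @return Named list with one parameter list per cell type.
#' @export
default_membrane_params <- function(rgc_leak_scale = RGC_LEAK_SCALE) {
  li <- function(C_m, G_m, E_rest, G_light = 0)
    list(model = if (G_light > 0) "photoreceptor" else "leaky",
         C_m = C_m, G_m = G_m, E_rest = E_rest, G_light = G_light,
         E_light = E_LIGHT)
  rgc_leak_scale <- rep_len(rgc_leak_scale, 2)
  k <- 0
  rgc <- function(G_m, E_rest, E_Na, E_K, E_h,
                  G_Na, G_K, G_KA, G_Ca, G_KCa, G_h, G_CaT)
    list(model = "rgc", C_m = 50, soma_diameter = 26,
         G_m = G_m * rgc_leak_scale[(k <<- k + 1)], E_rest = E_rest,
         E_Na = E_Na, E_K = E_K, E_h = E_h,
         G_Na = G_Na, G_K = G_K, G_KA = G_KA, G_Ca = G_Ca,
         G_KCa = G_KCa, G_h = G_h, G_CaT = G_CaT)
  list(
    PR         = li(80, 4.0, -50, G_light = 0.9),
    HRZ        = li(210, 2.5, -65),
    BP_ON      = li(50, 2.0, -45),
    BP_OFF     = li(50, 2.0, -45),
    AMA_ON_WF  = li(50, 2.0, -50),
    AMA_OFF_WF = li(50, 2.0, -50),
    AMA_ON_NF  = li(50, 2.0, -50),
    RGC_ON  = rgc(0.3,   -66.5, 35, -72, -45.8,
                  1072, 40.5, 94.5, 2.1, 0.04,   0.4287, 0.008),
    RGC_OFF = rgc(0.274, -70.5, 35, -68, -26.8,
                  249,  68.85, 18.9, 1.6, 0.0474, 0.1429, 0.1983)
  )
}

# Calibrated RGC leak multipliers (ON, OFF); see methods vignette.
RGC_LEAK_SCALE <- c(1.895, 0.645)

#' Default synaptic parameters (the twelve projections)
#'
#' Each row defines one typed projection: synaptic delay `tau` (ms),
#' reversal potential `E_syn` (mV), conductance bounds `G_min`/`G_max`
#' (nS), sigmoid midpoint `V50` (mV) and steepness `beta` (mV), transfer
#' kind (`I` = conductance increases with presynaptic depolarization,
#' `D` = decreases), and spatial pooling length `sigma` (um).
#'
#' @return data.frame with one row per projection.
#' @export
default_synapse_specs <- function() {
  df <- data.frame(
    pre  = c("PR", "HRZ", "PR", "PR", "BP_ON", "BP_ON", "BP_OFF",
             "BP_ON", "AMA_ON_WF", "BP_OFF", "AMA_OFF_WF", "AMA_ON_NF"),
    post = c("HRZ", "PR", "BP_ON", "BP_OFF", "AMA_ON_WF", "AMA_ON_NF",
             "AMA_OFF_WF", "RGC_ON", "RGC_ON", "RGC_OFF", "RGC_OFF",
             "RGC_OFF"),
    tau   = c(7, 7, 5, 13, 5, 5, 11, 5, 5, 13, 12, 12),
    E_syn = c(0, -67, 0, 0, 0, 0, 0, 0, -70, 0, -70, -80),
    G_min = c(0, 0, 0.1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    G_max = c(7.0, 3.0, 1.1, 3.75, 1.0, 0.2, 1.8, 2.5, 2.0, 2.5, 2.5, 2.0),
    V50   = c(-43.0, -29.5, -47.0, -41.5, -33.5, -35.0, -44.0, -33.5,
              -42.5, -44.0, -34.4, -47.5),
    beta  = c(2.0, 7.4, 1.7, 1.2, 3.0, 3.0, 3.0, 3.0, 2.5, 3.0, 2.5, 2.0),
    kind  = c("I", "I", "D", "I", "I", "I", "I", "I", "I", "I", "I", "I"),
    sigma = c(10.5, 2.5, 3.85, 3.85, 24.0, 6.0, 24.0, 6.0, 6.0, 6.0, 6.0,
              6.0),
    stringsAsFactors = FALSE
  )
  df$projection <- paste(df$pre, df$post, sep = "->")
  df
}

#' Depth bands occupied by surviving inner neurons during remodeling
#'
#' Migration destinations for the late-degeneration transform: amacrine
#' cells move in equal proportions to the horizontal-cell layer, the inner
#' plexiform layer, and the ganglion-cell layer; bipolar cells split
#' between the inner plexiform and ganglion-cell layers; RGCs move to the
#' horizontal-cell layer (toward the glial seal).
#'
#' @return Named list: per cell class, a matrix with columns `z_min`,
#'   `z_max`, `prop` (destination proportions summing to 1).
#' @export
migration_rules <- function() {
  band <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE,
                dimnames = list(NULL, c("z_min", "z_max", "prop")))
    stopifnot(abs(sum(m[, "prop"]) - 1) < 1e-12)
    m
  }
  list(
    BP  = band(25, 39, 0.5,
               40, 80, 0.5),
    AMA = band(100, 128, 1 / 3,
               40, 80, 1 / 3,
               25, 39, 1 / 3),
    RGC = band(100, 128, 1)
  )
}

# Map a concrete cell type to its migration class (NA = never migrates).
.migration_class <- function(cell_type) {
  cls <- c(PR = NA, HRZ = NA, BP_ON = "BP", BP_OFF = "BP",
           AMA_ON_WF = "AMA", AMA_OFF_WF = "AMA", AMA_ON_NF = "AMA",
           RGC_ON = "RGC", RGC_OFF = "RGC")
  unname(cls[cell_type])
}
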