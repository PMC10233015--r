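# Light stimuli, the extracellular disk electrode, and pulse trains.

new_light <- function(type, ...) {
  structure(list(type = type, ...), class = c(paste0("light_", type),
                                              "light_stimulus"))
}

#' Light stimuli
#'
#' Constructors for the space-time intensity fields `l(x, y, t)` in
#' `[0, 1]` used to drive the cones:
#' * `light_full_field()`: spatially uniform constant intensity.
#' * `light_disk()`: a disk (optionally surrounded by an annulus) appearing
#'   at `onset_ms` on a uniform background.
#' * `light_square_wave()`: a disk whose intensity alternates between
#'   `background * (1 + contrast)` and `background` with a fixed phase
#'   duration.
#' * `light_cloud()`: spatially correlated Gaussian white-noise movie
#'   (pixelated, low-pass filtered with a spatial Gaussian, clipped to
#'   `[0, 1]`) for receptive-field mapping.
#'
#' @param intensity,background Intensities in `[0, 1]`.
#' @param radius Disk radius (um).
#' @param ring Optional `c(inner, outer)` radii (um) of a surrounding
#'   annulus shown at `ring_intensity`.
#' @param ring_intensity Annulus intensity.
#' @param center Disk center (um).
#' @param onset_ms Time (ms) at which the disk/annulus appears; before it
#'   the field is uniform background.
#' @param contrast Signed contrast of the modulated disk (e.g. 1, 0.5,
#'   -0.5, -1).
#' @param phase_ms Square-wave phase duration (ms).
#' @param duration_s Cloud movie duration (s).
#' @param patch Cloud extent `c(width, height)` (um).
#' @param pixel_um Cloud pixel size (um).
#' @param mean,sd Cloud pixel mean and standard deviation before clipping.
#' @param refresh_hz Cloud refresh rate (Hz).
#' @param filter_sd Spatial Gaussian filter SD (um).
#' @param seed Cloud RNG seed.
#' @return A `light_stimulus` object; evaluate with [light_at()].
#' @name light_stimuli
NULL

#' @rdname light_stimuli
#' @export
light_full_field <- function(intensity = 0.5) {
  stopifnot(intensity >= 0, intensity <= 1)
  new_light("full_field", intensity = intensity)
}

#' @rdname light_stimuli
#' @export
light_disk <- function(radius = 40, intensity = 1, background = 0.5,
                       ring = NULL, ring_intensity = 0, center = c(0, 0),
                       onset_ms = 0) {
  stopifnot(radius > 0)
  new_light("disk", radius = radius, intensity = intensity,
            background = background, ring = ring,
            ring_intensity = ring_intensity, center = center,
            onset_ms = onset_ms)
}

#' @rdname light_stimuli
#' @export
light_square_wave <- function(contrast, radius = 40, background = 0.5,
                              phase_ms = 200, center = c(0, 0),
                              onset_ms = 0) {
  new_light("square_wave", contrast = contrast, radius = radius,
            background = background, phase_ms = phase_ms, center = center,
            onset_ms = onset_ms)
}

#' @rdname light_stimuli
#' @export
light_cloud <- function(duration_s = 10, patch = c(300, 300),
                        pixel_um = 6.25, mean = 0.5, sd = 0.175,
                        refresh_hz = 20, filter_sd = 12.5, seed = 1L) {
  nx <- ceiling(patch[1] / pixel_um)
  ny <- ceiling(patch[2] / pixel_um)
  n_frames <- ceiling(duration_s * refresh_hz)
  frames <- with_seed(seed, {
    arr <- array(stats::rnorm(nx * ny * n_frames), c(nx, ny, n_frames))
    sig_px <- filter_sd / pixel_um
    half <- max(1L, ceiling(3 * sig_px))
    kern <- stats::dnorm(-half:half, sd = sig_px)
    kern <- kern / sum(kern)
    for (f in seq_len(n_frames)) {
      fr <- arr[, , f]
      fr <- apply(fr, 2, function(col) conv_same(col, kern))
      fr <- t(apply(fr, 1, function(row) conv_same(row, kern)))
      # restore the nominal contrast the filter removed, then clip
      fr <- fr / stats::sd(fr) * sd + mean
      arr[, , f] <- pmin(pmax(fr, 0), 1)
    }
    arr
  })
  new_light("cloud", frames = frames, patch = patch, pixel_um = pixel_um,
            refresh_hz = refresh_hz, mean = mean, sd = sd,
            filter_sd = filter_sd, seed = seed,
            duration_ms = n_frames / refresh_hz * 1000)
}

# 1-D "same" convolution with replicated edges.
conv_same <- function(x, kern) {
  half <- (length(kern) - 1L) / 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  stats::filter(xp, kern, sides = 2)[(half + 1L):(half + length(x))]
}

#' Evaluate a light stimulus
#'
#' @param stimulus A `light_stimulus`.
#' @param x,y Positions (um); vectors of equal length.
#' @param t Time (ms), scalar.
#' @return Intensities in `[0, 1]`, one per position.
#' @export
light_at <- function(stimulus, x, y, t) {
  UseMethod("light_at")
}

#' @export
light_at.light_full_field <- function(stimulus, x, y, t) {
  rep(stimulus$intensity, length(x))
}

#' @export
light_at.light_disk <- function(stimulus, x, y, t) {
  out <- rep(stimulus$background, length(x))
  if (t < stimulus$onset_ms) return(out)
  r <- sqrt((x - stimulus$center[1])^2 + (y - stimulus$center[2])^2)
  if (!is.null(stimulus$ring))
    out[r > stimulus$ring[1] & r <= stimulus$ring[2]] <- stimulus$ring_intensity
  out[r <= stimulus$radius] <- stimulus$intensity
  out
}

#' @export
light_at.light_square_wave <- function(stimulus, x, y, t) {
  out <- rep(stimulus$background, length(x))
  if (t < stimulus$onset_ms) return(out)
  phase <- floor((t - stimulus$onset_ms) / stimulus$phase_ms)
  if (phase %% 2 == 0) {
    lev <- min(max(stimulus$background * (1 + stimulus$contrast), 0), 1)
    r <- sqrt((x - stimulus$center[1])^2 + (y - stimulus$center[2])^2)
    out[r <= stimulus$radius] <- lev
  }
  out
}

#' @export
light_at.light_cloud <- function(stimulus, x, y, t) {
  dm <- dim(stimulus$frames)
  f <- min(max(floor(t / 1000 * stimulus$refresh_hz) + 1, 1), dm[3])
  ix <- pmin(pmax(floor((x + stimulus$patch[1] / 2) / stimulus$pixel_um) + 1,
                  1), dm[1])
  iy <- pmin(pmax(floor((y + stimulus$patch[2] / 2) / stimulus$pixel_um) + 1,
                  1), dm[2])
  stimulus$frames[cbind(ix, iy, f)]
}

# Temporal breakpoints (ms) of a stimulus on [0, t_end]: times at which the
# field changes.  Used to rasterize light onto the cones as
# piecewise-constant segments.
light_breaks <- function(stimulus, t_end) {
  br <- switch(stimulus$type,
    full_field = numeric(0),
    disk = stimulus$onset_ms,
    square_wave = c(stimulus$onset_ms,
                    seq(stimulus$onset_ms, t_end, by = stimulus$phase_ms)),
    cloud = seq(0, t_end, by = 1000 / stimulus$refresh_hz)
  )
  sort(unique(c(0, br[br > 0 & br < t_end], t_end)))
}

# ---------------------------------------------------------------------------
# Extracellular electrical stimulation

#' Disk stimulation electrode
#'
#' @param placement `"epiretinal"` (centered at `(0, 0, -2)` um, vitreal
#'   side) or `"subretinal"` (`(0, 0, 135)` um, beneath the bipolar
#'   layer), or `"custom"` with an explicit `center`.
#' @param diameter Disk diameter (um), default 80.
#' @param center Optional `c(x, y, z)` (um) overriding the placement.
#' @return A `disk_electrode` object.
#' @export
disk_electrode <- function(placement = c("epiretinal", "subretinal", "custom"),
                           diameter = 80, center = NULL) {
  placement <- match.arg(placement)
  stopifnot(diameter > 0)
  if (is.null(center))
    center <- switch(placement, epiretinal = c(0, 0, -2),
                     subretinal = c(0, 0, 135),
                     custom = stop("'custom' placement needs 'center'"))
  structure(list(placement = placement, diameter = diameter,
                 center = as.numeric(center)), class = "disk_electrode")
}

#' Extracellular potential of an equipotential disk
#'
#' Classic disk-electrode solution in a semi-infinite homogeneous medium:
#' `v_e = (2 V0 / pi) * asin(2 a / (sqrt((r - a)^2 + d^2) +
#' sqrt((r + a)^2 + d^2)))` with disk radius `a = diameter / 2`, lateral
#' distance `r` and axial offset `d` from the disk plane.  Equals `V0` on
#' the disk and decays to zero far away.
#'
#' @param electrode A [disk_electrode()].
#' @param V0 Disk potential (mV).
#' @param x,y,z Field positions (um), vectors of equal length.
#' @return Potential (mV) at each position.
#' @export
electrode_potential <- function(electrode, V0, x, y, z) {
  a <- electrode$diameter / 2
  r <- sqrt((x - electrode$center[1])^2 + (y - electrode$center[2])^2)
  d <- z - electrode$center[3]
  arg <- 2 * a / (sqrt((r - a)^2 + d^2) + sqrt((r + a)^2 + d^2))
  2 * V0 / pi * asin(pmin(arg, 1))
}

#' Extracellular coupling current of a spherical soma
#'
#' The drive a cell receives from the electrode field: half the
#' extracellular coupling conductance times the average absolute potential
#' difference across `n_pairs` uniformly sampled, diametrically opposing
#' point pairs on the soma sphere, signed by the polarity of `V0`.
#'
#' @param electrode A [disk_electrode()].
#' @param soma_center `c(x, y, z)` (um).
#' @param soma_diameter Soma diameter (um).
#' @param G_ext Extracellular coupling conductance (nS).
#' @param V0 Disk potential (mV); default 1 so the result is a gain in
#'   pA per mV of disk potential.
#' @param n_pairs Number of antipodal sample pairs.
#' @param seed RNG seed for the sphere sampling.
#' @return Current (pA); `sign(V0) * G_ext / 2 * mean(|delta v_e|)`.
#' @export
soma_coupling_current <- function(electrode, soma_center, soma_diameter,
                                  G_ext, V0 = 1, n_pairs = 500, seed = 1L) {
  gains <- soma_coupling_gains(electrode,
                               matrix(soma_center, nrow = 1),
                               soma_diameter, G_ext, n_pairs = n_pairs,
                               seed = seed)
  gains * abs(V0) * sign(V0)
}

# Vectorized coupling gains (pA per mV of V0) for many somas.  Each soma
# gets its own seeded antipodal sample.  `field` defaults to the disk
# potential at V0 = 1 mV; an arbitrary field function (x, y, z) -> mV can
# be substituted (used by the analytic checks of the sphere average).
soma_coupling_gains <- function(electrode, centers, soma_diameter, G_ext,
                                n_pairs = 500, seed = 1L,
                                field = function(x, y, z)
                                  electrode_potential(electrode, 1, x, y, z)) {
  n <- nrow(centers)
  soma_diameter <- rep_len(soma_diameter, n)
  G_ext <- rep_len(G_ext, n)
  with_seed(seed, {
    out <- numeric(n)
    chunk <- max(1L, floor(2e6 / n_pairs))
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      m <- length(idx) * n_pairs
      dir <- matrix(stats::rnorm(3 * m), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      rad <- rep(soma_diameter[idx] / 2, each = n_pairs)
      cx <- rep(centers[idx, 1], each = n_pairs)
      cy <- rep(centers[idx, 2], each = n_pairs)
      cz <- rep(centers[idx, 3], each = n_pairs)
      vp <- field(cx + rad * dir[, 1], cy + rad * dir[, 2],
                  cz + rad * dir[, 3])
      vm <- field(cx - rad * dir[, 1], cy - rad * dir[, 2],
                  cz - rad * dir[, 3])
      dv <- abs(vp - vm)
      out[idx] <- 0.5 * G_ext[idx] *
        colMeans(matrix(dv, nrow = n_pairs))
    }
    out
  })
}

# ---------------------------------------------------------------------------
# Pulse trains

#' Charge-balanced biphasic pulse train
#'
#' Cathodic-first rectangular biphasic pulses: each pulse is a cathodic
#' phase immediately followed (after an optional interphase gap) by an
#' anodic phase of equal duration and amplitude, so the net charge per
#' pulse is zero.
#'
#' @param amplitude_ua Pulse amplitude (uA).
#' @param frequency_hz Pulse rate (Hz), default 20.
#' @param phase_ms Single-phase duration (ms), default 0.45.
#' @param duration_s Train duration (s), default 1.
#' @param interphase_ms Gap between the two phases (ms), default 0.
#' @param onset_ms Train onset (ms), default 0.
#' @return A `pulse_train` object.
#' @export
biphasic_train <- function(amplitude_ua, frequency_hz = 20, phase_ms = 0.45,
                           duration_s = 1, interphase_ms = 0, onset_ms = 0) {
  period <- 1000 / frequency_hz
  if (2 * phase_ms + interphase_ms > period)
    stop("pulse phases do not fit in the stimulation period")
  structure(list(amplitude_ua = amplitude_ua, frequency_hz = frequency_hz,
                 phase_ms = phase_ms, duration_s = duration_s,
                 interphase_ms = interphase_ms, onset_ms = onset_ms),
            class = "pulse_train")
}

#' Normalized pulse-train waveform
#'
#' @param train A [biphasic_train()].
#' @param t Time (ms); vectorized.
#' @return -1 during cathodic phases, +1 during anodic phases, 0
#'   elsewhere.
#' @export
pulse_waveform <- function(train, t) {
  period <- 1000 / train$frequency_hz
  tt <- t - train$onset_ms
  inside <- tt >= 0 & tt < train$duration_s * 1000
  ph <- tt %% period
  out <- numeric(length(t))
  out[inside & ph < train$phase_ms] <- -1
  a0 <- train$phase_ms + train$interphase_ms
  out[inside & ph >= a0 & ph < a0 + train$phase_ms] <- 1
  out
}

# Piecewise-constant waveform segments on [0, t_end]: boundaries (ms) and
# the normalized value on each segment.
train_segments <- function(train, t_end) {
  period <- 1000 / train$frequency_hz
  onsets <- seq(train$onset_ms, train$onset_ms + train$duration_s * 1000 -
                  1e-9, by = period)
  a0 <- train$phase_ms + train$interphase_ms
  br <- sort(unique(c(0, t_end, outer(onsets, c(0, train$phase_ms, a0,
                                                a0 + train$phase_ms), "+"))))
  br <- br[br >= 0 & br <= t_end]
  mid <- (br[-1] + br[-length(br)]) / 2
  list(breaks = br, value = pulse_waveform(train, mid))
}

# Default conversion from pulse amplitude (uA) to disk potential V0 (mV):
# the access-resistivity constant of the stimulation medium.  Calibrated
# once so that a 60 uA epiretinal train is suprathreshold for healthy RGCs
# under the electrode (see methods vignette); relative (percent-of-healthy)
# thresholds are invariant to this constant.
V0_PER_UA <- 400
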