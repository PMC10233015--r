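# Membrane models: leaky integrators, photoreceptors, and seven-channel
# Hodgkin-Huxley RGC somas, plus the documented gating rate-table component.

#' Leak current
#'
#' `i_leak = -G_m * (v_m - E_rest)`; positive (depolarizing) when the cell
#' is below rest.
#'
#' @param v_m Membrane potential (mV).
#' @param G_m Leak conductance (nS).
#' @param E_rest Resting potential (mV).
#' @return Current (pA).
#' @export
leak_current <- function(v_m, G_m, E_rest) -G_m * (v_m - E_rest)

#' Light-gated conductance of a cone
#'
#' `g_light = G_light * (1 - l)`: fully open in darkness, closed at full
#' light.  The resulting current is `-g_light * (v_m - E_light)` with
#' `E_light = -8 mV`, so darkness depolarizes the cone.
#'
#' @param l Light intensity in `[0, 1]`.
#' @param G_light Conductance ceiling (nS).
#' @return Conductance (nS).
#' @export
light_conductance <- function(l, G_light) {
  if (any(l < 0 | l > 1)) stop("light intensity 'l' must lie in [0, 1]")
  G_light * (1 - l)
}

# x / (1 - exp(-x / s)), continuous at x = 0 (limit s).  Workhorse for the
# linoid rate functions.
linoid <- function(x, s) {
  out <- x / (1 - exp(-x / s))
  small <- abs(x) < 1e-7
  out[small] <- s + x[small] / 2
  out
}

#' Gating rate functions of the RGC ion channels
#'
#' The explicit rate-table component: opening/closing rates (ms^-1) as
#' functions of membrane potential for the ten gating variables of the
#' seven-channel RGC soma.  Channels and exponents: Na (`m^3 h`), Ca
#' (`c^3`), delayed-rectifier K (`n^4`), inactivating K (`mA^3 hA`),
#' Ca-activated K (gated by internal calcium, not voltage),
#' hyperpolarization-activated cation current (`nh`), and low-threshold
#' T-type Ca (`mT^3 hT`, with two-state inactivation `hT`/`dT`).
#'
#' Na/Ca/K/KA kinetics follow the classic amphibian/mammalian RGC
#' five-channel formulation; the h-current uses standard
#' thalamic-relay-style kinetics; the T-type inactivation pair uses slow,
#' bounded rates with a second (deep) inactivated state so that
#' `hT + dT <= 1` is dynamically invariant.  The component is a plain list
#' of R closures so alternative kinetics can be swapped in and tabulated
#' for the integration engine.
#'
#' @return Named list; each element is `function(v)` returning
#'   `list(alpha = ..., beta = ...)` in ms^-1.
#' @export
rgc_rate_functions <- function() {
  list(
    m = function(v) list(alpha = 5 * exp((v + 35) / 14),
                         beta = 5 * exp(-(v + 35) / 14)),
    h = function(v) {
      hinf <- 1 / (1 + exp((v + 50) / 6))
      tau <- 0.2 + 25 / (1 + exp((v + 35) / 4))
      list(alpha = hinf / tau, beta = (1 - hinf) / tau)
    },
    c = function(v) list(alpha = 0.3 * linoid(v + 13, 10),
                         beta = 10 * exp(-(v + 38) / 18)),
    n = function(v) list(alpha = 0.02 * linoid(v + 40, 10),
                         beta = 0.4 * exp(-(v + 50) / 80)),
    mA = function(v) list(alpha = 0.006 * linoid(v + 90, 10),
                          beta = 0.1 * exp(-(v + 30) / 10)),
    hA = function(v) {
      # incomplete inactivation (floor 0.2): the residual A-current at
      # depolarized potentials opposes plateau states at the large Na
      # densities of the ON class
      a0 <- 0.04 * exp(-(v + 70) / 20)
      b0 <- 0.6 / (1 + exp(-0.1 * (v + 40)))
      tau <- 1 / (a0 + b0)
      inf <- 0.2 + 0.8 * a0 * tau
      list(alpha = inf / tau, beta = (1 - inf) / tau)
    },
    nh = function(v) {
      ninf <- 1 / (1 + exp((v + 75) / 5.5))
      tau <- 1 / (exp(-14.59 - 0.086 * v) + exp(-1.87 + 0.0701 * v))
      list(alpha = ninf / tau, beta = (1 - ninf) / tau)
    },
    mT = function(v) {
      minf <- 1 / (1 + exp(-(v + 52) / 7.4))
      tau <- 0.44 + 0.15 / (exp((v + 27) / 10) + exp(-(v + 102) / 15))
      list(alpha = minf / tau, beta = (1 - minf) / tau)
    },
    hT = function(v) list(alpha = 0.02 / (1 + exp((v + 78) / 4)),
                          beta = 0.02 / (1 + exp(-(v + 78) / 4))),
    dT = function(v) list(alpha = 0.004 / (1 + exp(-(v + 65) / 5)),
                          beta = 0.001 / (1 + exp((v + 85) / 5)))
  )
}

# Calcium-pool and Nernst constants of the RGC model (documented component;
# concentrations in mM, times in ms).
ca_constants <- function(soma_diameter = 26) {
  r_m <- soma_diameter / 2 * 1e-6                 # soma radius (m)
  vol_l <- 4 / 3 * pi * r_m^3 * 1e3               # soma volume (litres)
  list(
    k_in = 1e-15 / (2 * 96485) / vol_l,  # mM per pA per ms (influx, z = 2)
    tau = 50,                            # pool decay time constant (ms)
    ca_rest = 1e-4,                      # resting internal Ca (mM)
    ca_diss = 1e-3,                      # KCa half-activation (mM)
    ca_out = 1.8,                        # external Ca (mM)
    rt_2f = 12.7                         # RT/2F at ~22 C (mV)
  )
}

#' Tabulate the gating rates on a voltage grid
#'
#' @param v Voltage grid (mV).
#' @return Matrix with columns `<gate>_alpha`, `<gate>_beta` (ms^-1) for
#'   the ten gates, one row per grid voltage.
#' @export
rgc_rate_table <- function(v = seq(-120, 60, by = 0.05)) {
  fns <- rgc_rate_functions()
  cols <- lapply(fns, function(f) {
    ab <- f(v)
    cbind(ab$alpha, ab$beta)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(t(outer(names(fns), c("alpha", "beta"),
                                     paste, sep = "_")))
  attr(out, "v") <- v
  out
}

#' Steady-state gating variables at a fixed voltage
#'
#' First-order gates settle at `alpha / (alpha + beta)`; the coupled
#' T-type inactivation pair settles at the fixed point of its two-state
#' kinetics.  Used to initialize simulations at rest.
#'
#' @param v Membrane potential (mV), scalar.
#' @param ca Internal calcium (mM) used for the KCa gate.
#' @return Named list of gating values plus `Ca_i` and `m_KCa`.
#' @export
gating_steady_state <- function(v, ca = ca_constants()$ca_rest) {
  fns <- rgc_rate_functions()
  g <- lapply(fns[c("m", "h", "c", "n", "mA", "hA", "nh", "mT")], function(f) {
    ab <- f(v)
    ab$alpha / (ab$alpha + ab$beta)
  })
  ab_h <- fns$hT(v); ab_d <- fns$dT(v)
  rh <- ab_h$alpha / ab_h$beta
  rd <- ab_d$alpha / ab_d$beta
  z <- 1 / (1 + rh + rd)
  cc <- ca_constants()
  c(g, list(hT = rh * z, dT = rd * z, Ca_i = ca,
            m_KCa = (ca / cc$ca_diss)^2 / (1 + (ca / cc$ca_diss)^2)))
}

# Surface area of a spherical soma (cm^2), pi * d^2.
soma_area_cm2 <- function(diameter_um) pi * (diameter_um * 1e-4)^2

# Convert a conductance density (mS cm^-2) to nS for a soma diameter (um).
density_to_nS <- function(g_density, diameter_um = 26) {
  g_density * soma_area_cm2(diameter_um) * 1e6
}

#' Total ionic current of an RGC soma
#'
#' Sum of the eight ionic current densities (Na, Ca, K, KA, KCa, h, CaT,
#' leak) with their gating exponents, times the soma surface area.  The Ca
#' reversal potential is computed from the internal calcium concentration
#' by the Nernst relation.
#'
#' @param v_m Membrane potential (mV).
#' @param gating Named list as returned by [gating_steady_state()]
#'   (`m, h, c, n, mA, hA, nh, mT, hT, dT, Ca_i, m_KCa`).
#' @param params RGC parameter list from [default_membrane_params()].
#' @return Current (pA); positive values depolarize.
#' @export
rgc_ionic_current <- function(v_m, gating, params) {
  if (gating$Ca_i <= 0) stop("internal calcium concentration must be > 0")
  cc <- ca_constants(params$soma_diameter)
  e_ca <- cc$rt_2f * log(cc$ca_out / gating$Ca_i)
  gs <- function(dens) density_to_nS(dens, params$soma_diameter)
  with(gating, {
    -(gs(params$G_Na) * m^3 * h * (v_m - params$E_Na) +
      gs(params$G_Ca) * c^3 * (v_m - e_ca) +
      gs(params$G_K) * n^4 * (v_m - params$E_K) +
      gs(params$G_KA) * mA^3 * hA * (v_m - params$E_K) +
      gs(params$G_KCa) * m_KCa * (v_m - params$E_K) +
      gs(params$G_h) * nh * (v_m - params$E_h) +
      gs(params$G_CaT) * mT^3 * hT * (v_m - e_ca) +
      gs(params$G_m) * (v_m - params$E_rest))
  })
}

#' Advance the gating state one time step (reference implementation)
#'
#' Exponential (Rush-Larsen) updates for the first-order gates, forward
#' Euler for the coupled T-type inactivation pair and the calcium pool.
#' This mirrors the compiled engine and is used as its cross-check.
#'
#' @param gating Gating state list (see [gating_steady_state()]).
#' @param v_m Membrane potential (mV) held during the step.
#' @param dt Time step (ms), > 0.
#' @param i_ca Total calcium current (pA) feeding the internal pool
#'   (positive = influx); default 0.
#' @param soma_diameter Soma diameter (um).
#' @return Updated gating state list.
#' @export
gating_step <- function(gating, v_m, dt, i_ca = 0, soma_diameter = 26) {
  stopifnot(dt > 0)
  fns <- rgc_rate_functions()
  g <- gating
  for (nm in c("m", "h", "c", "n", "mA", "hA", "nh", "mT")) {
    ab <- fns[[nm]](v_m)
    xinf <- ab$alpha / (ab$alpha + ab$beta)
    g[[nm]] <- xinf + (g[[nm]] - xinf) * exp(-dt * (ab$alpha + ab$beta))
    g[[nm]] <- min(max(g[[nm]], 0), 1)
  }
  ab_h <- fns$hT(v_m); ab_d <- fns$dT(v_m)
  z <- 1 - g$hT - g$dT
  hT <- g$hT + dt * (ab_h$alpha * z - ab_h$beta * g$hT)
  dT <- g$dT + dt * (ab_d$alpha * z - ab_d$beta * g$dT)
  g$hT <- min(max(hT, 0), 1)
  g$dT <- min(max(dT, 0), 1)
  cc <- ca_constants(soma_diameter)
  ca <- g$Ca_i + dt * (cc$k_in * max(i_ca, 0) -
                       (g$Ca_i - cc$ca_rest) / cc$tau)
  g$Ca_i <- max(ca, 1e-9)
  g$m_KCa <- (g$Ca_i / cc$ca_diss)^2 / (1 + (g$Ca_i / cc$ca_diss)^2)
  g
}

#' One voltage step of a leaky-integrator membrane (reference)
#'
#' Forward-Euler update of `C_m dv/dt = i_syn + i_ext + i_leak (+ i_light)`
#' used by the graded cell types; with constant inputs this tracks the
#' closed-form RC relaxation `v_inf + (v_0 - v_inf) exp(-t / tau)`,
#' `tau = C_m / G_m`, to well under 0.1 % at the default step.
#'
#' @param v_m Membrane potential(s) (mV).
#' @param params Leaky-integrator parameter list (`C_m`, `G_m`, `E_rest`).
#' @param dt Time step (ms).
#' @param i_in Additional input current (pA): synaptic + external + light.
#' @return Updated membrane potential(s) (mV).
#' @export
membrane_step <- function(v_m, params, dt, i_in = 0) {
  if (any(!is.finite(v_m))) stop("non-finite membrane state")
  v_m + dt / params$C_m *
    (leak_current(v_m, params$G_m, params$E_rest) + i_in)
}
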