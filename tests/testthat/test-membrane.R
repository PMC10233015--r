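test_that("leak current follows the ohmic battery", {
  expect_equal(leak_current(-50, 4, -50), 0)
  # cone parameters, 10 mV above rest
  expect_equal(leak_current(-40, 4, -50), -40)
  expect_equal(leak_current(-30, 4, -50), 2 * leak_current(-40, 4, -50))
})

test_that("light conductance closes with light", {
  expect_equal(light_conductance(1, 0.9), 0)
  expect_equal(light_conductance(0, 0.9), 0.9)
  expect_equal(light_conductance(0.5, 0.9), 0.45)
  expect_error(light_conductance(1.2, 0.9), "\\[0, 1\\]")
})

test_that("first-order gates settle at alpha / (alpha + beta)", {
  fns <- rgc_rate_functions()
  for (v in c(-80, -60, -40)) {
    g <- gating_steady_state(v)
    for (nm in c("m", "h", "c", "n", "mA", "hA", "nh", "mT")) {
      ab <- fns[[nm]](v)
      expect_equal(g[[nm]], ab$alpha / (ab$alpha + ab$beta), tolerance = 1e-12)
    }
    # relaxation from a perturbed state converges to the fixed point
    # (long horizon: the h-current gate has tau ~ 1 s at -80 mV)
    gg <- gating_steady_state(-70)
    for (i in 1:20000) gg <- gating_step(gg, v, dt = 0.5)
    for (nm in c("m", "h", "n", "nh"))
      expect_equal(gg[[nm]], g[[nm]], tolerance = 2e-3)
  }
})

test_that("T-type inactivation pair stays in the simplex", {
  set.seed(1)
  g <- gating_steady_state(-65)
  vs <- runif(5000, -90, 10)
  for (v in vs) {
    g <- gating_step(g, v, dt = 0.1)
    expect_true(g$hT >= 0 && g$dT >= 0 && g$hT + g$dT <= 1 + 1e-12)
  }
})

test_that("ionic current reduces correctly in single-channel limits", {
  p <- default_membrane_params()$RGC_ON
  # all channels zero except leak, at rest
  p0 <- p
  for (nm in c("G_Na", "G_K", "G_KA", "G_Ca", "G_KCa", "G_h", "G_CaT"))
    p0[[nm]] <- 0
  g <- gating_steady_state(p$E_rest)
  expect_equal(rgc_ionic_current(p$E_rest, g, p0), 0, tolerance = 1e-12)
  # sodium-only reduction with m = h = 1
  p_na <- p0; p_na$G_Na <- p$G_Na; p_na$G_m <- 0
  g1 <- g; g1$m <- 1; g1$h <- 1
  a_cm2 <- pi * (26e-4)^2
  expect_equal(rgc_ionic_current(-40, g1, p_na),
               -p$G_Na * a_cm2 * 1e6 * (-40 - p$E_Na), tolerance = 1e-9)
  expect_error(rgc_ionic_current(-40, modifyList(g, list(Ca_i = -1)), p),
               "calcium")
})

test_that("gating_step matches forward Euler as dt -> 0", {
  g0 <- gating_steady_state(-65)
  v <- -40
  fns <- rgc_rate_functions()
  # one exponential step vs many tiny steps (Richardson-style comparison)
  g_big <- gating_step(g0, v, dt = 0.1)
  g_small <- g0
  for (i in 1:100) g_small <- gating_step(g_small, v, dt = 0.001)
  for (nm in c("m", "h", "n", "mT"))
    expect_equal(g_big[[nm]], g_small[[nm]], tolerance = 1e-3)
})

test_that("leaky membrane tracks the closed-form RC solution", {
  # single horizontal cell, constant injected current, engine integration
  net <- single_cell_net("HRZ")
  p <- default_membrane_params()$HRZ
  inj <- 50
  sim <- run_simulation(net, config = sim_config(duration = 400, seed = 1,
                                                 record = 1,
                                                 trace_dt = 0.025,
                                                 init_sd = 0),
                        i_const = data.frame(id = 1, pa = inj))
  tau <- p$C_m / p$G_m
  v_inf <- p$E_rest + inj / p$G_m
  tt <- sim$trace_t
  analytic <- v_inf + (p$E_rest - v_inf) * exp(-tt / tau)
  rel_err <- max(abs(sim$traces[1, ] - analytic)) / abs(v_inf - p$E_rest)
  expect_lt(rel_err, 0.001)
})

test_that("cone membrane time constant is C_m / G_m = 20 ms", {
  net <- single_cell_net("PR")
  inj <- 40
  sim <- run_simulation(net, config = sim_config(duration = 200, seed = 1,
                                                 record = 1, trace_dt = 0.1,
                                                 init_sd = 0),
                        i_const = data.frame(id = 1, pa = inj))
  v0 <- -50; v_inf <- -50 + inj / 4
  # 63 % rise time
  idx <- which(sim$traces[1, ] >= v0 + 0.632 * (v_inf - v0))[1]
  expect_equal(sim$trace_t[idx], 20, tolerance = 0.05)
})

test_that("isolated RGC F-I curves are non-decreasing with full spikes", {
  for (cls in rgc_types()) {
    net <- single_cell_net(cls)
    rates <- vapply(c(0, 30, 80, 160), function(a) {
      sim <- run_simulation(net, config = sim_config(duration = 1200,
                                                     seed = 1),
                            i_const = data.frame(id = 1, pa = a))
      sum(sim$spikes$t_ms > 200) / 1
    }, 0)
    expect_true(all(diff(rates) >= 0))
    expect_gt(max(rates), 0)
  }
})
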