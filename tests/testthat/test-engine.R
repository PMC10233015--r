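test_that("runs are deterministic given network, stimuli and seed", {
  net <- tiny_net()
  cfg <- sim_config(duration = 800, seed = 11)
  a <- run_simulation(net, light_full_field(0.5), config = cfg)
  b <- run_simulation(net, light_full_field(0.5), config = cfg)
  expect_identical(a$spikes, b$spikes)
  c2 <- run_simulation(net, light_full_field(0.5),
                       config = sim_config(duration = 800, seed = 12))
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("only RGCs emit spikes", {
  net <- tiny_net()
  sim <- run_simulation(net, light_disk(onset_ms = 300),
                        config = sim_config(duration = 700, seed = 1))
  expect_true(all(sim$spikes$cell_type %in% rgc_types()))
})

test_that("spike times are strictly increasing with the 1 ms lockout", {
  net <- tiny_net()
  sim <- run_simulation(net, light_full_field(0.5),
                        config = sim_config(duration = 1500, seed = 1))
  for (tt in split(sim$spikes$t_ms, sim$spikes$id))
    if (length(tt) > 1) expect_true(all(diff(tt) >= 1 - 1e-9))
})

test_that("with synapses disabled and no stimulus, cells relax to rest", {
  # graded types only, no connectome: pure leak decay from randomized start
  specs <- default_mosaic_specs()[c("HRZ", "BP_ON", "AMA_ON_WF")]
  lay <- build_layout(specs, patch = c(80, 80), seed = 2)
  con <- build_connectome(lay, default_synapse_specs()[0, ])
  net <- build_network(lay, con)
  sim <- run_simulation(net, config = sim_config(duration = 600, seed = 2,
                                                 record = "all",
                                                 trace_dt = 10))
  mem <- default_membrane_params()
  for (ct in names(specs)) {
    ids <- as.character(lay$cells$id[lay$cells$cell_type == ct])
    final <- sim$traces[ids, ncol(sim$traces)]
    expect_equal(unname(final), rep(mem[[ct]]$E_rest, length(ids)),
                 tolerance = 1e-4)
    # monotone approach: |v - E_rest| never increases
    dev <- abs(sim$traces[ids, , drop = FALSE] - mem[[ct]]$E_rest)
    expect_true(all(diff(t(dev)) <= 1e-9))
  }
})

test_that("snapshot shows the layered light response", {
  net <- tiny_net()
  onset <- 500
  sim <- run_simulation(net, light_disk(radius = 40, onset_ms = onset),
                        config = sim_config(duration = onset + 130, seed = 1,
                                            record = "all", trace_dt = 2))
  snap <- snapshot(sim, onset + 110)
  r <- sqrt(snap$x^2 + snap$y^2)
  pr_in <- snap$v_m[snap$cell_type == "PR" & r <= 30]
  pr_out <- snap$v_m[snap$cell_type == "PR" & r > 45]
  # photoreceptors under the bright disk hyperpolarize
  expect_lt(mean(pr_in), mean(pr_out) - 1)
  mem <- default_membrane_params()
  bp_on <- snap$v_m[snap$cell_type == "BP_ON" & r <= 30]
  bp_off <- snap$v_m[snap$cell_type == "BP_OFF" & r <= 30]
  expect_gt(mean(bp_on), mem$BP_ON$E_rest)      # ON bipolars depolarized
  pre <- snapshot(sim, onset - 20)
  bp_off_pre <- pre$v_m[pre$cell_type == "BP_OFF" & r <= 30]
  expect_lt(mean(bp_off), mean(bp_off_pre))     # OFF bipolars hyperpolarized
  expect_error(snapshot(sim, 1e5), "outside")
})

test_that("synaptic-update stride at the default grid is converged", {
  net <- tiny_net()
  a <- run_simulation(net, light_full_field(0.5),
                      config = sim_config(duration = 1000, seed = 3,
                                          syn_update_ms = 0.25))
  b <- run_simulation(net, light_full_field(0.5),
                      config = sim_config(duration = 1000, seed = 3,
                                          syn_update_ms = 0.125))
  ra <- nrow(a$spikes); rb <- nrow(b$spikes)
  expect_lte(abs(ra - rb) / max(rb, 1), 0.02)
})

test_that("spikes can be written out and re-analyzed", {
  net <- tiny_net()
  sim <- run_simulation(net, light_full_field(0.5),
                        config = sim_config(duration = 800, seed = 1))
  p <- file.path(tempdir(), "spikes.csv")
  write_spikes(sim, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), nrow(sim$spikes))
  r1 <- spontaneous_rate(sim, window = c(200, 800))
  r2 <- spontaneous_rate(back, window = c(200, 800), cells = sim$cells)
  expect_equal(r1$mean_hz, r2$mean_hz)
})
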