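test_that("spatial weights are normalized exponential-decay pools", {
  w <- spatial_weights(c(0, 0), matrix(c(5, 0), 1), sigma = 6)
  expect_equal(w, 1)
  # two cells at distances d and d + sigma have weight ratio e
  pre <- rbind(c(4, 0), c(4 + 6, 0))
  w2 <- spatial_weights(c(0, 0), pre, sigma = 6, cutoff = 50)
  expect_equal(w2[1] / w2[2], exp(1), tolerance = 1e-9)
  set.seed(2)
  pre_r <- matrix(runif(40, -10, 10), ncol = 2)
  expect_equal(sum(spatial_weights(c(0, 0), pre_r, sigma = 6)), 1)
  expect_warning(w0 <- spatial_weights(c(0, 0), matrix(c(100, 0), 1), 2.5),
                 "orphan")
  expect_equal(w0, 0)
})

test_that("graded transmission sigmoid hits its anchor points", {
  specs <- default_synapse_specs()
  for (k in seq_len(nrow(specs))) {
    sp <- as.list(specs[k, ])
    expect_equal(presyn_conductance(sp$V50, sp),
                 (sp$G_min + sp$G_max) / 2, tolerance = 1e-12)
    hi <- presyn_conductance(200, sp); lo <- presyn_conductance(-200, sp)
    if (sp$kind == "I") {
      expect_equal(hi, sp$G_max, tolerance = 1e-6)
      expect_equal(lo, sp$G_min, tolerance = 1e-6)
    } else {
      expect_equal(hi, sp$G_min, tolerance = 1e-6)
      expect_equal(lo, sp$G_max, tolerance = 1e-6)
    }
    # bounded and monotone over the physiological range
    g <- presyn_conductance(seq(-90, 0, by = 1), sp)
    expect_true(all(g >= sp$G_min - 1e-9 & g <= sp$G_max + 1e-9))
    expect_true(all(diff(g) >= 0) || all(diff(g) <= 0))
  }
  # cone -> ON bipolar is sign-inverting with a 0.1 nS floor
  pr_bpon <- as.list(specs[specs$projection == "PR->BP_ON", ])
  expect_equal(presyn_conductance(1e3, pr_bpon), 0.1, tolerance = 1e-9)
})

test_that("synaptic current is ohmic toward its reversal", {
  expect_equal(synaptic_current(0, -50, 0), 0)
  expect_equal(synaptic_current(1.5, -70, -70), 0)
  # wide-field ON amacrine onto ON RGC is inhibitory at rest
  expect_lt(synaptic_current(2, -66.5, -70), 0)
  expect_error(synaptic_current(-1, -50, 0), "g_syn")
})

test_that("the wiring contains exactly the twelve typed projections", {
  net <- tiny_net()
  sets <- net$connectome$sets
  expect_length(sets, 12)
  expect_setequal(names(sets), default_synapse_specs()$projection)
  # no RGC efferents
  pres <- vapply(sets, function(s) s$spec$pre, "")
  expect_false(any(pres %in% rgc_types()))
  # every OFF RGC pools from its three afferent projections
  off_ids <- net$layout$cells$id[net$layout$cells$cell_type == "RGC_OFF"]
  for (proj in c("BP_OFF->RGC_OFF", "AMA_OFF_WF->RGC_OFF",
                 "AMA_ON_NF->RGC_OFF")) {
    s <- sets[[proj]]
    n_in <- diff(s$ptr)[match(off_ids, s$post_id)]
    expect_true(all(n_in > 0))
  }
})

test_that("healthy pooling weights sum to one per postsynaptic cell", {
  net <- tiny_net()
  for (s in net$connectome$sets) {
    sums <- vapply(seq_along(s$post_id), function(i)
      if (s$ptr[i + 1] > s$ptr[i]) sum(s$w[(s$ptr[i] + 1):s$ptr[i + 1]])
      else NA_real_, 0)
    expect_equal(sums[!is.na(sums)], rep(1, sum(!is.na(sums))),
                 tolerance = 1e-12)
  }
})

test_that("removing all cones leaves downstream wiring intact", {
  net <- tiny_net()
  d <- end_phase12(net)
  sets <- d$connectome$sets
  # cone-driven pools are empty of edges
  expect_equal(length(sets[["PR->BP_ON"]]$w), 0)
  # inner projections keep their healthy weights and delays
  s0 <- net$connectome$sets[["BP_ON->RGC_ON"]]
  s1 <- sets[["BP_ON->RGC_ON"]]
  expect_identical(s1$w, s0$w)
  expect_identical(s1$spec$tau, s0$spec$tau)
})

test_that("edge export matches the compressed representation", {
  net <- tiny_net()
  edges <- connectome_edges(net$connectome)
  expect_named(edges, c("pre_id", "post_id", "projection", "weight"))
  n_per_set <- vapply(net$connectome$sets, function(s) length(s$w), 0)
  expect_equal(nrow(edges), sum(n_per_set))
  expect_true(all(edges$weight > 0))
})

test_that("missing populations are a configuration error", {
  lay <- build_layout(default_mosaic_specs()["PR"], patch = c(60, 60))
  expect_error(build_connectome(lay), "missing population")
})
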