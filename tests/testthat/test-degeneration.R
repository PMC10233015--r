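test_that("stage descriptors validate and derive their quantities", {
  st <- degeneration_state(0.4, 0)
  expect_equal(st$cone_survival, 0.6)
  expect_equal(st$G_light_scale, 0.6)
  expect_error(degeneration_state(1.2, 0), "\\[0, 1\\]")
  expect_error(degeneration_state(0.5, 0.3), "Phase III")
  expect_equal(progression_schedule(0)$s, 0)
  expect_equal(progression_schedule(1), degeneration_state(1, 0))
  expect_equal(progression_schedule(1.5)$migration_fraction, 0.25)
  expect_error(progression_schedule(2.5), "\\[0, 2\\]")
})

test_that("cone death removes exactly round(s * N) cones and scales G_light", {
  net <- tiny_net()
  n0 <- sum(net$layout$cells$cell_type == "PR")
  d0 <- apply_phase12(net, 0)
  expect_identical(d0$layout$cells, net$layout$cells)
  d5 <- apply_phase12(net, 0.5)
  expect_equal(sum(d5$layout$cells$cell_type == "PR"), n0 - round(0.5 * n0))
  expect_equal(d5$glight_scale, 0.5)
  # monotone in s
  counts <- vapply(c(0, 0.3, 0.6, 0.9), function(s)
    sum(apply_phase12(net, s)$layout$cells$cell_type == "PR"), 0)
  expect_true(all(diff(counts) <= 0))
  expect_error(apply_phase12(net, 1.5), "\\[0, 1\\]")
})

test_that("death sets are nested and cumulative application matches", {
  net <- tiny_net()
  ids3 <- apply_phase12(net, 0.3)$layout$cells$id
  ids6 <- apply_phase12(net, 0.6)$layout$cells$id
  expect_true(all(ids6 %in% ids3))
  cumulative <- apply_phase12(apply_phase12(net, 0.3), 0.6)
  expect_identical(sort(cumulative$layout$cells$id), sort(ids6))
})

test_that("end of Phase I/II removes all outer-retina cells, idempotently", {
  net <- tiny_net()
  d <- end_phase12(net)
  cen <- layout_census(d$layout)
  expect_equal(unname(cen[c("PR", "HRZ")]), c(0L, 0L))
  cen0 <- layout_census(net$layout)
  inner <- setdiff(cell_types(), c("PR", "HRZ"))
  expect_equal(cen[inner], cen0[inner])
  expect_identical(layout_census(end_phase12(d)$layout), cen)
})

test_that("Phase III reduces inner populations and migrates survivors", {
  net <- sweep_net()
  expect_error(apply_phase3(net, 0.5), "Phase I/II")
  base <- end_phase12(net)
  expect_identical(apply_phase3(base, 0)$layout$cells, base$layout$cells)
  d1 <- apply_phase3(base, 1)
  cen <- layout_census(d1$layout)
  expect_true(all(cen[c("BP_ON", "BP_OFF", "AMA_ON_WF", "AMA_OFF_WF",
                        "AMA_ON_NF")] == 0))
  # RGC count constant across the whole course
  expect_equal(sum(cen[rgc_types()]),
               sum(layout_census(net$layout)[rgc_types()]))
  d5 <- apply_phase3(base, 0.5)
  cells0 <- base$layout$cells
  cells5 <- d5$layout$cells
  rules <- migration_rules()
  for (ct in c("BP_ON", "AMA_ON_NF", "RGC_ON")) {
    sel5 <- cells5[cells5$cell_type == ct, ]
    m <- match(sel5$id, cells0$id)
    moved <- abs(sel5$z - cells0$z[m]) > 1e-12
    # migration fraction 0.5 * t of survivors, exact under rank selection
    expect_equal(sum(moved), round(0.25 * nrow(sel5)))
    # x, y never change
    expect_equal(sel5$x, cells0$x[m])
    expect_equal(sel5$y, cells0$y[m])
    # destinations lie in the permitted bands
    bands <- rules[[retisim:::.migration_class(ct)]]
    in_band <- vapply(sel5$z[moved], function(z)
      any(z >= bands[, "z_min"] & z <= bands[, "z_max"]), TRUE)
    expect_true(all(in_band))
  }
  # amacrine destinations split in thirds (multinomial check on the
  # migrant counts)
  ama5 <- cells5[grepl("^AMA", cells5$cell_type), ]
  m <- match(ama5$id, cells0$id)
  moved <- ama5[abs(ama5$z - cells0$z[m]) > 1e-12, ]
  counts <- c(sum(moved$z >= 100), sum(moved$z >= 40 & moved$z <= 80),
              sum(moved$z <= 39))
  expect_equal(sum(counts), nrow(moved))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("migration leaves weights and delays untouched", {
  net <- tiny_net()
  base <- end_phase12(net)
  d <- apply_phase3(base, 0.4)
  s0 <- base$connectome$sets[["BP_ON->RGC_ON"]]
  s1 <- d$connectome$sets[["BP_ON->RGC_ON"]]
  # restrict healthy set to surviving pre/post cells: weights identical
  alive <- d$layout$cells$id
  keep_post <- s0$post_id %in% alive
  expect_identical(s1$post_id, s0$post_id[keep_post])
  expect_identical(s1$spec$tau, s0$spec$tau)
  # weights of surviving edges are the healthy values (fixed normalizer)
  e0 <- connectome_edges(base$connectome)
  e1 <- connectome_edges(d$connectome)
  e0 <- e0[e0$projection == "BP_ON->RGC_ON" & e0$pre_id %in% alive &
             e0$post_id %in% alive, ]
  e1 <- e1[e1$projection == "BP_ON->RGC_ON", ]
  expect_equal(e1$weight, e0$weight)
})

test_that("a degeneration stage is reproducible from (s, t, seed)", {
  net <- tiny_net()
  a <- degenerate(net, s = 1, t = 0.6, seed = 5)
  b <- degenerate(net, s = 1, t = 0.6, seed = 5)
  expect_identical(a$layout$cells, b$layout$cells)
  c2 <- degenerate(net, s = 1, t = 0.6, seed = 6)
  expect_false(identical(a$layout$cells$z, c2$layout$cells$z))
})
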