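# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Reduced 100 x 100 um patch network used by most simulation tests.
tiny_net <- function() cached("tiny_net", function() make_fixture(1 / 3, seed = 1))

# Network containing a single cell of one type (no synapses).
single_cell_net <- function(cell_type, membrane = default_membrane_params()) {
  cached(paste0("single_", cell_type), function() {
    spec <- list(mosaic_spec(cell_type, 200, 30, 30,
                             if (cell_type == "PR") 4 else 2))
    names(spec) <- cell_type
    lay <- build_layout(spec, patch = c(100, 100), seed = 1)
    con <- build_connectome(lay, default_synapse_specs()[0, ])
    build_network(lay, con, membrane = membrane)
  })
}

# Full default-patch layout (geometry only; no connectome).
full_layout <- function() cached("full_layout", function() build_layout(seed = 1))

# Full default network (layout + connectome); used by the acceptance tests.
full_net <- function() cached("full_net", function()
  suppressWarnings(build_network(full_layout())))

# 150 um patch for degeneration sweeps.
sweep_net <- function() cached("sweep_net", function() make_fixture(0.5, seed = 1))

rgc_rates <- function(sim, window = NULL) {
  r <- spontaneous_rate(sim, window = window)
  stats::setNames(r$by_class$mean, r$by_class$cell_type)
}
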