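# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# 960-facet 3-layer phantom with electrodes and a cached lead-field context
fix_model3 <- function() fixture("model3", function() {
  m3 <- build_phantom_3(n_subdiv = 2)
  el <- project_to_skin(fibonacci_layout(128, 0.65), m3$interfaces[[1]])
  list(model = m3, electrodes = el, lfc = lead_field_context(m3, el))
})

# coarse single-sphere homogeneous model
fix_sphere1 <- function() fixture("sphere1", function() {
  mesh <- icosphere(0.09, 3)
  list(mesh = mesh,
       model = head_model(list(mesh), sigma_in = 0.33, sigma_out = 0,
                          refinable = FALSE, tissue = "skin"),
       sigma = 0.33, radius = 0.09)
})

# random-geometry small facet cloud for operator/backend checks
fix_cloud <- function(n = 500L, seed = 42L) {
  set.seed(seed)
  mesh <- icosphere(0.05, 2)                     # 320 facets
  extra <- icosphere(0.03, 1, center = c(0.005, -0.002, 0.001))  # 80 facets
  list(mesh, extra)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected)), tol)
}
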