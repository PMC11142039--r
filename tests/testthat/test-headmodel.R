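test_that("conductivity contrast matches its definition and edge cases", {
  expect_equal(contrast(0.33, 0.33), 0)
  expect_equal(contrast(0.33, 0), 1)
  # VWB skull inside skin
  expect_equal(contrast(0.010, 0.430), (0.010 - 0.430) / (0.010 + 0.430))
  expect_error(contrast(-1, 0.2), "sigma_in")
  expect_error(contrast(0.2, -0.1), "sigma_out")
})

test_that("shipped conductivity presets carry the published tissue values", {
  it7 <- conductivity_set("IT'IS7")
  expect_equal(as.numeric(it7[c("skin", "skull", "csf", "gm", "wm")]),
               c(0.147, 0.0179, 1.880, 0.419, 0.348))
  vwb7 <- conductivity_set("VWB7")
  expect_equal(as.numeric(vwb7[c("skin", "skull", "csf", "gm", "wm")]),
               c(0.430, 0.010, 1.790, 0.330, 0.140))
  sn7 <- conductivity_set("SimNIBS7")
  expect_equal(as.numeric(sn7[c("skin", "skull", "csf", "gm", "wm")]),
               c(0.465, 0.010, 1.654, 0.275, 0.126))
  # 3-layer class: BRAIN row and the VWB skin/skull pair
  expect_equal(conductivity_set("ITIS3")[["brain"]], 0.375)
  expect_equal(conductivity_set("VWB3")[["brain"]], 0.330)
  expect_equal(conductivity_set("SimNIBS3")[["brain"]], 0.330)
  vwb3 <- conductivity_set("VWB3")
  expect_equal(as.numeric(vwb3[c("skin", "skull")]), c(0.430, 0.010))
  expect_error(conductivity_set("nope"), "unknown")
})

test_that("5-layer phantom wires contrasts, counts and refinability", {
  m5 <- build_phantom_5(n_subdiv = 2)
  expect_equal(facet_counts(m5), rep(320L, 5))
  expect_equal(m5$K[1], 1)                        # skin against air
  it7 <- conductivity_set("ITIS7")
  expect_equal(m5$K[4], (0.419 - 1.880) / (0.419 + 1.880))  # GM inside CSF
  expect_false(m5$refinable[1])
  expect_true(all(m5$refinable[-1]))
  m3sub <- build_phantom_5(n_subdiv = 3)
  expect_equal(facet_counts(m3sub), rep(1280L, 5))
  expect_error(build_phantom_5(radii_mm = c(92, 86, 90, 78, 70)), "decreasing")
})

test_that("uniform conductivity collapses interior contrasts to zero", {
  flat <- structure(setNames(rep(0.3, 5), c("skin", "skull", "csf", "gm", "wm")),
                    name = "FLAT", class = "conductivity_set")
  m <- build_phantom_5(conductivities = flat, n_subdiv = 2)
  expect_equal(m$K, c(1, 0, 0, 0, 0))
})

test_that("contrast is invariant under uniform conductivity scaling", {
  it7 <- conductivity_set("ITIS7")
  scaled <- structure(unclass(it7) * 3.7, name = "S", class = "conductivity_set")
  m1 <- build_phantom_5(conductivities = it7, n_subdiv = 2)
  m2 <- build_phantom_5(conductivities = scaled, n_subdiv = 2)
  expect_equal(m1$K, m2$K, tolerance = 1e-14)
  # at most (number of interfaces) distinct K values per phantom
  ctx_K <- rep(m1$K, facet_counts(m1))
  expect_lte(length(unique(ctx_K)), length(m1$interfaces))
})

test_that("nesting check accepts nested shells and reports violations", {
  good <- head_model(list(icosphere(2, 1), icosphere(1, 1)),
                     sigma_in = c(1, 2), sigma_out = c(0, 1))
  expect_true(nesting_check(good)$ok)
  # swapped order: construction must fail, and the raw check reports it
  bad <- good
  bad$interfaces <- rev(bad$interfaces)
  nc <- nesting_check(bad)
  expect_false(nc$ok)
  expect_match(nc$violation, "interface")
  expect_error(head_model(list(icosphere(1, 1), icosphere(2, 1)),
                          sigma_in = c(1, 2), sigma_out = c(0, 1)),
               "nested")
  # touching spheres (equal radii) are not strictly nested
  touch <- good
  touch$interfaces[[2]] <- icosphere(2, 1)
  expect_false(nesting_check(touch)$ok)
})

test_that("conductivity chain consistency is enforced", {
  expect_error(head_model(list(icosphere(2, 1), icosphere(1, 1)),
                          sigma_in = c(1, 2), sigma_out = c(0, 1.5)),
               "chain")
})

test_that("local_sigma resolves the containing compartment", {
  m5 <- build_phantom_5(n_subdiv = 2)
  it7 <- conductivity_set("ITIS7")
  pts <- rbind(c(0, 0, 0.074),    # between GM and WM -> gm
               c(0, 0, 0),        # center -> wm
               c(0, 0, 0.0885),   # between skull and skin -> skin
               c(0, 0, 0.2))      # outside
  expect_equal(local_sigma(m5, pts),
               c(it7[["gm"]], it7[["wm"]], it7[["skin"]], 0))
})
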