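test_that("dipole placement sits between GM and WM with the requested orientation", {
  m5 <- build_phantom_5(n_subdiv = 2)
  # GM 78 mm, WM 70 mm: halfway -> 74 mm
  dp <- place_dipole(m5, c(0, 0, 1), 0.5, "radial")
  expect_equal(sqrt(sum(dp$position^2)), 0.074, tolerance = 1e-9)
  # radial: moment parallel to the position direction, within the tilt of a
  # subdivision-2 facet normal (up to ~10 degrees)
  cosang <- sum(dp$moment * dp$position) /
    (sqrt(sum(dp$moment^2)) * sqrt(sum(dp$position^2)))
  expect_gt(cosang, cos(12 * pi / 180))
  # tangential: moment orthogonal to the nearest GM facet normal
  dpt <- place_dipole(m5, c(0, 0, 1), 0.5, "tangential")
  gm <- m5$interfaces[[4]]
  nearest <- which.min(rowSums(sweep(gm$centroid, 2, dpt$position)^2))
  expect_lt(abs(sum(dpt$moment * gm$normal[nearest, ])), 1e-12)
  # sigma_local is the GM conductivity
  expect_equal(dp$sigma_local, conductivity_set("ITIS7")[["gm"]])
  expect_error(place_dipole(m5, c(0, 0, 1), 1.2), "depth_fraction")
})

test_that("study config validates conductivity sets and records the seed", {
  cfg <- study_config(seed = 42)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$conductivity_sets, c("ITIS", "VWB", "SIMNIBS"))
  expect_error(study_config(conductivity_sets = "BOGUS"), "unknown")
  # YAML roundtrip
  path <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(conductivity_sets = list("ITIS"), n_variants = 2L,
                        seed = 9L), path)
  cfg2 <- read_study_config(path)
  expect_equal(cfg2$n_variants, 2L)
  expect_equal(cfg2$seed, 9L)
  yaml::write_yaml(list(bogus_key = 1), path)
  expect_error(read_study_config(path), "unknown config key")
})

test_that("degenerate config (no interior contrast) localizes to sub-mm error", {
  # 5-layer phantom whose csf/gm/wm all share the 3-layer BRAIN conductivity:
  # the two models are electromagnetically identical
  it3 <- conductivity_set("ITIS3")
  flat7 <- structure(setNames(c(it3[["skin"]], it3[["skull"]], rep(it3[["brain"]], 3)),
                              c("skin", "skull", "csf", "gm", "wm")),
                     name = "FLAT7", class = "conductivity_set")
  m5 <- build_phantom_5(conductivities = flat7, n_subdiv = 2)
  m3 <- build_phantom_3(n_subdiv = 2)
  el5 <- project_to_skin(fibonacci_layout(128, 0.65), m5$interfaces[[1]])
  el3 <- project_to_skin(fibonacci_layout(128, 0.65), m3$interfaces[[1]])
  dp <- place_dipole(m5, c(0.2, 0.1, 0.95), 0.5, "radial")
  V <- electrode_voltages(solve_charges(m5, dp), el5)
  fit <- fit_dipole(V, m3, el3, strategy = "truth", true_position = dp$position)
  err <- error_metrics(dp, fit)
  expect_lt(err$distance_mm, 1)
})

test_that("study reports roundtrip to disk with their manifest", {
  cfg <- study_config(conductivity_sets = "ITIS",
                      dipoles = canonical_dipoles()[c(1, 4)],
                      n_variants = 1L,
                      n_subdiv_5 = 2L, n_subdiv_3 = 1L,
                      n_electrodes = 64L, amr_max_steps = 2L,
                      fit_max_evals = 120L, seed = 11L)
  r1 <- suppressWarnings(run_study(cfg))
  dir <- tempfile()
  write_study_report(r1, dir)
  expect_true(file.exists(file.path(dir, "cells.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.yml")))
  tab <- utils::read.delim(file.path(dir, "cells.tsv"))
  expect_equal(nrow(tab), nrow(r1$cells))
  expect_true(all(tab$seed == 11L))
})

test_that("study aggregates are coherent with their cells", {
  cfg <- study_config(conductivity_sets = "VWB",
                      dipoles = canonical_dipoles()[c(1, 4)],
                      n_variants = 1L, n_subdiv_5 = 2L, n_subdiv_3 = 1L,
                      n_electrodes = 64L, amr_max_steps = 2L,
                      fit_max_evals = 120L, seed = 3L)
  rep <- suppressWarnings(run_study(cfg))
  # matched conductivity pairing: every cell used the requested set
  expect_true(all(rep$cells$set == "VWB"))
  ag <- rep$aggregates
  expect_true(all(is.na(ag$mm_sd) | ag$mm_sd >= 0))
  for (i in seq_len(nrow(ag))) {
    sub <- rep$cells[rep$cells$dipole == ag$dipole[i] &
                       rep$cells$condition == ag$condition[i], ]
    expect_gte(ag$mm_mean[i], min(sub$distance_mm) - 1e-12)
    expect_lte(ag$mm_mean[i], max(sub$distance_mm) + 1e-12)
  }
})

test_that("3-layer model self-comparison achieves near-exact recovery without AMR", {
  cfg <- study_config(conductivity_sets = "ITIS",
                      dipoles = canonical_dipoles()[2],
                      n_variants = 1L, n_subdiv_3 = 2L,
                      n_electrodes = 128L, amr_max_steps = 4L,
                      fit_max_evals = 400L, seed = 2L)
  rep <- suppressWarnings(model_comparison_3layer(cfg))
  noamr <- rep$cells[rep$cells$condition == "noamr", ]
  # identical forward/inverse discretization: machine-precision recovery
  expect_lt(max(noamr$distance_mm), 0.05)
  expect_lt(max(noamr$angle_deg), 0.05)
  amr <- rep$cells[rep$cells$condition == "amr", ]
  # AMR-forward vs non-AMR inverse: small but nonzero model discrepancy
  expect_lt(max(amr$distance_mm), 5)
})
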