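test_that("impressed dipole field and potential match the closed form", {
  sig <- 0.4
  q <- 2e-8
  dp <- dipole(c(0, 0, 0), c(0, 0, q), sigma_local = sig)
  d <- c(0.01, 0.02, 0.04)
  # on-axis: phi = q/(4 pi sigma d^2), |E| = 2 q/(4 pi sigma d^3)
  pts <- cbind(0, 0, d)
  expect_equal(impressed_potential(dp, pts), q / (4 * pi * sig * d^2),
               tolerance = 1e-12)
  E <- impressed_field(dp, pts)
  expect_equal(sqrt(rowSums(E^2)), 2 * q / (4 * pi * sig * d^3),
               tolerance = 1e-12)
  # d^-3 decay on axis: doubling the distance divides |E| by 8
  expect_equal(sqrt(sum(E[3, ]^2)) / sqrt(sum(E[1, ]^2)), (d[1] / d[3])^3,
               tolerance = 1e-12)
  # antisymmetry across the equatorial plane
  v <- c(0.013, -0.007, 0.011)
  expect_equal(impressed_potential(dp, rbind(v)),
               -impressed_potential(dp, rbind(c(v[1], v[2], -v[3]))),
               tolerance = 1e-14)
  expect_error(impressed_potential(dp, rbind(c(0, 0, 0))), "singular")
})

test_that("operator reduces to rho/2 at zero contrast and is linear", {
  meshes <- fix_cloud()
  model <- head_model(meshes, sigma_in = c(0.3, 0.3), sigma_out = c(0.3, 0.3),
                      refinable = c(TRUE, TRUE), check_nesting = FALSE)
  set.seed(1)
  rho <- rnorm(sum(facet_counts(model)))
  expect_equal(apply_operator(model, rho), rho / 2, tolerance = 1e-14)
  # zero in, zero out; linearity
  m2 <- head_model(meshes, sigma_in = c(0.1, 0.9), sigma_out = c(0.4, 0.1),
                   refinable = c(TRUE, TRUE), check_nesting = FALSE)
  expect_equal(apply_operator(m2, rho * 0), rho * 0)
  a <- apply_operator(m2, rho)
  b <- apply_operator(m2, rev(rho))
  expect_equal(apply_operator(m2, 2 * rho + 3 * rev(rho)), 2 * a + 3 * b,
               tolerance = 1e-12)
})

test_that("compiled and reference n-body backends agree to 1e-10", {
  meshes <- fix_cloud()
  model <- head_model(meshes, sigma_in = c(0.2, 1.5), sigma_out = c(0.05, 0.2),
                      refinable = c(TRUE, TRUE), check_nesting = FALSE)
  set.seed(7)
  for (rep in 1:3) {
    rho <- rnorm(sum(facet_counts(model)))
    a <- apply_operator(model, rho, backend = "compiled")
    b <- apply_operator(model, rho, backend = "reference")
    expect_lt(sqrt(sum((a - b)^2) / sum(a^2)), 1e-10)
  }
})

test_that("near-field analytic triangle integrals match quadrature", {
  # oracle: centroid point-sums over a finely subdivided source triangle
  quad <- function(r, v0, v1, v2, depth = 6) {
    tri <- list(rbind(v0, v1, v2))
    for (d in seq_len(depth)) {
      tri <- unlist(lapply(tri, function(t) {
        m12 <- (t[1, ] + t[2, ]) / 2; m23 <- (t[2, ] + t[3, ]) / 2
        m31 <- (t[3, ] + t[1, ]) / 2
        list(rbind(t[1, ], m12, m31), rbind(t[2, ], m23, m12),
             rbind(t[3, ], m31, m23), rbind(m12, m23, m31))
      }), recursive = FALSE)
    }
    I0 <- 0; g <- c(0, 0, 0)
    for (t in tri) {
      c3 <- colMeans(t)
      e1 <- t[2, ] - t[1, ]; e2 <- t[3, ] - t[1, ]
      a <- sqrt(sum(c(e1[2] * e2[3] - e1[3] * e2[2],
                      e1[3] * e2[1] - e1[1] * e2[3],
                      e1[1] * e2[2] - e1[2] * e2[1])^2)) / 2
      d <- r - c3; rr <- sqrt(sum(d^2))
      I0 <- I0 + a / rr
      g <- g + a * d / rr^3
    }
    list(I0 = I0, grad = g)
  }
  v0 <- c(0, 0, 0); v1 <- c(0.01, 0, 0); v2 <- c(0, 0.012, 0.002)
  for (r in list(c(0.004, 0.003, 0.006), c(-0.01, 0.02, 0.005),
                 c(0.003, 0.004, 0.002))) {
    a <- chargebem:::cb_tri_analytic(r, v0, v1, v2)
    q <- quad(r, v0, v1, v2)
    # midpoint-rule oracle converges ~O(h^2); its own error bounds the check
    expect_equal(a$I0, q$I0, tolerance = 3e-4)
    expect_equal(as.numeric(a$grad), q$grad, tolerance = 5e-3)
  }
})

test_that("zero interior contrast leaves interior interfaces uncharged", {
  flat <- structure(setNames(rep(0.3, 3), c("skin", "skull", "brain")),
                    name = "FLAT", class = "conductivity_set")
  m <- build_phantom_3(conductivities = flat, n_subdiv = 2)
  dp <- dipole(c(0, 0, 0.05), c(1e-8, 0, 0), sigma_local = 0.3)
  sol <- solve_charges(m, dp)
  ctx <- sol$context
  inner <- ctx$iface > 1
  expect_lt(max(abs(sol$rho[inner])), 1e-10 * max(abs(sol$rho)))
})

test_that("sphere in a uniform field reproduces the classical interior factor", {
  sig_in <- 0.5; sig_out <- 2
  m <- head_model(list(icosphere(0.05, 3)), sig_in, sig_out, refinable = FALSE)
  sol <- solve_charges(m, uniform_field(c(0, 0, 1)))
  pts <- rbind(c(0, 0, 0), c(0.012, -0.008, 0.015), c(-0.01, 0.01, -0.02))
  E <- electric_field(sol, pts)
  fac <- 3 * sig_out / (sig_in + 2 * sig_out)
  expect_lt(max(abs(E[, 3] - fac)) / fac, 0.02)
  expect_lt(max(abs(E[, 1:2])), 0.02 * fac)
  # induced charge is proportional to cos(theta)
  ct <- sol$context$cent[, 3] / sqrt(rowSums(sol$context$cent^2))
  fitq <- stats::lm(sol$rho ~ ct)
  expect_gt(summary(fitq)$r.squared, 0.999)
})

test_that("central radial dipole matches the homogeneous-sphere closed form", {
  fx <- fix_sphere1()
  q <- 1e-8
  dp <- dipole(c(0, 0, 1e-4), c(0, 0, q), sigma_local = fx$sigma)
  sol <- solve_charges(fx$model, dp)
  pts <- fx$mesh$centroid
  rr <- sqrt(rowSums(pts^2))
  phi <- surface_potential(sol, pts)
  # exact interior Neumann solution at the evaluation radius:
  # phi(r, theta) = q cos(theta)/(4 pi sigma) (1/r^2 + 2 r / R^3)
  ct <- pts[, 3] / rr
  phi_exact <- q * ct / (4 * pi * fx$sigma) * (1 / rr^2 + 2 * rr / fx$radius^3)
  expect_lt(sqrt(sum((phi - phi_exact)^2) / sum(phi_exact^2)), 0.05)
})

test_that("solver enforces charge neutrality and reports its residual", {
  fx <- fix_model3()
  dp <- dipole(c(0.01, 0.015, 0.05), c(1e-8, -2e-9, 5e-9))
  sol <- solve_charges(fx$model, dp)
  expect_lt(charge_neutrality(sol), 1e-6)
  expect_lt(sol$stats$residual, 1e-6)
  # per-interface neutrality too
  ctx <- sol$context
  for (i in 1:3) {
    idx <- ctx$iface == i
    expect_lt(abs(sum(sol$rho[idx] * ctx$area[idx])),
              1e-9 * sum(abs(sol$rho[idx]) * ctx$area[idx]) + 1e-300)
  }
  expect_error(solve_charges(fx$model, dp, tol = 0.5), "tol")
  expect_error(solve_charges(fx$model,
                             dipole(c(0, 0, 0.2), c(1e-8, 0, 0))),
               "outside")
})

test_that("GMRES and dense solution paths agree", {
  fx <- fix_model3()
  dp <- dipole(c(0, -0.01, 0.045), c(0, 1e-8, 1e-8))
  sd_ <- solve_charges(fx$model, dp, method = "dense")
  sg <- solve_charges(fx$model, dp, method = "gmres", tol = 1e-9)
  expect_lt(sqrt(sum((sd_$rho - sg$rho)^2) / sum(sd_$rho^2)), 1e-7)
})

test_that("electrode voltages are linear in the moment and referenced correctly", {
  fx <- fix_model3()
  p <- c(0.012, -0.01, 0.05)
  basis <- lapply(1:3, function(j) {
    m <- c(0, 0, 0); m[j] <- 1e-8
    as.numeric(electrode_voltages(solve_charges(fx$model, dipole(p, m)),
                                  fx$electrodes))
  })
  q <- c(0.3, -1.2, 0.8)
  Vq <- as.numeric(electrode_voltages(
    solve_charges(fx$model, dipole(p, 1e-8 * q)), fx$electrodes))
  Vsuper <- q[1] * basis[[1]] + q[2] * basis[[2]] + q[3] * basis[[3]]
  expect_lt(max(abs(Vq - Vsuper)) / max(abs(Vq)), 1e-10)
  # flipping the moment sign negates every voltage
  Vneg <- as.numeric(electrode_voltages(
    solve_charges(fx$model, dipole(p, -1e-8 * q)), fx$electrodes))
  expect_equal(Vneg, -Vq, tolerance = 1e-10)
  # vector length equals electrode count
  expect_length(Vq, length(fx$electrodes$labels))
  # average reference sums to zero and is idempotent
  Va <- avg_reference(eeg_sample(Vq))
  expect_lt(abs(sum(Va)), 1e-12 * sqrt(sum(Va^2)))
  expect_equal(as.numeric(avg_reference(Va)), as.numeric(Va))
})

test_that("far potential of the neutral charge distribution decays faster than r^-1", {
  fx <- fix_sphere1()
  dp <- dipole(c(0, 0, 0.02), c(1e-8, 0, 0), sigma_local = fx$sigma)
  sol <- solve_charges(fx$model, dp)
  ctx <- sol$context
  # secondary potential only (the induced charges are neutral)
  sec <- function(r) {
    chargebem:::cb_potential(rbind(c(r, 0, 0)), ctx$V, ctx$F, ctx$cent,
                             ctx$area, sol$rho, ctx$len, 3)
  }
  r1 <- 10 * fx$radius; r2 <- 20 * fx$radius
  ratio <- abs(sec(r2)) / abs(sec(r1))
  expect_lt(ratio, (r1 / r2)^2 * 1.5)  # at least dipolar (r^-2) decay
})

test_that("BEM-vs-oracle RDM decreases with mesh refinement on the 4-shell phantom", {
  # well-separated shells so the coarsest resolution still nests
  radii <- c(90, 78, 66, 54) / 1000
  it7 <- conductivity_set("ITIS7")
  sig <- as.numeric(it7[c("skin", "skull", "csf", "gm")])
  dp <- dipole(c(0, 0, 0.7 * radii[4]), c(1e-8, 0, 0))
  sm <- sphere_model(radii, sig, 200)
  el <- fibonacci_layout(64, 0.65) * radii[1]
  phi_o <- sphere_potential(sm, dp, el)
  rdms <- vapply(c(1, 2, 3), function(sub) {
    meshes <- lapply(radii, icosphere, n_subdiv = sub)
    model <- head_model(meshes, sigma_in = sig, sigma_out = c(0, sig[-4]),
                        refinable = c(FALSE, TRUE, TRUE, TRUE),
                        check_nesting = FALSE)
    sol <- solve_charges(model, dp)
    rdm_mag(phi_o, surface_potential(sol, el))$rdm
  }, numeric(1))
  expect_true(all(diff(rdms) < 0))
})
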