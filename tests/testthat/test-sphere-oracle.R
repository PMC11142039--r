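test_that("one-shell central radial dipole matches the closed form", {
  R <- 0.09; sig <- 0.33; q <- 1e-8
  sm <- sphere_model(R, sig)
  th <- seq(0.05, pi - 0.05, length.out = 25)
  pts <- cbind(R * sin(th), 0, R * cos(th))
  phi <- sphere_potential(sm, dipole(c(0, 0, 0), c(0, 0, q)), pts)
  expect_equal(phi, 3 * q * cos(th) / (4 * pi * sig * R^2), tolerance = 1e-10)
})

test_that("one-shell eccentric dipoles match the textbook image series", {
  R <- 0.09; sig <- 0.5; b <- 0.05
  sm <- sphere_model(R, sig, 300)
  legP <- function(k, x) {
    p0 <- 1; p1 <- x
    if (k == 1) return(p1)
    for (j in 2:k) { p <- ((2 * j - 1) * x * p1 - (j - 1) * p0) / j; p0 <- p1; p1 <- p }
    p1
  }
  legP1 <- function(k, x) {
    s <- sqrt(max(0, 1 - x^2)); pm <- 0; pc <- s
    if (k == 1) return(pc)
    for (j in 1:(k - 1)) { pn <- ((2 * j + 1) * x * pc - (j + 1) * pm) / j; pm <- pc; pc <- pn }
    pc
  }
  th <- seq(0.1, pi - 0.1, length.out = 9)
  ph <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- do.call(rbind, lapply(th, function(t) cbind(R * sin(t) * cos(ph),
                                                     R * sin(t) * sin(ph),
                                                     R * cos(t))))
  n <- 1:200
  # radial: phi(R) = q/(4 pi sig R^2) sum (2n+1)(b/R)^(n-1) P_n
  got_r <- sphere_potential(sm, dipole(c(0, 0, b), c(0, 0, 1e-8)), pts)
  ref_r <- apply(pts, 1, function(p) {
    ct <- p[3] / R
    1e-8 / (4 * pi * sig * R^2) *
      sum((2 * n + 1) * (b / R)^(n - 1) * vapply(n, legP, numeric(1), x = ct))
  })
  expect_equal(got_r, ref_r, tolerance = 1e-8)
  # tangential: phi(R) = q/(4 pi sig R^2) sum (2n+1)/n (b/R)^(n-1) P1_n cos(phi)
  got_t <- sphere_potential(sm, dipole(c(0, 0, b), c(1e-8, 0, 0)), pts)
  ref_t <- apply(pts, 1, function(p) {
    ct <- p[3] / R; st <- sqrt(max(0, 1 - ct^2))
    cp <- if (st > 1e-12) p[1] / (R * st) else 0
    1e-8 / (4 * pi * sig * R^2) *
      sum((2 * n + 1) / n * (b / R)^(n - 1) * vapply(n, legP1, numeric(1), x = ct)) * cp
  })
  expect_equal(got_t, ref_t, tolerance = 1e-8)
})

test_that("outer-surface potential integrates to zero (current conservation)", {
  radii <- c(92, 86, 80, 78) / 1000
  sig <- c(0.147, 0.0179, 1.88, 0.419)
  sm <- sphere_model(radii, sig, 200)
  dp <- dipole(c(0.01, -0.02, 0.04), c(1e-8, 5e-9, -3e-9))
  # quasi-uniform quadrature nodes: icosphere facet centroids with area weights
  m <- icosphere(radii[1], 3)
  pts <- m$centroid / sqrt(rowSums(m$centroid^2)) * radii[1]
  phi <- sphere_potential(sm, dp, pts)
  expect_lt(abs(sum(phi * m$area)) / sum(abs(phi) * m$area), 1e-3)
})

test_that("degenerate equal-conductivity shells merge into one", {
  R <- 0.09; sig <- 0.4
  one <- sphere_model(R, sig)
  two <- sphere_model(c(R, 0.06), c(sig, sig))
  dp <- dipole(c(0.01, 0.005, 0.03), c(1e-8, -1e-8, 2e-9))
  th <- seq(0.1, pi - 0.1, length.out = 11)
  pts <- cbind(R * sin(th) * 0.6, R * sin(th) * 0.8, R * cos(th))
  expect_equal(sphere_potential(one, dp, pts), sphere_potential(two, dp, pts),
               tolerance = 1e-10)
})

test_that("series is stable under truncation-order doubling", {
  radii <- c(92, 86, 80, 78, 70) / 1000
  sig <- c(0.147, 0.0179, 1.88, 0.419, 0.348)
  # dipole in the GM shell region (between the 78 and 70 mm interfaces)
  dp <- dipole(c(0, 0, 0.074), c(1e-8, 0, 0))
  el <- fibonacci_layout(64, 0.65) * radii[1]
  p200 <- sphere_potential(sphere_model(radii, sig, 200), dp, el)
  p400 <- sphere_potential(sphere_model(radii, sig, 400), dp, el)
  expect_lt(max(abs(p400 - p200)) / max(abs(p400)), 1e-6)
  # eccentricity guard
  expect_error(sphere_potential(sphere_model(radii, sig, 100),
                                dipole(c(0, 0, 0.0779), c(1e-8, 0, 0)), el),
               "eccentricity")
})

test_that("rdm_mag matches its definition on canonical cases", {
  v <- c(1, -2, 3, 0.5)
  expect_equal(rdm_mag(v, v), list(rdm = 0, mag = 1))
  expect_equal(rdm_mag(v, 2 * v), list(rdm = 0, mag = 2))
  expect_equal(rdm_mag(v, -v), list(rdm = 2, mag = 1))
  expect_error(rdm_mag(v, v[-1]), "length")
  expect_error(rdm_mag(v * 0, v), "zero")
})
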