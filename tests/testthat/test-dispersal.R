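test_that("radial densities are normalised and match closed forms", {
  ke <- kernel_tampines_exp()
  expect_equal(radial_pdf(ke, 0), 1 / 45.2, tolerance = 1e-12)
  kl <- kernel_lognormal(66.8)
  expect_equal(radial_pdf(kl, 0), 0)
  for (k in list(ke, kl, kernel_lognormal(74.4))) {
    total <- integrate(function(r) radial_pdf(k, r), 0, Inf,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_error(radial_pdf(ke, -1), "non-negative")
})

test_that("moment-matched convention recovers the MRR mean and sd", {
  k <- kernel_spec("lognormal", xi = 45.2, sigma = 66.8, t = 7, q = 0.95,
                   ms_convention = "moment")
  mean_r <- integrate(function(r) r * radial_pdf(k, r), 0, Inf,
                      rel.tol = 1e-10)$value
  expect_equal(mean_r, 45.2, tolerance = 1e-6)
  m2 <- integrate(function(r) r^2 * radial_pdf(k, r), 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(sqrt(m2 - mean_r^2), 66.8, tolerance = 1e-5)
  # log-scale location is shared by both conventions
  expect_equal(k$M, log(45.2^2 / sqrt(45.2^2 + 66.8^2)), tolerance = 1e-12)
})

test_that("habitat radius is the q-quantile of the kernel", {
  ke <- kernel_tampines_exp()
  expect_equal(habitat_radius(ke), -45.2 * log(0.05), tolerance = 1e-12)
  k75 <- kernel_spec("exponential", xi = 75, t = 5, q = 0.8)
  expect_equal(habitat_radius(k75), -75 * log(0.2), tolerance = 1e-12)
  for (k in list(ke, k75, kernel_lognormal(66.8), kernel_lognormal(74.4))) {
    mass <- integrate(function(r) radial_pdf(k, r), 0, habitat_radius(k),
                      rel.tol = 1e-10)$value
    expect_equal(mass, k$q, tolerance = 1e-8)
  }
  expect_error(kernel_spec("exponential", xi = 45.2, t = 7, q = 1.2))
})

test_that("polar reduction agrees with direct 2-D quadrature off-singularity", {
  for (k in list(kernel_tampines_exp(), kernel_lognormal(66.8))) {
    for (xs in c(200, 300)) {
      m1 <- suppressWarnings(migration_rate(k, xs, method = "polar"))
      m2 <- suppressWarnings(migration_rate(k, xs, method = "quad2d"))
      expect_equal(m1, m2, tolerance = 1e-4)
    }
  }
})

test_that("migration rate: sigma-independence, monotonicity, 1/t scaling", {
  ke <- kernel_tampines_exp()
  # exponential kernel never sees sigma
  k2 <- kernel_spec("exponential", xi = 45.2, sigma = 74.4, t = 7, q = 0.95)
  xs <- c(100, 150, 200, 250)
  expect_identical(suppressWarnings(migration_rate(ke, xs)),
                   suppressWarnings(migration_rate(k2, xs)))
  # strictly decreasing beyond habitat contact
  rs <- habitat_radius(ke)
  far <- seq(2 * rs + 10, 2 * rs + 400, length.out = 6)
  mm <- migration_rate(ke, far)
  expect_true(all(diff(mm) < 0))
  # tail vanishes
  expect_lt(migration_rate(ke, 30 * 45.2), 1e-12)
  # the experimental period enters only as a 1/t prefactor
  k14 <- kernel_spec("exponential", xi = 45.2, t = 14, q = 0.95)
  expect_equal(suppressWarnings(migration_rate(k14, 150)),
               suppressWarnings(migration_rate(ke, 150)) / 2,
               tolerance = 1e-10)
  expect_error(migration_rate(ke, 0), "positive")
})

test_that("Monte-Carlo dispersal oracle confirms the disk-mass integral", {
  # m * t is the probability that an isotropic draw from the kernel,
  # launched from the source center, lands in the destination disk
  set.seed(1303)
  n <- 2e5
  for (k in list(kernel_tampines_exp(), kernel_lognormal(74.4))) {
    rs <- habitat_radius(k)
    rho <- if (k$family == "exponential") rexp(n, rate = 1 / k$xi)
           else rlnorm(n, meanlog = k$M, sdlog = k$S)
    phi <- runif(n, 0, 2 * pi)
    for (xs in c(100, 200)) {
      inside <- (rho * cos(phi) - xs)^2 + (rho * sin(phi))^2 <= rs^2
      p_hat <- mean(inside)
      se <- sqrt(p_hat * (1 - p_hat) / n)
      m <- suppressWarnings(migration_rate(k, xs))
      expect_lt(abs(m * k$t - p_hat), 4 * se + 1e-9)
    }
  }
})

test_that("migration matrices respect geometry", {
  k75 <- kernel_spec("exponential", xi = 75, t = 5, q = 0.8)
  expect_identical(migration_matrix(k75, 0), matrix(0, 1, 1))
  M <- suppressWarnings(migration_matrix(k75, c(0, 200, 600)))
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_gt(M[1, 2], M[2, 3])          # 200 m closer than 400 m
  expect_equal(M[1, 3], suppressWarnings(migration_rate(k75, 600)),
               tolerance = 1e-12)
  # equal spacing gives equal coefficients
  Me <- suppressWarnings(migration_matrix(k75, c(0, 300, 600)))
  expect_equal(Me[1, 2], Me[2, 3], tolerance = 1e-12)
  expect_error(migration_matrix(k75, matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
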