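test_that("nine-compartment field: extinction, capacity, direct arithmetic", {
  p <- model2_params_baseline(phi_w = 11)
  expect_identical(vector_field_model2(rep(0, 9), p), rep(0, 9))
  # at aquatic capacity the recruitment factor vanishes
  s <- c(1.5e5, 0.5e5, 10, 10, 10, 10, 10, 10, 0)
  f <- vector_field_model2(s, p)
  expect_equal(f[1], -(0.02 + 0.114) * 1.5e5, tolerance = 1e-12)
  expect_equal(f[2], -(0.02 + 0.114) * 0.5e5, tolerance = 1e-12)
  # direct evaluation at the two-habitat sweep initial state (habitat A)
  sA <- c(200, 300, 300, 500, 100, 100, 400, 0, 0)
  fA <- vector_field_model2(sA, p)
  expect_equal(fA[1],
               (13 * 100 + 0.05 * 11 * 100) * (1 - 500 / 2e5) - 0.134 * 200,
               tolerance = 1e-12)
  expect_equal(fA[2], 0.95 * 11 * 100 * (1 - 500 / 2e5) - 0.134 * 300,
               tolerance = 1e-12)
  # all males are non-carriers here: no sterile recruitment
  expect_equal(fA[9], 0, tolerance = 1e-12)
})

test_that("mating fractions are defined as zero without males", {
  p <- model2_params_baseline(phi_w = 11)
  s <- c(100, 100, 50, 50, 20, 20, 0, 0, 5)
  f <- vector_field_model2(s, p)
  expect_equal(f[5], -p$mu_fu * 20, tolerance = 1e-12)   # F_pu: decay only
  expect_equal(f[9], -p$mu_fu * 5, tolerance = 1e-12)    # F_ps: decay only
  # carrier females mature regardless of male availability
  expect_equal(f[6], p$sigma * 50 - p$mu_fw * 20, tolerance = 1e-12)
})

test_that("multi-habitat coupling: decoupling, symmetry, conservation", {
  p <- model2_params_baseline(phi_w = 11)
  s <- model2_sweep_ic()
  # zero migration reproduces the isolated habitats
  f0 <- vector_field_model2_Nhab(s, p, M = 0)
  expect_equal(f0, c(vector_field_model2(s[1:9], p),
                     vector_field_model2(s[10:18], p)), tolerance = 1e-12)
  # identical habitats: coupling terms vanish
  s_id <- c(s[1:9], s[1:9])
  expect_equal(vector_field_model2_Nhab(s_id, p, M = 0.01),
               c(vector_field_model2(s[1:9], p),
                 vector_field_model2(s[1:9], p)), tolerance = 1e-12)
  # antisymmetry: coupling contributions cancel across habitats,
  # and the aquatic compartments receive none
  fc <- vector_field_model2_Nhab(s, p, M = 0.01)
  coupling <- fc - f0
  expect_equal(coupling[1:2], c(0, 0))
  expect_equal(coupling[10:11], c(0, 0))
  expect_equal(coupling[3:9] + coupling[12:18], rep(0, 7),
               tolerance = 1e-12)
})

test_that("per-habitat aquatic capacities override the shared one", {
  p <- model2_params_baseline(phi_w = 11)
  s <- model2_sweep_ic()
  f <- vector_field_model2_Nhab(s, p, M = 0, K = c(2e5, 4e5))
  pB <- model2_params_baseline(phi_w = 11, K = 4e5)
  expect_equal(f[10:18], vector_field_model2(s[10:18], pB),
               tolerance = 1e-12)
})

test_that("carrier proportion counts carrier adults over all adults", {
  s <- c(10, 20, 1, 2, 3, 4, 5, 6, 7)
  expect_equal(carrier_proportion(s), (2 + 4 + 6) / sum(1:7))
  expect_equal(carrier_proportion(s, include_sterile = FALSE),
               12 / sum(1:6))
  two <- c(s, rep(0, 9))
  expect_equal(carrier_proportion(two), c(12 / 28, NaN))
})

test_that("non-negativity is preserved under integration", {
  p <- model2_params_baseline(phi_w = 11)
  sim <- simulate_model2(model2_sweep_ic(), p, M = 0.001,
                         times = seq(0, 500, by = 10))
  expect_true(all(sim$states >= 0))
})
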