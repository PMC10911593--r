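test_that("capacity-derived death rates hold capacities at equilibrium", {
  p <- params_baseline()
  net <- basin_network(p)
  expect_equal(net$d, c(92.8 / 160000, 136.2 / 360000), tolerance = 1e-12)
  # with non-carriers exactly at capacity the coupled field vanishes
  resid <- vector_field_Nhab(c(0, 0, 400, 600), net, p)
  expect_lt(max(abs(resid)), 1e-10)
  # no migration: d reduces to (b_U - delta_U)/K; equal K: coupling term dies
  expect_equal(death_rates_from_capacities(c(400, 600),
                                           matrix(0, 2, 2), p),
               0.229 / c(400, 600), tolerance = 1e-12)
  expect_equal(death_rates_from_capacities(c(500, 500),
                                           matrix(c(0, .05, .05, 0), 2), p),
               rep(0.229 / 500, 2), tolerance = 1e-12)
})

test_that("the migration bound protects the smaller habitat", {
  p <- params_baseline()
  expect_equal(migration_upper_bound(400, 600, p), 0.229 / (1 - 2 / 3),
               tolerance = 1e-12)
  expect_identical(migration_upper_bound(500, 500, p), Inf)
  expect_lt(0.006, migration_upper_bound(400, 600, p))
  expect_error(habitat_network(M = 0.7, K = c(400, 600), p = p),
               "migration too strong")
})

test_that("network invariants: decoupling, exchange symmetry, relabeling", {
  p <- params_baseline()
  # decoupling: zero migration reproduces the isolated habitats
  net0 <- habitat_network(M = matrix(0, 2, 2), K = c(400, 600), p = p)
  s <- c(30, 80, 350, 550)
  f <- vector_field_Nhab(s, net0, p)
  for (j in 1:2) {
    pj <- model1_params(p$b_I, p$b_U, p$delta_I, p$delta_U, net0$d[j])
    expect_equal(f[c(j, 2 + j)],
                 vector_field_1hab(s[c(j, 2 + j)], pj), tolerance = 1e-12)
  }
  # pure-exchange conservation: the coupling contributions sum to zero
  net <- basin_network(p)
  fc <- vector_field_Nhab(s, net, p)
  f0 <- vector_field_Nhab(s, habitat_network(M = matrix(0, 2, 2),
                                             d = net$d), p)
  coupling <- fc - f0
  expect_equal(sum(coupling[1:2]), 0, tolerance = 1e-14)
  expect_equal(sum(coupling[3:4]), 0, tolerance = 1e-14)
  # relabeling habitats permutes the field exactly
  perm <- c(2, 1)
  netp <- habitat_network(M = net$M[perm, perm], d = net$d[perm])
  sp <- c(s[1:2][perm], s[3:4][perm])
  fp <- vector_field_Nhab(sp, netp, p)
  expect_equal(fp, c(fc[1:2][perm], fc[3:4][perm]), tolerance = 1e-14)
})

test_that("network constructor rejects malformed migration matrices", {
  expect_error(habitat_network(M = matrix(c(0, 1, 2, 0), 2), d = c(1, 1)),
               "symmetric")
  expect_error(habitat_network(M = matrix(c(1, 0, 0, 1), 2), d = c(1, 1)),
               "diagonal")
  expect_error(habitat_network(M = 0.1, K = c(400, 600), d = c(1e-3, 1e-3)),
               "exactly one")
})

test_that("states on the critical ratio keep their ratios invariant", {
  p <- params_baseline()
  ratio <- critical_ratio(p)
  expect_equal(ratio, stable_manifold_slope(p))
  net <- habitat_network(M = 0.001, K = c(400, 500), p = p)
  x0 <- c(400, 500) / ratio
  sim <- simulate_model1(x0, c(400, 500), net, p,
                         times = seq(0, 200, by = 1),
                         rtol = 1e-12, atol = 1e-12)
  ratios <- sim$states[, 3:4] / sim$states[, 1:2]
  expect_lt(max(abs(ratios - ratio)), 1e-6)
})

test_that("habitats started strictly below the ratio all reach fixation", {
  p <- params_baseline()
  ratio <- critical_ratio(p)
  net <- habitat_network(M = 0.001, K = c(400, 500), p = p)
  x0 <- c(400, 500) / (0.9 * ratio)    # ratios y/x = 0.9 * critical
  fin <- steady_state(simulate_model1(x0, c(400, 500), net, p, 4000))$state
  expect_true(all(classify_outcome(fin, net, p)$label ==
                  "carrier_fixation"))
})
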