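test_that("every shipped fixture loads and validates", {
  for (nm in list_fixtures())
    expect_s3_class(suppressWarnings(scenario_fixture(nm)), "wb_scenario")
})

test_that("fixtures carry the printed parameter sets", {
  sc <- scenario_fixture("fig5_basin")
  expect_equal(unlist(sc$params),
               c(b_I = 0.285, b_U = 0.3, delta_I = 0.079, delta_U = 0.071))
  expect_equal(sc$habitats$K, c(400, 600))
  expect_equal(sc$net$M[1, 2], 0.006)
  m2 <- scenario_fixture("fig9a_sweep")
  expect_equal(m2$p$psi, 0.114)
  expect_equal(m2$p$K, 2e5)
  expect_equal(m2$p$phi_w, 11)
  expect_equal(m2$state0[1:9], c(200, 300, 300, 500, 100, 100, 400, 0, 0))
  kt <- scenario_fixture("kernel_tampines_exponential")
  expect_equal(kt$kernel$xi, 45.2)
  expect_equal(kt$kernel$t, 7)
  expect_equal(kt$kernel$q, 0.95)
  ky <- scenario_fixture("kernel_yishun_lognormal")
  expect_equal(ky$kernel$sigma, 74.4)
})

test_that("schema violations are rejected with named constraints", {
  both <- tempfile(fileext = ".yaml")
  writeLines(c("model: model1",
               "params: {b_I: 0.285, b_U: 0.3, delta_I: 0.079, delta_U: 0.071}",
               "habitats: {K: [400, 600], d: [0.001, 0.001]}",
               "migration: {m: 0.006}"), both)
  expect_error(load_scenario(both), "exactly one")
  unk <- tempfile(fileext = ".yaml")
  writeLines(c("model: model1", "bogus_key: 1",
               "params: {b_I: 0.285, b_U: 0.3, delta_I: 0.079, delta_U: 0.071}",
               "habitats: {d: [0.001]}"), unk)
  expect_error(load_scenario(unk), "unknown scenario key")
  # explicit coefficient beats geometry, with a warning
  mixed <- tempfile(fileext = ".yaml")
  writeLines(c("model: model1",
               "params: {b_I: 0.285, b_U: 0.3, delta_I: 0.079, delta_U: 0.071}",
               "habitats: {d: [0.001, 0.001]}",
               "migration:",
               "  m: 0.006",
               "  kernel: {family: exponential, xi: 45.2, t: 7, q: 0.95}",
               "  distances: [[0, 100], [100, 0]]"), mixed)
  expect_warning(sc <- load_scenario(mixed), "explicit value wins")
  expect_equal(sc$M[1, 2], 0.006)
})

test_that("scenario runs are deterministic and exports round-trip", {
  r1 <- suppressWarnings(
    run_scenario(scenario_fixture("kernel_tampines_exponential")))
  r2 <- suppressWarnings(
    run_scenario(scenario_fixture("kernel_tampines_exponential")))
  expect_identical(r1, r2)
  out <- tempfile(fileext = ".csv")
  paths <- write_results(r1, out, note = "kernel check")
  expect_true(all(file.exists(paths)))
  reread <- read.csv(out, comment.char = "#")
  expect_equal(reread$m, r1$m, tolerance = 1e-12)
  j <- jsonlite::read_json(paths[["json"]], simplifyVector = TRUE)
  expect_equal(j$m, r1$m, tolerance = 1e-12)
})

test_that("the phase-portrait fixture reproduces its fixation outcome", {
  res <- run_scenario(scenario_fixture("fig1_phase"))
  expect_identical(res$outcome$label, "carrier_fixation")
  expect_equal(res$state, c(400, 0), tolerance = 1e-6)
})
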