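# Shared parameter sets and small builders used across the suite.

# phase-portrait demo rates (separatrix slope 0.448/0.102)
params_demo <- function(d = 0.001)
  model1_params(b_I = 0.45, b_U = 0.55, delta_I = 0.05, delta_U = 0.048,
                d = d)

# baseline field estimates for Aedes aegypti with/without the wMel strain
params_baseline <- function(d = NA_real_)
  model1_params(b_I = 0.285, b_U = 0.300, delta_I = 0.079,
                delta_U = 0.071, d = d)

# two-habitat basin scenario: capacities 400/600, m = 0.006
basin_network <- function(p = params_baseline())
  habitat_network(M = 0.006, K = c(400, 600), p = p)

# Singapore MRR kernel estimates (xi = 45.2 m over 7 days, q = 0.95)
kernel_tampines_exp <- function()
  kernel_spec("exponential", xi = 45.2, t = 7, q = 0.95)
kernel_lognormal <- function(sigma)
  kernel_spec("lognormal", xi = 45.2, sigma = sigma, t = 7, q = 0.95)

# published migration-coefficient table for those kernels
table2_printed <- function() {
  list(
    exponential = data.frame(
      x_star = c(100, 150, 200, 250),
      m = c(0.1160, 0.0315, 0.0062, 0.0015),
      unit = c(1e-4, 1e-4, 1e-4, 1e-4)),
    lognormal_66.8 = data.frame(
      x_star = c(100, 150, 200, 250),
      m = c(0.0098, 4.55e-4, 4.27e-5, 6.20e-6),
      unit = c(1e-4, 1e-6, 1e-7, 1e-8)),
    lognormal_74.4 = data.frame(
      x_star = c(100, 150, 200, 250),
      m = c(0.0032, 9.78e-5, 6.47e-6, 6.91e-7),
      unit = c(1e-4, 1e-7, 1e-8, 1e-9)))
}

# nine-compartment baseline with reduced carrier fecundity, and the
# two-habitat initial conditions used by the migration-sweep experiments
model2_sweep_ic <- function() {
  c(200, 300, 300, 500, 100, 100, 400, 0, 0,   # habitat A
    200, 0, 800, 0, 100, 0, 400, 0, 0)          # habitat B
}

# random admissible parameter sets for property-style tests
random_valid_params <- function(n, seed = 42) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    b_U <- runif(1, 0.2, 0.8)
    b_I <- runif(1, 0.1, b_U)
    delta_U <- runif(1, 0.01, 0.15)
    delta_I <- runif(1, delta_U, 0.2)
    d <- runif(1, 1e-4, 5e-3)
    p <- try(model1_params(b_I, b_U, delta_I, delta_U, d), silent = TRUE)
    if (inherits(p, "try-error")) next
    if (!isTRUE(validate_params(p))) next
    i <- i + 1L
    out[[i]] <- p
  }
  out
}
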