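#' Smallest single-habitat release that fixes carriers everywhere
#'
#' Starts every habitat saturated with non-carriers (at capacity), releases
#' \code{n} carriers into one habitat, integrates the coupled
#' two-compartment model, and classifies the outcome.  Integer bisection
#' returns the smallest release size \code{n} for which carriers reach
#' fixation in \emph{all} habitats (so \code{n - 1} fails).
#'
#' @param net a [habitat_network()] built from capacities \code{K}.
#' @param p a [model1_params()] object.
#' @param habitat index of the release habitat.
#' @param y0 initial non-carrier populations; defaults to \code{net$K}.
#' @param cap largest release size tried (default 10 x the largest
#'   capacity); if even \code{cap} fails the threshold is reported
#'   unreachable.
#' @param horizon integration horizon (days).
#' @param ... passed to [integrate_model()] via [simulate_model1()].
#' @return list with \code{release} (smallest succeeding integer, or
#'   \code{NA} if unreachable), \code{reachable}, \code{habitat},
#'   \code{horizon}.
#' @export
minimal_release <- function(net, p, habitat, y0 = net$K,
                            cap = 10 * max(y0), horizon = 4000, ...) {
  stopifnot(inherits(net, "habitat_network"), habitat %in% seq_len(net$N))
  if (is.null(y0)) stop("'y0' required when the network was built from 'd'")
  succeeds <- function(n) {
    x0 <- numeric(net$N); x0[habitat] <- n
    fin <- steady_state(simulate_model1(x0, y0, net, p, horizon, ...))$state
    all(classify_outcome(fin, net, p)$label == "carrier_fixation")
  }
  if (!succeeds(cap))
    return(list(release = NA_integer_, reachable = FALSE,
                habitat = habitat, horizon = horizon))
  lo <- 0; hi <- cap          # lo fails, hi succeeds
  while (hi - lo > 1L) {
    mid <- floor((lo + hi) / 2)
    if (succeeds(mid)) hi <- mid else lo <- mid
  }
  list(release = as.integer(hi), reachable = TRUE, habitat = habitat,
       horizon = horizon)
}

#' Basin-of-attraction boundary for a two-habitat release
#'
#' With both habitats saturated by non-carriers, scans a grid of Habitat-A
#' release sizes and, for each, bisects (to a resolution of one individual)
#' the smallest Habitat-B release for which carriers fix in both habitats.
#' The resulting curve separates the joint releases that succeed from those
#' that fail; its axis intercepts equal the [minimal_release()] thresholds.
#'
#' @param net a two-habitat [habitat_network()].
#' @param p a [model1_params()] object.
#' @param x_A_grid Habitat-A release sizes to scan.
#' @param y0 initial non-carrier populations; defaults to \code{net$K}.
#' @param x_B_max largest Habitat-B release considered.
#' @param horizon integration horizon (days).
#' @param ... passed to the integrator.
#' @return data frame with columns \code{x_A} and \code{x_B} (the boundary:
#'   smallest succeeding Habitat-B release; 0 when \code{x_A} alone
#'   suffices, \code{NA} when even \code{x_B_max} fails).
#' @export
basin_boundary <- function(net, p, x_A_grid, y0 = net$K,
                           x_B_max = 10 * max(y0), horizon = 4000, ...) {
  stopifnot(inherits(net, "habitat_network"), net$N == 2L)
  succeeds <- function(xa, xb) {
    fin <- steady_state(
      simulate_model1(c(xa, xb), y0, net, p, horizon, ...))$state
    all(classify_outcome(fin, net, p)$label == "carrier_fixation")
  }
  xb_min <- vapply(x_A_grid, function(xa) {
    if (succeeds(xa, 0)) return(0)
    if (!succeeds(xa, x_B_max)) return(NA_real_)
    lo <- 0; hi <- x_B_max
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (succeeds(xa, mid)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  data.frame(x_A = x_A_grid, x_B = xb_min)
}

#' Sweep the migration coefficient and bracket qualitative transitions
#'
#' Integrates the two-habitat two-compartment model to steady state for
#' each migration coefficient on a grid, records the steady populations and
#' per-habitat outcome labels, and brackets every migration value at which
#' the joint outcome changes (e.g. the loss of a stable all-positive
#' coexistence state) by bisection.
#'
#' @param p a [model1_params()] object.
#' @param d length-2 density-dependent death rates (held fixed across the
#'   sweep, as when they are specified directly rather than derived from
#'   capacities).
#' @param m_grid strictly increasing migration coefficients to scan.
#' @param x0,y0 length-2 initial carrier/non-carrier populations.
#' @param horizon integration horizon (days).
#' @param m_tol bisection resolution for transition brackets.
#' @param ... passed to the integrator.
#' @return list with \code{grid} (data frame: m, steady populations,
#'   joint outcome) and \code{transitions} (data frame: m_lower, m_upper,
#'   m_mid and the outcomes on either side; empty when no change occurs).
#' @export
migration_sweep <- function(p, d, m_grid, x0, y0, horizon = 6000,
                            m_tol = 1e-5, ...) {
  stopifnot(length(d) == 2L, length(x0) == 2L, length(y0) == 2L,
            !is.unsorted(m_grid, strictly = TRUE))
  outcome_at <- function(m) {
    net <- habitat_network(M = m, d = d)
    fin <- steady_state(simulate_model1(x0, y0, net, p, horizon, ...))$state
    cls <- classify_outcome(fin, net, p)
    list(joint = paste(cls$label, collapse = "+"), state = fin)
  }
  res <- lapply(m_grid, outcome_at)
  grid <- data.frame(
    m = m_grid,
    x_A = vapply(res, function(r) r$state[1], numeric(1)),
    x_B = vapply(res, function(r) r$state[2], numeric(1)),
    y_A = vapply(res, function(r) r$state[3], numeric(1)),
    y_B = vapply(res, function(r) r$state[4], numeric(1)),
    outcome = vapply(res, `[[`, character(1), "joint"),
    stringsAsFactors = FALSE)
  trans <- list()
  for (i in seq_len(length(m_grid) - 1L)) {
    if (grid$outcome[i] != grid$outcome[i + 1L]) {
      lo <- m_grid[i]; hi <- m_grid[i + 1L]
      lab_lo <- grid$outcome[i]
      while (hi - lo > m_tol) {
        mid <- (lo + hi) / 2
        if (outcome_at(mid)$joint == lab_lo) lo <- mid else hi <- mid
      }
      trans[[length(trans) + 1L]] <- data.frame(
        m_lower = lo, m_upper = hi, m_mid = (lo + hi) / 2,
        outcome_below = lab_lo, outcome_above = grid$outcome[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  list(grid = grid,
       transitions = if (length(trans)) do.call(rbind, trans) else
         data.frame(m_lower = numeric(), m_upper = numeric(),
                    m_mid = numeric(), outcome_below = character(),
                    outcome_above = character()))
}

#' Migration sweep for the two-habitat nine-compartment model
#'
#' For each migration coefficient, integrates the two-habitat
#' nine-compartment model to \code{horizon} and records the adult carrier
#' proportion in each habitat; then bisects the coefficient at which the
#' Habitat-B proportion first crosses \code{threshold}.
#'
#' @param p a [model2_params()] object.
#' @param state0 length-18 initial state (Habitat A block then Habitat B).
#' @param m_grid increasing migration coefficients.
#' @param horizon evaluation time (days); the proportion is read at exactly
#'   this time.
#' @param threshold fixation cutoff on the Habitat-B proportion.
#' @param m_tol bisection resolution.
#' @param K optional length-2 per-habitat aquatic capacities overriding
#'   \code{p$K}.
#' @param ... passed to the integrator.
#' @return list with \code{grid} (m, prop_A, prop_B) and
#'   \code{threshold_m} (bracket midpoint of the crossing; \code{NA} when
#'   the grid does not straddle it).
#' @export
model2_migration_sweep <- function(p, state0, m_grid, horizon = 2500,
                                   threshold = 0.5, m_tol = 1e-5,
                                   K = NULL, ...) {
  prop_at <- function(m) {
    fin <- steady_state(
      simulate_model2(state0, p, M = m, times = horizon, K = K, ...))$state
    carrier_proportion(fin)
  }
  props <- t(vapply(m_grid, prop_at, numeric(2)))
  grid <- data.frame(m = m_grid, prop_A = props[, 1], prop_B = props[, 2])
  above <- grid$prop_B > threshold
  threshold_m <- NA_real_
  if (any(above) && any(!above)) {
    i <- which(!above & c(above[-1L], FALSE))[1L]   # last below before a cross
    lo <- m_grid[i]; hi <- m_grid[i + 1L]
    while (hi - lo > m_tol) {
      mid <- (lo + hi) / 2
      if (prop_at(mid)[2L] > threshold) hi <- mid else lo <- mid
    }
    threshold_m <- (lo + hi) / 2
  }
  list(grid = grid, threshold_m = threshold_m)
}

#' Habitat-size versus migration success map (nine-compartment model)
#'
#' For each pair (migration coefficient, capacity ratio
#' \eqn{K_B/K_A}), integrates the two-habitat nine-compartment model to
#' \code{horizon} and records whether the Habitat-B adult carrier
#' proportion exceeds \code{threshold} at exactly that time.
#'
#' @inheritParams model2_migration_sweep
#' @param ratio_grid values of \eqn{K_B/K_A}.
#' @return data frame with columns \code{m}, \code{ratio}, \code{prop_B},
#'   \code{success}.
#' @export
model2_capacity_map <- function(p, state0, m_grid, ratio_grid,
                                horizon = 2500, threshold = 0.5, ...) {
  res <- expand.grid(m = m_grid, ratio = ratio_grid)
  res$prop_B <- mapply(function(m, ratio) {
    fin <- steady_state(simulate_model2(state0, p, M = m, times = horizon,
                                        K = c(p$K, ratio * p$K), ...))$state
    carrier_proportion(fin)[2L]
  }, res$m, res$ratio)
  res$success <- res$prop_B > threshold
  res
}

#' Release-size versus migration outcome map (nine-compartment model)
#'
#' Simulates a half-female, half-male release of carriers into Habitat A
#' (\eqn{F_w^{(A)}(0) = M_w^{(A)}(0) = } release) for each combination of
#' release size and migration coefficient, and classifies the outcome as
#' fixation in neither habitat, Habitat A only, or both.
#'
#' @inheritParams model2_migration_sweep
#' @param release_grid carrier release sizes.
#' @return data frame with columns \code{release}, \code{m},
#'   \code{prop_A}, \code{prop_B}, \code{outcome} (one of \code{"none"},
#'   \code{"A_only"}, \code{"both"}).
#' @export
model2_release_map <- function(p, state0, release_grid, m_grid,
                               horizon = 2500, threshold = 0.5, ...) {
  res <- expand.grid(release = release_grid, m = m_grid)
  props <- mapply(function(rel, m) {
    s0 <- state0
    s0[4L] <- rel; s0[8L] <- rel   # F_w and M_w in Habitat A
    fin <- steady_state(
      simulate_model2(s0, p, M = m, times = horizon, ...))$state
    carrier_proportion(fin)
  }, res$release, res$m)
  res$prop_A <- props[1L, ]
  res$prop_B <- props[2L, ]
  res$outcome <- ifelse(res$prop_A > threshold & res$prop_B > threshold,
                        "both",
                 ifelse(res$prop_A > threshold, "A_only", "none"))
  res
}
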