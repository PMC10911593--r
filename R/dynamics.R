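#' Integrate a habitat model to a time horizon
#'
#' Thin wrapper around [deSolve::ode()] (lsoda: adaptive, stiff-capable)
#' shared by every model in the package.  States are clipped to zero inside
#' the right-hand side and again on output, so trajectories started in the
#' non-negative orthant stay there up to integrator tolerance.
#'
#' @param rhs function of a state vector returning its time derivative.
#' @param state0 non-negative initial state.
#' @param times output times (days); a scalar horizon \code{T} is expanded
#'   to \code{c(0, T)}.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param labels optional state-component names for the trajectory columns.
#' @return An object of class \code{"habitat_sim"}: a list with
#'   \code{times}, \code{states} (time x component matrix, clipped to >= 0)
#'   and the \code{rhs} used (for convergence checks).
#' @export
integrate_model <- function(rhs, state0, times, rtol = 1e-10, atol = 1e-10,
                            labels = NULL) {
  if (length(times) == 1L) times <- c(0, times)
  out <- deSolve::ode(y = as.numeric(state0), times = times,
                      func = function(t, y, parms) list(rhs(y)),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("integration failed; last good time ", max(out[, 1L]))
  states <- pmax(unclass(out)[, -1L, drop = FALSE], 0)
  dimnames(states) <- NULL
  if (!is.null(labels)) colnames(states) <- labels
  structure(list(times = out[, 1L], states = states, rhs = rhs),
            class = "habitat_sim")
}

#' @export
print.habitat_sim <- function(x, ...) {
  cat(sprintf("habitat_sim: %d states over t = [%g, %g] (%d output times)\n",
              ncol(x$states), min(x$times), max(x$times), length(x$times)))
  ss <- steady_state(x)
  cat(sprintf("  final state %s; converged: %s\n",
              paste(signif(ss$state, 4), collapse = ", "), ss$converged))
  invisible(x)
}

#' Terminal state and convergence flag of a simulation
#'
#' Returns the state at the horizon and whether the dynamics have settled:
#' the maximum derivative magnitude, relative to the state scale, is below
#' \code{tol}.  Non-convergence is a flag, not an error (trajectories
#' passing near a saddle settle slowly).
#'
#' @param sim a [integrate_model()] result.
#' @param tol relative derivative tolerance for the converged flag.
#' @return list with \code{state}, \code{time}, \code{converged}.
#' @export
steady_state <- function(sim, tol = 1e-8) {
  stopifnot(inherits(sim, "habitat_sim"))
  fin <- unname(sim$states[nrow(sim$states), ])
  deriv <- sim$rhs(fin)
  scale <- max(abs(fin), 1)
  list(state = fin, time = max(sim$times),
       converged = max(abs(deriv)) / scale < tol)
}

#' Simulate the two-compartment model on a habitat network
#'
#' @param x0,y0 initial carrier/non-carrier populations, length N.
#' @param net a [habitat_network()]; for a single isolated habitat pass
#'   \code{net = NULL} and a [model1_params()] with \code{d} set.
#' @param p a [model1_params()] object.
#' @param times horizon or output-time vector (days); default 2000.
#' @param ... passed to [integrate_model()].
#' @return a \code{"habitat_sim"}; state layout \code{c(x_1..x_N, y_1..y_N)}.
#' @examples
#' p <- model1_params(0.45, 0.55, 0.05, 0.048, 0.001)
#' sim <- simulate_model1(100, 100, net = NULL, p = p, times = 2000)
#' steady_state(sim)$state   # approaches (400, 0)
#' @export
simulate_model1 <- function(x0, y0, net, p, times = 2000, ...) {
  if (is.null(net)) {
    rhs <- function(s) vector_field_1hab(s, p)
    labels <- c("x", "y")
  } else {
    stopifnot(length(x0) == net$N, length(y0) == net$N)
    rhs <- function(s) vector_field_Nhab(s, net, p)
    labels <- c(paste0("x", seq_len(net$N)), paste0("y", seq_len(net$N)))
  }
  integrate_model(rhs, c(x0, y0), times, labels = labels, ...)
}

#' Simulate the nine-compartment model on one or more habitats
#'
#' @param state0 initial state: length 9 (single habitat), or 9N stacked
#'   habitat blocks, or a 9 x N matrix.
#' @param p a [model2_params()] object.
#' @param M migration matrix (or scalar m for two habitats); \code{NULL}
#'   for a single habitat.
#' @param times horizon or output-time vector (days); default 2500.
#' @param K optional per-habitat aquatic capacities, see
#'   [vector_field_model2_Nhab()].
#' @param ... passed to [integrate_model()].
#' @return a \code{"habitat_sim"}.
#' @export
simulate_model2 <- function(state0, p, M = NULL, times = 2500, K = NULL,
                            ...) {
  state0 <- as.numeric(state0)
  if (is.null(M)) {
    stopifnot(length(state0) == 9L)
    rhs <- function(s) vector_field_model2(s, p)
    labels <- model2_compartments()
  } else {
    rhs <- function(s) vector_field_model2_Nhab(s, p, M, K = K)
    n <- length(state0) / 9L
    labels <- paste0(rep(model2_compartments(), n),
                     rep(paste0(".", seq_len(n)), each = 9L))
  }
  integrate_model(rhs, state0, times, labels = labels, ...)
}

#' Classify the invasion outcome in each habitat
#'
#' For the two-compartment model a habitat is labelled
#' \code{carrier_fixation} when non-carriers are extinct
#' (\eqn{y_j < \epsilon_j}) and carriers are not, \code{carrier_loss} in
#' the reverse case, and \code{coexistence} when both persist.  The
#' per-habitat extinction threshold \eqn{\epsilon_j} defaults to
#' \code{eps_frac} times the habitat's non-carrier-only equilibrium
#' \eqn{(b_U - \delta_U)/d_j}: equilibria are of order the carrying
#' capacity, and numerical decay leaves trace amounts.
#'
#' For the nine-compartment model the label is \code{carrier_fixation}
#' when the adult carrier proportion exceeds \code{threshold} (default
#' 0.5), else \code{carrier_loss}; the raw proportion is reported
#' alongside.
#'
#' @param state terminal state vector (layout as the corresponding
#'   simulate function).
#' @param net a [habitat_network()] (model 1) and \code{p} its parameters;
#'   or a [model2_params()] via \code{p} with \code{net = NULL} (model 2,
#'   habitat count inferred from the state length).
#' @param p parameter object matching the model.
#' @param eps_frac extinction threshold as a fraction of the non-carrier
#'   equilibrium (model 1).
#' @param threshold carrier-proportion cutoff for fixation (model 2).
#' @param include_sterile see [carrier_proportion()].
#' @return data frame with one row per habitat: \code{habitat},
#'   \code{label}, \code{proportion}, and steady populations.
#' @export
classify_outcome <- function(state, net = NULL, p, eps_frac = 1e-3,
                             threshold = 0.5, include_sterile = TRUE) {
  if (inherits(p, "model1_params")) {
    if (is.null(net))
      net <- habitat_network(M = matrix(0, 1, 1), d = p$d)
    n <- net$N
    x <- state[seq_len(n)]; y <- state[n + seq_len(n)]
    eps <- eps_frac * (p$b_U - p$delta_U) / net$d
    lab <- ifelse(y < eps & x >= eps, "carrier_fixation",
           ifelse(x < eps & y >= eps, "carrier_loss", "coexistence"))
    lab[x < eps & y < eps] <- "carrier_loss"   # joint extinction: no carriers
    data.frame(habitat = seq_len(n), label = lab,
               proportion = ifelse(x + y > 0, x / (x + y), 0),
               x = x, y = y, stringsAsFactors = FALSE)
  } else if (inherits(p, "model2_params")) {
    S <- matrix(pmax(as.numeric(state), 0), nrow = 9L)
    prop <- carrier_proportion(S, include_sterile = include_sterile)
    adults <- colSums(S[3:9, , drop = FALSE])
    lab <- ifelse(!is.nan(prop) & prop > threshold,
                  "carrier_fixation", "carrier_loss")
    data.frame(habitat = seq_len(ncol(S)), label = lab, proportion = prop,
               adults = adults, stringsAsFactors = FALSE)
  } else stop("'p' must be a model1_params or model2_params object")
}

#' Tidy long-format view of a trajectory
#'
#' @param sim a \code{"habitat_sim"}.
#' @return data frame with columns \code{time}, \code{compartment},
#'   \code{value}, suitable for CSV export or plotting.
#' @export
as_tidy_trajectory <- function(sim) {
  stopifnot(inherits(sim, "habitat_sim"))
  comp <- colnames(sim$states)
  if (is.null(comp)) comp <- paste0("s", seq_len(ncol(sim$states)))
  data.frame(
    time = rep(sim$times, times = ncol(sim$states)),
    compartment = rep(comp, each = length(sim$times)),
    value = as.numeric(sim$states),
    stringsAsFactors = FALSE)
}
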