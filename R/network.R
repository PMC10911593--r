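#' A network of diffusively coupled habitats
#'
#' A habitat is a discrete region of high mosquito density (a stagnant pond,
#' an overgrown lot) treated as one well-mixed compartment.  Habitats
#' exchange adults at a rate proportional to the population difference, with
#' symmetric migration coefficients \eqn{m_{jk}} (day^-1): the net flux into
#' habitat \eqn{j} from habitat \eqn{k} is \eqn{m_{jk}(C_k - C_j)} for each
#' motile compartment \eqn{C}.
#'
#' Exactly one of \code{K} (carrying capacities) or \code{d} (per-habitat
#' density-dependent death rates) must be given for the two-compartment
#' model: mixing the two silently changes the all-non-carrier equilibrium.
#' When \code{K} is given, \code{d} is derived by
#' [death_rates_from_capacities()] so that "non-carriers at capacity" is an
#' exact equilibrium of the coupled system.
#'
#' @param M symmetric N x N migration-coefficient matrix with zero diagonal
#'   (day^-1).  A scalar is accepted for N = 2 as shorthand for the single
#'   off-diagonal coefficient.
#' @param K per-habitat carrying capacities (individuals), or \code{NULL}.
#' @param d per-habitat density-dependent death rates, or \code{NULL}.
#' @param p a [model1_params()] object; required when \code{K} is given.
#'
#' @return An object of class \code{"habitat_network"} with elements
#'   \code{N}, \code{M}, \code{K} (possibly NULL) and \code{d}.
#' @examples
#' p <- model1_params(0.285, 0.3, 0.079, 0.071)
#' net <- habitat_network(M = 0.006, K = c(400, 600), p = p)
#' net$d   # c(5.8e-4, 3.7833e-4)
#' @export
habitat_network <- function(M, K = NULL, d = NULL, p = NULL) {
  if (is.null(K) == is.null(d))
    stop("supply exactly one of 'K' (capacities) or 'd' (death rates)")
  n <- if (!is.null(K)) length(K) else length(d)
  if (length(M) == 1L && n == 2L)
    M <- matrix(c(0, M, M, 0), 2, 2)
  M <- as.matrix(M)
  if (!is.numeric(M) || nrow(M) != n || ncol(M) != n)
    stop("'M' must be a ", n, " x ", n, " numeric matrix")
  if (any(M < 0)) stop("migration coefficients must be non-negative")
  if (any(diag(M) != 0)) stop("'M' must have a zero diagonal")
  if (!isTRUE(all.equal(M, t(M))))
    stop("'M' must be symmetric: migration has no directional bias")
  if (!is.null(K)) {
    if (any(K <= 0)) stop("carrying capacities must be positive")
    if (is.null(p)) stop("'p' is required to derive death rates from 'K'")
    d <- death_rates_from_capacities(K, M, p)
  } else {
    if (any(d <= 0)) stop("death rates must be positive")
  }
  structure(list(N = n, M = M, K = K, d = as.numeric(d)),
            class = "habitat_network")
}

#' @export
print.habitat_network <- function(x, ...) {
  cat(sprintf("Habitat network: %d habitat(s)\n", x$N))
  if (!is.null(x$K)) cat("  K:", paste(format(x$K), collapse = ", "), "\n")
  cat("  d:", paste(signif(x$d, 6), collapse = ", "), "\n")
  if (x$N > 1L) {
    cat("  migration coefficients (day^-1):\n")
    print(signif(x$M, 4))
  }
  invisible(x)
}

#' Density-dependent death rates that hold capacities at equilibrium
#'
#' Solves the all-non-carrier steady state of the coupled model for the
#' per-habitat density-dependent death rates:
#' \deqn{d_j = \frac{1}{K_j}\Big(b_U - \delta_U +
#'   \sum_k m_{jk}\big(K_k/K_j - 1\big)\Big),}
#' so that \eqn{x = 0, y = K} is an equilibrium by construction.  Migration
#' out of a small habitat towards a large one drains it faster than births
#' replace; if the coupling is too strong the formula turns negative and the
#' capacity profile is unsustainable (see [migration_upper_bound()]).
#'
#' @param K carrying capacities (individuals), all positive.
#' @param M migration matrix as in [habitat_network()].
#' @param p a [model1_params()] object.
#'
#' @return numeric vector of per-habitat rates \eqn{d_j}.
#' @export
death_rates_from_capacities <- function(K, M, p) {
  stopifnot(inherits(p, "model1_params"), all(K > 0))
  n <- length(K)
  M <- as.matrix(M)
  d <- vapply(seq_len(n), function(j) {
    (p$b_U - p$delta_U + sum(M[j, ] * (K / K[j] - 1))) / K[j]
  }, numeric(1))
  if (any(d <= 0))
    stop("migration too strong for the capacity profile: derived d_j <= 0 ",
         "for habitat(s) ", paste(which(d <= 0), collapse = ", "),
         "; reduce m below the admissible bound (see migration_upper_bound)")
  d
}

#' Largest admissible migration coefficient for a two-habitat pair
#'
#' With capacity ratio \eqn{a = \min(K)/\max(K)}, the death rate of the
#' smaller habitat derived by [death_rates_from_capacities()] stays positive
#' iff \eqn{m < (b_U - \delta_U)/(1 - a)}.  Equal capacities impose no
#' bound.
#'
#' @param K_A,K_B the two carrying capacities.
#' @param p a [model1_params()] object.
#' @return the supremum of admissible \eqn{m} (\code{Inf} when
#'   \eqn{K_A = K_B}).
#' @export
migration_upper_bound <- function(K_A, K_B, p) {
  stopifnot(inherits(p, "model1_params"), K_A > 0, K_B > 0)
  a <- min(K_A, K_B) / max(K_A, K_B)
  if (a == 1) return(Inf)
  (p$b_U - p$delta_U) / (1 - a)
}

#' Vector field of the N-habitat two-compartment model
#'
#' Each habitat runs the single-habitat dynamics with its own
#' density-dependent death rate \eqn{d_j}, plus diffusive exchange of both
#' carriers and non-carriers with every other habitat.
#'
#' @param state numeric vector \code{c(x_1..x_N, y_1..y_N)}.
#' @param net a [habitat_network()].
#' @param p a [model1_params()] object (the shared rate constants; its own
#'   \code{d} slot is ignored in favour of \code{net$d}).
#'
#' @return numeric vector of the 2N time derivatives, same layout as
#'   \code{state}.
#' @export
vector_field_Nhab <- function(state, net, p) {
  stopifnot(inherits(net, "habitat_network"), inherits(p, "model1_params"))
  n <- net$N
  if (length(state) != 2L * n)
    stop("'state' must have length 2N = ", 2L * n)
  x <- pmax(state[seq_len(n)], 0)
  y <- pmax(state[n + seq_len(n)], 0)
  tot <- x + y
  dx <- (p$b_I - p$delta_I) * x - net$d * x * tot +
    as.numeric(net$M %*% x) - rowSums(net$M) * x
  dy <- ci_birth(p$b_U, x, y) - p$delta_U * y - net$d * y * tot +
    as.numeric(net$M %*% y) - rowSums(net$M) * y
  c(dx, dy)
}

#' Critical non-carrier-to-carrier ratio for networked invasion
#'
#' The separatrix slope of the single-habitat model (see
#' [stable_manifold_slope()]) plays a second role on networks: if every
#' habitat starts exactly at \eqn{y_j/x_j} equal to this ratio, the ratios
#' stay constant for all time and the trajectory runs inside the stable
#' manifold of a coupled coexistence equilibrium.  Starting every habitat
#' strictly below the ratio is a sufficient (not necessary) condition for
#' carrier persistence in every habitat.
#'
#' @inheritParams stable_manifold_slope
#' @return the critical ratio (identical to the separatrix slope).
#' @export
critical_ratio <- function(p) stable_manifold_slope(p)
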