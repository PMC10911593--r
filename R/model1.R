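#' Parameters for the two-compartment carrier/non-carrier model
#'
#' Bundles the rate constants of the minimal Wolbachia invasion model, which
#' tracks only the carrier population \eqn{x} and non-carrier population
#' \eqn{y} of a single well-mixed habitat:
#' \deqn{dx/dt = (b_I - \delta_I) x - d\,x(x+y)}
#' \deqn{dy/dt = b_U y^2/(x+y) - \delta_U y - d\,y(x+y)}
#' The quadratic non-carrier birth term encodes cytoplasmic incompatibility:
#' a non-carrier female produces viable offspring only when she mates with a
#' non-carrier male, an event of probability \eqn{y/(x+y)} in a well-mixed
#' population.
#'
#' @param b_I carrier (infected) birth rate, day^-1.
#' @param b_U non-carrier (uninfected) birth rate, day^-1.
#' @param delta_I carrier density-independent death rate, day^-1.
#' @param delta_U non-carrier density-independent death rate, day^-1.
#' @param d density-dependent death rate, day^-1 per individual.  May be
#'   omitted (\code{NA}) when the habitat network derives it from carrying
#'   capacities.
#'
#' @return An object of class \code{"model1_params"}.
#' @seealso [validate_params()] for the biological admissibility conditions,
#'   [model1_equilibria()], [stable_manifold_slope()].
#' @examples
#' p <- model1_params(b_I = 0.285, b_U = 0.300, delta_I = 0.079,
#'                    delta_U = 0.071, d = 0.001)
#' validate_params(p)
#' @export
model1_params <- function(b_I, b_U, delta_I, delta_U, d = NA_real_) {
  fields <- list(b_I = b_I, b_U = b_U, delta_I = delta_I, delta_U = delta_U)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  if (!is.na(d) && (!is.numeric(d) || length(d) != 1L || d <= 0))
    stop("'d' must be a single positive number (or NA)", call. = FALSE)
  structure(list(b_I = b_I, b_U = b_U, delta_I = delta_I,
                 delta_U = delta_U, d = as.numeric(d)),
            class = "model1_params")
}

#' @export
print.model1_params <- function(x, ...) {
  cat("Two-compartment Wolbachia model parameters (day^-1):\n")
  cat(sprintf("  birth  : carriers b_I = %g, non-carriers b_U = %g\n",
              x$b_I, x$b_U))
  cat(sprintf("  death  : carriers delta_I = %g, non-carriers delta_U = %g\n",
              x$delta_I, x$delta_U))
  cat(sprintf("  density-dependent death d = %s\n",
              if (is.na(x$d)) "(derived from capacities)" else format(x$d)))
  v <- validate_params(x)
  if (!isTRUE(v)) cat("  WARNING: admissibility violated:",
                      paste(v, collapse = "; "), "\n")
  invisible(x)
}

#' Check the biological admissibility of model parameters
#'
#' The minimal model is meaningful only when both populations are viable in
#' isolation and the carrier strain carries a (weak) fitness cost:
#' \eqn{b_I > d + \delta_I}, \eqn{b_U > d + \delta_U}, \eqn{b_U \ge b_I},
#' and \eqn{\delta_I \ge \delta_U}.  Under these restrictions the model is
#' bistable, with carrier-only and non-carrier-only states both locally
#' stable.
#'
#' @param p a [model1_params()] object.  When \code{d} is unset the
#'   viability inequalities are checked with \code{d = 0} (they must then be
#'   re-checked per habitat once the habitat-specific rates are known).
#'
#' @return \code{TRUE} when every inequality holds, otherwise a character
#'   vector naming each violated inequality.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model1_params"))
  d <- if (is.na(p$d)) 0 else p$d
  bad <- character()
  if (!(p$b_I > d + p$delta_I)) bad <- c(bad, "b_I > d + delta_I")
  if (!(p$b_U > d + p$delta_U)) bad <- c(bad, "b_U > d + delta_U")
  if (!(p$b_U >= p$b_I))        bad <- c(bad, "b_U >= b_I")
  if (!(p$delta_I >= p$delta_U)) bad <- c(bad, "delta_I >= delta_U")
  if (length(bad) == 0L) TRUE else bad
}

# CI birth term b_U * y^2/(x+y), extended continuously by 0 at x+y = 0.
ci_birth <- function(b_U, x, y) {
  tot <- x + y
  out <- numeric(length(y))
  pos <- tot > 0
  out[pos] <- b_U * y[pos]^2 / tot[pos]
  out
}

#' Vector field of the single-habitat two-compartment model
#'
#' @param state numeric vector \code{c(x, y)}: carrier and non-carrier
#'   populations.  Tiny negative values (integrator round-off) are clipped
#'   to zero before evaluation.
#' @param p a [model1_params()] object with \code{d} set.
#'
#' @return numeric vector \code{c(dx, dy)} of time derivatives (day^-1).
#' @examples
#' p <- model1_params(0.45, 0.55, 0.05, 0.048, d = 0.001)
#' vector_field_1hab(c(100, 100), p)   # c(20, 2.7)
#' @export
vector_field_1hab <- function(state, p) {
  stopifnot(inherits(p, "model1_params"), length(state) == 2L)
  if (is.na(p$d)) stop("'d' is unset; supply it or derive it from capacities")
  x <- max(state[[1L]], 0)
  y <- max(state[[2L]], 0)
  tot <- x + y
  c((p$b_I - p$delta_I) * x - p$d * x * tot,
    ci_birth(p$b_U, x, y) - p$delta_U * y - p$d * y * tot)
}

model1_jacobian <- function(state, p, eps = 1e-6) {
  # central finite differences; exact enough for stability classification
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- eps * max(1, abs(state[j]))
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (vector_field_1hab(up, p) - vector_field_1hab(dn, p)) / (2 * h)
  }
  J
}

#' Equilibria of the single-habitat model
#'
#' Under the admissibility conditions (see [validate_params()]) the model
#' has three equilibria: a carrier-only state \eqn{((b_I-\delta_I)/d, 0)},
#' a non-carrier-only state \eqn{(0, (b_U-\delta_U)/d)} (both locally
#' asymptotically stable), and an unstable coexistence saddle whose total
#' population equals the carrier-only equilibrium population.  The stated
#' classification is verified numerically from the Jacobian eigenvalues; a
#' disagreement (which would indicate a degenerate parameter set) raises an
#' error.
#'
#' @inheritParams vector_field_1hab
#' @return A data frame with one row per equilibrium and columns
#'   \code{equilibrium}, \code{x}, \code{y}, \code{stability}.
#' @export
model1_equilibria <- function(p) {
  stopifnot(inherits(p, "model1_params"))
  v <- validate_params(p)
  if (!isTRUE(v))
    stop("parameters violate admissibility: ", paste(v, collapse = "; "))
  d <- p$d
  if (is.na(d)) stop("'d' is unset")
  x1 <- (p$b_I - p$delta_I) / d
  y2 <- (p$b_U - p$delta_U) / d
  x3 <- (p$b_U - p$delta_U - p$b_I + p$delta_I) * (p$b_I - p$delta_I) /
    (p$b_U * d)
  y3 <- (p$delta_U + p$b_I - p$delta_I) * (p$b_I - p$delta_I) / (p$b_U * d)
  eq <- data.frame(
    equilibrium = c("carrier_only", "noncarrier_only", "coexistence"),
    x = c(x1, 0, x3), y = c(0, y2, y3),
    stability = c("stable", "stable", "saddle"),
    stringsAsFactors = FALSE)
  # verify the analytic classification against the Jacobian
  for (i in seq_len(nrow(eq))) {
    ev <- Re(eigen(model1_jacobian(c(eq$x[i], eq$y[i]), p),
                   only.values = TRUE)$values)
    lab <- if (all(ev < 0)) "stable" else if (any(ev > 0) && any(ev < 0))
      "saddle" else "unstable"
    if (lab != eq$stability[i])
      stop("numerical stability check disagrees with the analytic label at ",
           eq$equilibrium[i], " (eigenvalues ", paste(signif(ev, 4),
           collapse = ", "), ")")
  }
  eq
}

#' Slope of the separatrix between invasion success and failure
#'
#' The stable manifold of the coexistence saddle is the line
#' \eqn{y = c\,x} with
#' \eqn{c = (b_I-\delta_I+\delta_U)/(b_U-b_I+\delta_I-\delta_U)}.
#' Initial states with \eqn{y/x} below \eqn{c} converge to the carrier-only
#' equilibrium (invasion succeeds); above it, carriers are lost.  The slope
#' does not depend on \eqn{d}, so a single value applies to every habitat of
#' a coupled network; see [critical_ratio()].
#'
#' @inheritParams vector_field_1hab
#' @return the slope, a single positive number.
#' @examples
#' stable_manifold_slope(model1_params(0.45, 0.55, 0.05, 0.048, 0.001))
#' @export
stable_manifold_slope <- function(p) {
  stopifnot(inherits(p, "model1_params"))
  den <- p$b_U - p$b_I + p$delta_I - p$delta_U
  if (den <= 0)
    stop("degenerate basin geometry: b_U - b_I + delta_I - delta_U must be ",
         "positive, got ", signif(den, 4))
  (p$b_I - p$delta_I + p$delta_U) / den
}
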