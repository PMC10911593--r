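#' Dispersal-kernel specification
#'
#' A dispersal kernel is a probability density over the distance an
#' individual travels during an experimental period of \code{t} days,
#' estimated from mark-release-recapture (MRR) studies as the mean distance
#' traveled \code{xi} (and, for the log-normal family, a standard deviation
#' \code{sigma}).  A habitat's radius is defined as the radius of the disk
#' enclosing a fraction \code{q} of the kernel's mass.
#'
#' For the log-normal family the package converts \code{(xi, sigma)} to the
#' log-scale parameters \eqn{(M, S)} with
#' \eqn{M = \ln(\xi^2/\sqrt{\xi^2+\sigma^2})} and, under the default
#' \code{ms_convention = "table"},
#' \eqn{S = \sqrt{\ln(1 + (\xi/\sigma)^2)}}.  This is the convention under
#' which the package reproduces published migration-coefficient tables for
#' the Singapore MRR estimates; note that it is not an exact moment match
#' (the distribution's mean is not exactly \code{xi}).  The strict
#' moment-matched form \eqn{S = \sqrt{\ln(1 + (\sigma/\xi)^2)}}, for which
#' the mean and standard deviation equal \code{xi} and \code{sigma}
#' exactly, is available as \code{ms_convention = "moment"}.
#'
#' @param family \code{"exponential"} or \code{"lognormal"}.
#' @param xi mean distance traveled (meters), positive.
#' @param sigma standard deviation of distance traveled (meters); required
#'   by the log-normal family, ignored by the exponential.
#' @param t experimental period of the MRR estimate (days), positive.
#' @param q enclosure fraction defining the habitat radius, in (0, 1).
#' @param ms_convention log-normal \eqn{(M,S)} convention, see Details.
#'
#' @return An object of class \code{"kernel_spec"}.
#' @examples
#' kernel_spec("exponential", xi = 45.2, t = 7, q = 0.95)
#' kernel_spec("lognormal", xi = 45.2, sigma = 66.8, t = 7, q = 0.95)
#' @export
kernel_spec <- function(family = c("exponential", "lognormal"), xi,
                        sigma = NULL, t = 1, q = 0.95,
                        ms_convention = c("table", "moment")) {
  family <- match.arg(family)
  ms_convention <- match.arg(ms_convention)
  stopifnot(is.numeric(xi), length(xi) == 1L, xi > 0,
            is.numeric(t), length(t) == 1L, t > 0,
            is.numeric(q), length(q) == 1L, q > 0, q < 1)
  k <- list(family = family, xi = xi, sigma = sigma, t = t, q = q,
            ms_convention = ms_convention)
  if (family == "lognormal") {
    if (is.null(sigma) || !is.numeric(sigma) || sigma <= 0)
      stop("the log-normal family requires a positive 'sigma'")
    k$M <- log(xi^2 / sqrt(xi^2 + sigma^2))
    k$S <- switch(ms_convention,
                  table  = sqrt(log(1 + (xi / sigma)^2)),
                  moment = sqrt(log(1 + (sigma / xi)^2)))
  }
  structure(k, class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("%s dispersal kernel: xi = %g m", x$family, x$xi))
  if (x$family == "lognormal")
    cat(sprintf(", sigma = %g m (M = %.4f, S = %.4f, %s convention)",
                x$sigma, x$M, x$S, x$ms_convention))
  cat(sprintf("\n  period t = %g d, enclosure q = %g, habitat radius r* = %.2f m\n",
              x$t, x$q, habitat_radius(x)))
  invisible(x)
}

#' Radial probability density of a dispersal kernel
#'
#' The density of travel distance \eqn{r \ge 0}:
#' exponential \eqn{(1/\xi)e^{-r/\xi}}; log-normal
#' \eqn{\exp(-(\ln r - M)^2/(2S^2)) / (S r \sqrt{2\pi})} (0 at \eqn{r = 0}
#' by limit).  Integrates to 1 over \eqn{[0, \infty)}.
#'
#' @param k a [kernel_spec()].
#' @param r distances (meters), non-negative; vectorised.
#' @return densities, meter^-1.
#' @export
radial_pdf <- function(k, r) {
  stopifnot(inherits(k, "kernel_spec"))
  if (any(r < 0)) stop("distances must be non-negative")
  switch(k$family,
         exponential = exp(-r / k$xi) / k$xi,
         lognormal = stats::dlnorm(r, meanlog = k$M, sdlog = k$S))
}

#' Habitat radius enclosing a fraction q of the kernel mass
#'
#' The smallest \eqn{r^*} with \eqn{\int_0^{r^*} p(r)\,dr = q}:
#' \eqn{-\xi\ln(1-q)} for the exponential kernel and the log-normal
#' quantile \eqn{\exp(M + \sqrt{2}\,S\,\mathrm{erf}^{-1}(2q-1))} otherwise.
#'
#' @param k a [kernel_spec()].
#' @return the radius \eqn{r^*} (meters).
#' @examples
#' habitat_radius(kernel_spec("exponential", xi = 45.2, t = 7, q = 0.95))
#' @export
habitat_radius <- function(k) {
  stopifnot(inherits(k, "kernel_spec"))
  switch(k$family,
         exponential = -k$xi * log(1 - k$q),
         lognormal = stats::qlnorm(k$q, meanlog = k$M, sdlog = k$S))
}

#' Migration coefficient between two circular habitats
#'
#' The per-day probability rate that a mosquito resident in one habitat
#' turns up in another, obtained by spreading the dispersal kernel
#' isotropically from the source habitat's center and measuring the mass
#' that lands in the destination disk:
#' \deqn{m(x^*) = \frac{1}{2\pi t}\int_0^{2\pi}\!\!\int_0^{r^*}
#'   \frac{p(D(r,\theta))}{D(r,\theta)}\, r\, dr\, d\theta, \qquad
#'   D = \sqrt{(r\cos\theta + x^*)^2 + (r\sin\theta)^2},}
#' where \eqn{x^*} is the center-to-center distance and both habitats share
#' the radius \eqn{r^*} implied by the kernel (see [habitat_radius()]).
#'
#' The default \code{method = "polar"} evaluates an exact reduction of this
#' double integral to one dimension.  In polar coordinates about the
#' \emph{source} center, the circle of radius \eqn{\rho} intersects the
#' destination disk in an arc of angle
#' \eqn{\alpha(\rho) = 2\arccos\big((\rho^2 + x^{*2} - r^{*2})/(2\rho
#' x^*)\big)} (clamped to \eqn{[0, 2\pi]}), giving
#' \eqn{m = \frac{1}{2\pi t}\int p(\rho)\,\alpha(\rho)\, d\rho} over
#' \eqn{[\,|x^*-r^*|, x^*+r^*]}.  The reduced integrand is bounded, so the
#' computation remains accurate even when the destination disk contains the
#' source center (\eqn{x^* < r^*}), where direct two-dimensional quadrature
#' of the \eqn{1/D} singularity loses digits.  \code{method = "quad2d"}
#' performs that direct two-dimensional quadrature; it is retained as an
#' independent cross-check.
#'
#' @param k a [kernel_spec()].
#' @param x_star center-to-center distance (meters), positive; vectorised.
#' @param r_star habitat radius override (meters); defaults to
#'   [habitat_radius()] of the kernel.
#' @param method \code{"polar"} (exact 1-D reduction, default) or
#'   \code{"quad2d"} (direct 2-D quadrature).
#' @return migration coefficient(s) \eqn{m}, day^-1.
#' @examples
#' k <- kernel_spec("exponential", xi = 45.2, t = 7, q = 0.95)
#' migration_rate(k, x_star = c(100, 150, 200, 250))
#' @export
migration_rate <- function(k, x_star, r_star = habitat_radius(k),
                           method = c("polar", "quad2d")) {
  stopifnot(inherits(k, "kernel_spec"))
  method <- match.arg(method)
  if (any(x_star <= 0))
    stop("x_star must be positive: coincident habitat centers put the ",
         "kernel singularity at the source")
  if (any(x_star < 2 * r_star))
    warning("habitats overlap (x_star < 2 r_star); the migration estimate ",
            "treats them as distinct disks anyway", call. = FALSE)
  vapply(x_star, function(xs) {
    switch(method,
           polar = mig_rate_polar(k, xs, r_star),
           quad2d = mig_rate_quad2d(k, xs, r_star))
  }, numeric(1))
}

mig_rate_polar <- function(k, x_star, r_star) {
  arc <- function(rho) {
    cosa <- (rho^2 + x_star^2 - r_star^2) / (2 * rho * x_star)
    2 * acos(pmin(1, pmax(-1, cosa)))
  }
  f <- function(rho) radial_pdf(k, rho) * arc(rho)
  lo <- max(x_star - r_star, 0)
  val <- stats::integrate(f, lo, x_star + r_star, rel.tol = 1e-12,
                          abs.tol = 1e-16, subdivisions = 4000L)$value
  val / (2 * pi * k$t)
}

mig_rate_quad2d <- function(k, x_star, r_star) {
  g <- function(r, th) {
    D <- sqrt((r * cos(th) + x_star)^2 + (r * sin(th))^2)
    out <- r * radial_pdf(k, D)
    ifelse(D > 0, out / D, 0)
  }
  val <- pracma::integral2(g, 0, r_star, 0, 2 * pi, reltol = 1e-10)$Q
  val / (2 * pi * k$t)
}

#' Migration matrix from pairwise habitat distances
#'
#' Applies [migration_rate()] to every habitat pair, producing the
#' symmetric zero-diagonal coefficient matrix consumed by
#' [habitat_network()] and the nine-compartment network model.
#'
#' @param k a [kernel_spec()].
#' @param distances symmetric matrix of center-to-center distances (meters)
#'   with zero diagonal, or a vector of coordinates of collinear habitat
#'   centers (meters) from which distances are formed.
#' @return symmetric N x N matrix of migration coefficients (day^-1).
#' @examples
#' k <- kernel_spec("exponential", xi = 75, t = 5, q = 0.8)
#' migration_matrix(k, c(0, 200, 600))   # collinear habitats
#' @export
migration_matrix <- function(k, distances) {
  stopifnot(inherits(k, "kernel_spec"))
  if (is.null(dim(distances)))
    distances <- abs(outer(distances, distances, `-`))
  distances <- as.matrix(distances)
  if (!isTRUE(all.equal(distances, t(distances))) ||
      any(diag(distances) != 0))
    stop("'distances' must be symmetric with a zero diagonal")
  n <- nrow(distances)
  M <- matrix(0, n, n)
  if (n > 1L) {
    ut <- which(upper.tri(distances), arr.ind = TRUE)
    vals <- migration_rate(k, distances[ut])
    M[ut] <- vals
    M[ut[, c(2, 1), drop = FALSE]] <- vals
  }
  M
}
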