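#' Parameters for the nine-compartment sex/life-stage model
#'
#' The detailed single-habitat model tracks aquatic-stage mosquitoes,
#' unmated females, pregnant females, males, and sterile pregnant females,
#' each split by Wolbachia carrier status.  Cytoplasmic incompatibility
#' enters through the mating split: an unmated non-carrier female becomes a
#' fertile pregnant female with probability \eqn{M_u/(M_u+M_w)} (she mated a
#' non-carrier male) and a sterile one otherwise.  Carrier females are
#' fertile regardless of their mate, so their maturation \eqn{\sigma F_w}
#' carries no male-availability factor.
#'
#' @param b_f,b_m female/male emergence fractions (dimensionless).
#' @param sigma mating/maturation rate of unmated females, day^-1.
#' @param phi_u,phi_w per-capita egg-laying rates of non-carrier/carrier
#'   pregnant females, day^-1.
#' @param v_u,v_w maternal transmission fractions in [0, 1]: the fraction of
#'   a carrier mother's offspring that are non-carriers (\code{v_u}) or
#'   carriers (\code{v_w}).
#' @param psi aquatic development (emergence) rate, day^-1.
#' @param mu_a,mu_fu,mu_fw,mu_mu,mu_mw death rates of the aquatic stage,
#'   non-carrier/carrier females, and non-carrier/carrier males, day^-1.
#' @param K aquatic-stage carrying capacity (individuals).
#'
#' @return An object of class \code{"model2_params"}.
#' @examples
#' p <- model2_params_baseline(phi_w = 11)
#' @export
model2_params <- function(b_f, b_m, sigma, phi_u, phi_w, v_u, v_w,
                          psi, mu_a, mu_fu, mu_fw, mu_mu, mu_mw, K) {
  p <- list(b_f = b_f, b_m = b_m, sigma = sigma, phi_u = phi_u,
            phi_w = phi_w, v_u = v_u, v_w = v_w, psi = psi, mu_a = mu_a,
            mu_fu = mu_fu, mu_fw = mu_fw, mu_mu = mu_mu, mu_mw = mu_mw,
            K = K)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  if (v_u > 1 || v_w > 1)
    stop("transmission fractions v_u, v_w must lie in [0, 1]")
  structure(p, class = "model2_params")
}

#' Baseline parameter set for the nine-compartment model
#'
#' The published baseline rates for \emph{Aedes aegypti} with the wMel
#' Wolbachia strain.  The carrier egg-laying rate \code{phi_w} is
#' scenario-dependent (a reduced-fecundity value of 11 or the non-carrier
#' value 13) and must be chosen explicitly.
#'
#' @param phi_w carrier egg-laying rate, day^-1 (11 or 13 in the published
#'   experiments; any positive value is accepted).
#' @param K aquatic carrying capacity (default 2e5).
#' @return A [model2_params()] object.
#' @export
model2_params_baseline <- function(phi_w, K = 2e5) {
  model2_params(b_f = 0.5, b_m = 0.5, sigma = 1.0, phi_u = 13,
                phi_w = phi_w, v_u = 0.05, v_w = 0.95, psi = 0.114,
                mu_a = 0.02, mu_fu = 0.0571, mu_fw = 0.0633,
                mu_mu = 0.0952, mu_mw = 0.0952, K = K)
}

#' Compartment order of the nine-compartment model
#'
#' \code{A_u, A_w}: aquatic; \code{F_u, F_w}: unmated females;
#' \code{F_pu, F_pw}: pregnant females; \code{M_u, M_w}: males;
#' \code{F_ps}: sterile pregnant females.  Suffix \code{u} = non-carrier,
#' \code{w} = carrier.
#' @return character vector of the nine compartment names, in state order.
#' @export
model2_compartments <- function() {
  c("A_u", "A_w", "F_u", "F_w", "F_pu", "F_pw", "M_u", "M_w", "F_ps")
}

# which compartments are motile adults (everything but the aquatic stage)
model2_motile <- function() 3:9

#' Vector field of the single-habitat nine-compartment model
#'
#' Aquatic recruitment is logistic in the total aquatic population
#' (factor \eqn{1 - (A_u+A_w)/K}); when no males are present the mating
#' fractions are defined as zero, so unmated non-carrier females neither
#' mature nor become sterile.
#'
#' @param state numeric vector of the nine compartments in
#'   [model2_compartments()] order.
#' @param p a [model2_params()] object.
#' @return numeric vector of the nine time derivatives.
#' @export
vector_field_model2 <- function(state, p) {
  stopifnot(inherits(p, "model2_params"), length(state) == 9L)
  s <- pmax(as.numeric(state), 0)
  A_u <- s[1]; A_w <- s[2]; F_u <- s[3]; F_w <- s[4]; F_pu <- s[5]
  F_pw <- s[6]; M_u <- s[7]; M_w <- s[8]; F_ps <- s[9]
  logis <- 1 - (A_u + A_w) / p$K
  males <- M_u + M_w
  frac_u <- if (males > 0) M_u / males else 0
  frac_w <- if (males > 0) M_w / males else 0
  c((p$phi_u * F_pu + p$v_u * p$phi_w * F_pw) * logis - (p$mu_a + p$psi) * A_u,
    p$v_w * p$phi_w * F_pw * logis - (p$mu_a + p$psi) * A_w,
    p$b_f * p$psi * A_u - (p$sigma + p$mu_fu) * F_u,
    p$b_f * p$psi * A_w - (p$sigma + p$mu_fw) * F_w,
    p$sigma * F_u * frac_u - p$mu_fu * F_pu,
    p$sigma * F_w - p$mu_fw * F_pw,
    p$b_m * p$psi * A_u - p$mu_mu * M_u,
    p$b_m * p$psi * A_w - p$mu_mw * M_w,
    p$sigma * F_u * frac_w - p$mu_fu * F_ps)
}

#' Vector field of the N-habitat nine-compartment model
#'
#' Every motile (adult) compartment of habitat \eqn{j} gains the diffusive
#' term \eqn{\sum_k m_{jk}(C^{(k)} - C^{(j)})}; the aquatic compartments
#' have none, since larvae cannot migrate.  A single coefficient per habitat
#' pair applies to all motile subpopulations.
#'
#' @param state numeric vector of length 9N, habitats stacked consecutively
#'   (habitat 1's nine compartments, then habitat 2's, ...).
#' @param p a [model2_params()] object (shared across habitats).
#' @param M symmetric migration matrix with zero diagonal, or a scalar for
#'   N = 2.
#' @param K optional per-habitat aquatic carrying capacities (length N)
#'   overriding \code{p$K}; all other parameters stay habitat-independent.
#' @return numeric vector of the 9N time derivatives.
#' @export
vector_field_model2_Nhab <- function(state, p, M, K = NULL) {
  stopifnot(inherits(p, "model2_params"))
  if (length(M) == 1L) M <- matrix(c(0, M, M, 0), 2, 2)
  M <- as.matrix(M)
  n <- nrow(M)
  if (length(state) != 9L * n)
    stop("'state' must have length 9N = ", 9L * n)
  if (is.null(K)) K <- rep(p$K, n)
  stopifnot(length(K) == n, all(K > 0))
  S <- matrix(pmax(as.numeric(state), 0), nrow = 9L, ncol = n)
  D <- vapply(seq_len(n), function(j) {
    pj <- p; pj$K <- K[j]
    vector_field_model2(S[, j], pj)
  }, numeric(9L))
  mot <- model2_motile()
  # coupling: (S M^T)_cj - S_cj * rowsum_j(M), applied to motile rows only
  D[mot, ] <- D[mot, ] + S[mot, , drop = FALSE] %*% t(M) -
    sweep(S[mot, , drop = FALSE], 2L, rowSums(M), `*`)
  as.numeric(D)
}

#' Carrier proportion among adults
#'
#' The fraction of Wolbachia carriers among adult mosquitoes,
#' \eqn{(F_w + F_{pw} + M_w) / \text{(all adults)}}.  Sterile pregnant
#' females \eqn{F_{ps}} are counted in the denominator by default (they are
#' non-carrier-lineage adults); set \code{include_sterile = FALSE} to drop
#' them.
#'
#' @param state a nine-element single-habitat state, or a 9 x N matrix /
#'   length-9N vector of stacked habitat states (one proportion per
#'   habitat).
#' @param include_sterile logical; count \code{F_ps} in the denominator?
#' @return numeric vector of per-habitat proportions in [0, 1] (NaN for an
#'   adult-free habitat).
#' @export
carrier_proportion <- function(state, include_sterile = TRUE) {
  S <- matrix(pmax(as.numeric(state), 0), nrow = 9L)
  num <- S[4, ] + S[6, ] + S[8, ]
  den <- colSums(S[3:8, , drop = FALSE]) +
    if (include_sterile) S[9, ] else 0
  num / den
}
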