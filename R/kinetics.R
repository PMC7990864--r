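#' Growth rate of the acid-producing species (Streptococcus)
#'
#' Monod growth on saliva with a hyperbolic acid-inhibition factor:
#' `g1 = theta1 * rho_s * mu1 * s1/(k11+s1) * kl/(kl+s2)`. As the acid
#' concentration grows without bound the rate tends to zero; at
#' `s2 = kl` the rate is exactly half the uninhibited rate. Under the
#' competitive variant the inhibition factor is dropped.
#'
#' Vectorized over `theta1`, `s1`, `s2` (recycled to a common shape),
#' so it can be evaluated directly on gridded fields. Cells with zero
#' biomass contribute zero rate, so reaction terms vanish in the fluid
#' region without an explicit mask.
#'
#' @param theta1 volume fraction of species 1, in `[0, 1]`.
#' @param s1,s2 saliva and lactic-acid concentrations [kg/m^3], `>= 0`.
#' @param params a [biofilm_params()] object.
#' @param variant model variant, see [model_variant()].
#' @return biomass production rate [kg/(m^3 s)], same shape as inputs.
#' @export
growth_rate_streptococcus <- function(theta1, s1, s2, params,
                                      variant = "symbiotic") {
  stopifnot(inherits(params, "biofilm_params"))
  variant <- model_variant(variant)
  check_kinetic_inputs(theta1, s1, s2)
  g <- theta1 * params$rho_s * params$mu1 * s1 / (params$k11 + s1)
  if (variant == "symbiotic") g <- g * params$kl / (params$kl + s2)
  g
}

#' Growth rate of the acid-consuming species (Veillonella)
#'
#' Double Monod kinetics: `g2 = theta2 * rho_v * mu2 * s1/(k21+s1) *
#' s2/(k22+s2)`. The species cannot grow without lactic acid (`g2 = 0`
#' at `s2 = 0`), reflecting that it cannot use the saliva carbon source
#' directly. Under the competitive variant the acid factor is dropped
#' and growth is limited by saliva alone.
#'
#' @inheritParams growth_rate_streptococcus
#' @param theta2 volume fraction of species 2, in `[0, 1]`.
#' @return biomass production rate [kg/(m^3 s)], same shape as inputs.
#' @export
growth_rate_veillonella <- function(theta2, s1, s2, params,
                                    variant = "symbiotic") {
  stopifnot(inherits(params, "biofilm_params"))
  variant <- model_variant(variant)
  check_kinetic_inputs(theta2, s1, s2)
  g <- theta2 * params$rho_v * params$mu2 * s1 / (params$k21 + s1)
  if (variant == "symbiotic") g <- g * s2 / (params$k22 + s2)
  g
}

check_kinetic_inputs <- function(theta, s1, s2) {
  if (any(theta < 0 | theta > 1)) {
    stop("volume fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(s1 < 0) || any(s2 < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Substrate reaction rates from the biomass production rates
#'
#' Given the two growth rates, returns the four substrate source/sink
#' terms: saliva consumption `r11 = -g1/Y_s1` and `r12 = -g2/Y_v1`,
#' acid production `r21 = lam * g1`, and acid consumption
#' `r22 = -g2/Y_v2` (symbiotic) or `r22 = 0` (competitive; acid is
#' still produced and transported but has no sink, so it accumulates).
#'
#' @param g1,g2 biomass production rates [kg/(m^3 s)], `>= 0`.
#' @inheritParams growth_rate_streptococcus
#' @return A list of class `reaction_rates` with elements `g1`, `g2`,
#'   `r11`, `r12`, `r21`, `r22`.
#' @export
substrate_reaction_rates <- function(g1, g2, params,
                                     variant = "symbiotic") {
  stopifnot(inherits(params, "biofilm_params"))
  variant <- model_variant(variant)
  if (any(g1 < 0) || any(g2 < 0)) {
    stop("growth rates must be nonnegative", call. = FALSE)
  }
  r22 <- if (variant == "symbiotic") -g2 / params$Y_v2 else g2 * 0
  structure(list(
    g1 = g1, g2 = g2,
    r11 = -g1 / params$Y_s1,
    r12 = -g2 / params$Y_v1,
    r21 = params$lam * g1,
    r22 = r22
  ), class = "reaction_rates")
}

# Dimensionless Monod factor products per unit volume fraction.
# F1 = S1/(K11+S1) * KL/(KL+S2)  (acid factor dropped when competitive)
# F2 = S1/(K21+S1) * S2/(K22+S2) (acid factor dropped when competitive)
# The dimensionless growth sources are Psi_i * theta_i * F_i, the
# saliva sinks Theta_1i^2 * theta_i * F_i and the acid source/sink
# Theta_21^2 * theta_1 * F1 and Theta_22^2 * theta_2 * F2.
monod_factors <- function(S1, S2, groups, variant = "symbiotic") {
  F1 <- S1 / (groups$K11 + S1)
  F2 <- S1 / (groups$K21 + S1)
  if (variant == "symbiotic") {
    F1 <- F1 * groups$KL / (groups$KL + S2)
    F2 <- F2 * S2 / (groups$K22 + S2)
  }
  list(F1 = F1, F2 = F2)
}
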