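#' Physical parameters of the dual-species biofilm model
#'
#' Constructs the full set of dimensional constants describing the
#' symbiotic *Streptococcus--Veillonella* biofilm system. The defaults
#' are the documented reference parameter set for a 300 micrometre
#' square domain fed by saliva from the top boundary.
#'
#' All parameters are strictly positive. Several of the biological
#' constants (yields, half-rate constants, the acid production
#' coefficient) are order-of-magnitude estimates for oral biofilms and
#' are deliberately exposed as arguments rather than hard-wired.
#'
#' @param W,H domain width and height [m].
#' @param s1_bar saliva (nutrient) concentration held at the top
#'   boundary [kg/m^3].
#' @param D1,D2 diffusion coefficients of saliva and lactic acid
#'   [m^2/s].
#' @param rho_s,rho_v biomass densities of *Streptococcus* and
#'   *Veillonella* [kg/m^3].
#' @param Y_s1 yield of *Streptococcus* on saliva [-].
#' @param Y_v1,Y_v2 yields of *Veillonella* on saliva and on lactic
#'   acid [-].
#' @param lam lactic-acid production coefficient: mass of acid secreted
#'   per unit mass of *Streptococcus* produced [-].
#' @param mu1,mu2 maximum specific growth rates [1/s].
#' @param k11 Monod half-rate constant of *Streptococcus* on saliva
#'   [kg/m^3].
#' @param k21,k22 Monod half-rate constants of *Veillonella* on saliva
#'   and on lactic acid [kg/m^3].
#' @param kl acid inhibition constant: the *Streptococcus* growth rate
#'   is halved when the acid concentration equals `kl` [kg/m^3].
#' @param t_d characteristic time [s]; one day by default.
#'
#' @return An object of class `biofilm_params` (a named list).
#' @seealso [nondimensionalize()] for the dimensionless groups driving
#'   the solver.
#' @export
#' @examples
#' p <- biofilm_params()
#' p$mu1 * p$t_d   # dimensionless growth number of species 1
biofilm_params <- function(W = 300e-6, H = 300e-6,
                           s1_bar = 10,
                           D1 = 5e-10, D2 = 1e-9,
                           rho_s = 1100, rho_v = 1100,
                           Y_s1 = 0.1, Y_v1 = 0.1, Y_v2 = 0.1,
                           lam = 0.5,
                           mu1 = 3e-5, mu2 = 8e-5,
                           k11 = 0.878, k21 = 0.878, k22 = 0.0878,
                           kl = 1,
                           t_d = 86400) {
  p <- list(W = W, H = H, s1_bar = s1_bar, D1 = D1, D2 = D2,
            rho_s = rho_s, rho_v = rho_v,
            Y_s1 = Y_s1, Y_v1 = Y_v1, Y_v2 = Y_v2,
            lam = lam, mu1 = mu1, mu2 = mu2,
            k11 = k11, k21 = k21, k22 = k22, kl = kl, t_d = t_d)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  structure(p, class = "biofilm_params")
}

#' @export
print.biofilm_params <- function(x, ...) {
  cat("Biofilm model parameters (dimensional)\n")
  cat(sprintf("  domain      W = %.3g m, H = %.3g m\n", x$W, x$H))
  cat(sprintf("  nutrient    s1_bar = %.3g kg/m^3, D1 = %.3g m^2/s\n",
              x$s1_bar, x$D1))
  cat(sprintf("  acid        D2 = %.3g m^2/s, lambda = %.3g, kl = %.3g kg/m^3\n",
              x$D2, x$lam, x$kl))
  cat(sprintf("  growth      mu1 = %.3g 1/s, mu2 = %.3g 1/s\n", x$mu1, x$mu2))
  cat(sprintf("  Monod       k11 = %.3g, k21 = %.3g, k22 = %.3g kg/m^3\n",
              x$k11, x$k21, x$k22))
  cat(sprintf("  yields      Y_s1 = %.3g, Y_v1 = %.3g, Y_v2 = %.3g\n",
              x$Y_s1, x$Y_v1, x$Y_v2))
  cat(sprintf("  densities   rho_s = %.3g, rho_v = %.3g kg/m^3\n",
              x$rho_s, x$rho_v))
  cat(sprintf("  time scale  t_d = %.5g s\n", x$t_d))
  invisible(x)
}

#' Dimensionless groups of the biofilm model
#'
#' Maps the dimensional parameter set to the dimensionless groups that
#' drive the nondimensional solver. Lengths are scaled by the domain
#' height `H`, time by `t_d`, concentrations by the top-boundary saliva
#' concentration `s1_bar`, and the growth potential by `H^2 / t_d`.
#'
#' The groups are:
#' \describe{
#'   \item{D2_star}{`D2 * t_d / H^2`, dimensionless acid diffusivity.}
#'   \item{Theta11_sq}{`H^2 rho_s mu1 / (Y_s1 D1 s1_bar)`, Thiele-type
#'     number for saliva uptake by species 1.}
#'   \item{Theta12_sq}{`H^2 rho_v mu2 / (Y_v1 D1 s1_bar)`, saliva uptake
#'     by species 2.}
#'   \item{Theta21_sq}{`lam rho_s mu1 t_d / s1_bar`, acid production.}
#'   \item{Theta22_sq}{`rho_v mu2 t_d / (s1_bar Y_v2)`, acid
#'     consumption.}
#'   \item{Psi1, Psi2}{`mu_i t_d`, growth numbers.}
#'   \item{K11, K21, K22, KL}{half-rate and inhibition constants scaled
#'     by `s1_bar`.}
#' }
#'
#' @param params a [biofilm_params()] object.
#' @return An object of class `dimensionless_groups` (a named list).
#' @export
#' @examples
#' g <- nondimensionalize(biofilm_params())
#' g$Psi1    # 2.592 with the default parameter set
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "biofilm_params"))
  p <- params
  g <- list(
    D2_star    = p$D2 * p$t_d / p$H^2,
    Theta11_sq = p$H^2 * p$rho_s * p$mu1 / (p$Y_s1 * p$D1 * p$s1_bar),
    Theta12_sq = p$H^2 * p$rho_v * p$mu2 / (p$Y_v1 * p$D1 * p$s1_bar),
    Theta21_sq = p$lam * p$rho_s * p$mu1 * p$t_d / p$s1_bar,
    Theta22_sq = p$rho_v * p$mu2 * p$t_d / (p$s1_bar * p$Y_v2),
    Psi1       = p$mu1 * p$t_d,
    Psi2       = p$mu2 * p$t_d,
    K11        = p$k11 / p$s1_bar,
    K21        = p$k21 / p$s1_bar,
    K22        = p$k22 / p$s1_bar,
    KL         = p$kl / p$s1_bar
  )
  structure(g, class = "dimensionless_groups")
}

#' @export
print.dimensionless_groups <- function(x, ...) {
  cat("Dimensionless groups\n")
  for (nm in names(x)) cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Model variant selector
#'
#' The symbiotic variant is the full cross-feeding model: species 1
#' growth is inhibited by acid, species 2 growth requires acid, and
#' species 2 consumes acid. In the competitive variant the acid factors
#' are removed from both growth laws and the acid consumption term is
#' switched off, so both species compete for saliva only while acid is
#' still produced and transported (it accumulates without feedback).
#'
#' @param tag `"symbiotic"` or `"competitive"`.
#' @return The validated tag (character scalar).
#' @export
model_variant <- function(tag = c("symbiotic", "competitive")) {
  match.arg(tag)
}
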