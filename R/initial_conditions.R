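#' Evenly mixed initial condition under a sinusoidal interface
#'
#' The baseline scenario: both species evenly mixed (volume fraction
#' one half each) below a wavy biofilm--fluid interface
#' `Z = mean + amplitude * sin(wavenumber * X + phase)`; no biomass
#' above; no lactic acid anywhere; saliva initialized to its boundary
#' value (it is overwritten by the first quasi-steady solve).
#'
#' The defaults reproduce the reference interface
#' `Z = 0.1 + 0.05 sin(4 pi X + pi/2)` with a 50/50 species mixture.
#' Setting `amplitude = 0` gives the flat-interface mixed reference
#' used by the homogenization study.
#'
#' @param grid a [build_grid()] object.
#' @param mean,amplitude,wavenumber,phase interface shape parameters
#'   (dimensionless).
#' @param frac1 initial volume fraction of species 1 inside the biofilm
#'   (species 2 receives `1 - frac1`).
#' @return A `biofilm_state` with the mask set.
#' @export
#' @examples
#' st <- init_mixed(build_grid(50))
init_mixed <- function(grid, mean = 0.1, amplitude = 0.05,
                       wavenumber = 4 * pi, phase = pi / 2,
                       frac1 = 0.5) {
  stopifnot(inherits(grid, "biofilm_grid"))
  h <- mean + amplitude * sin(wavenumber * grid$xc + phase)
  if (any(h <= 0) || any(h >= 1)) {
    stop("interface must lie strictly inside the domain", call. = FALSE)
  }
  state <- new_state(grid)
  below <- outer(seq_len(grid$nx), seq_len(grid$nz),
                 function(i, j) grid$zc[j] < h[i])
  state$theta1[below] <- frac1
  state$theta2[below] <- 1 - frac1
  update_biofilm_mask(state)
}

#' Correlated random volume-fraction field
#'
#' Synthesizes a stationary Gaussian random field with
#' squared-exponential covariance `exp(-r^2 / corr_len^2)` on the
#' initial biofilm slab (`Z < z_top`) by spectral (FFT) sampling on a
#' periodic grid, maps it into `[0, 1]` by the rank-preserving normal
#' CDF transform, and affinely rescales it so the spatial mean is
#' exactly one half. The exact-mean constraint makes the initial mass
#' of each species identical across correlation lengths, which the
#' homogenization comparison requires.
#'
#' @param grid a [build_grid()] object.
#' @param corr_len dimensionless correlation length (e-folding distance
#'   of the target correlation); must be at least one cell.
#' @param seed integer seed; the field is reproducible per seed and the
#'   caller's RNG state is left untouched.
#' @param z_top top of the initial biofilm slab (dimensionless).
#' @return An `nx` by `nz` matrix holding the species-2 fraction in the
#'   slab and zero above it.
#' @export
generate_correlated_field <- function(grid, corr_len, seed, z_top = 0.2) {
  stopifnot(inherits(grid, "biofilm_grid"))
  if (corr_len < grid$dx) {
    stop("correlation length below grid resolution (corr_len < dx)",
         call. = FALSE)
  }
  nslab <- sum(grid$zc < z_top)
  if (nslab < 2L) stop("slab not resolved by the grid", call. = FALSE)
  z <- with_seed(seed, grf_periodic(grid$nx, nslab, grid$dx, grid$dz,
                                    corr_len))
  u <- stats::pnorm(z)
  d <- u - mean(u)
  # largest symmetric scaling that keeps the field inside [0, 1]
  s <- min(1, 0.5 / (max(abs(d)) + 1e-12))
  field <- matrix(0, grid$nx, grid$nz)
  field[, seq_len(nslab)] <- 0.5 + s * d
  field
}

# Periodic Gaussian random field with covariance exp(-r^2/len^2),
# sampled in Fourier space: power spectrum proportional to
# exp(-|k|^2 len^2 / 4), Hermitian-symmetrized complex white noise.
grf_periodic <- function(nx, nz, dx, dz, len) {
  kx <- 2 * pi * fft_freq(nx) / (nx * dx)
  kz <- 2 * pi * fft_freq(nz) / (nz * dz)
  k2 <- outer(kx^2, kz^2, `+`)
  amp <- exp(-k2 * len^2 / 8)
  noise <- matrix(stats::rnorm(nx * nz), nx, nz) +
    1i * matrix(stats::rnorm(nx * nz), nx, nz)
  z <- Re(stats::fft(amp * noise, inverse = TRUE)) / (nx * nz)
  (z - mean(z)) / stats::sd(z)
}

fft_freq <- function(n) {
  half <- floor(n / 2)
  c(0:half, seq.int(-(n - half - 1), -1))[seq_len(n)]
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Random-field initial condition
#'
#' Flat biofilm slab of thickness `z_top` whose species composition is
#' the correlated random field of [generate_correlated_field()]:
#' `theta2` is the field, `theta1` its complement, so the fractions sum
#' to one in the slab. No acid initially.
#'
#' @inheritParams generate_correlated_field
#' @return A `biofilm_state`.
#' @export
init_random_field <- function(grid, corr_len, seed, z_top = 0.2) {
  f <- generate_correlated_field(grid, corr_len, seed, z_top)
  state <- new_state(grid)
  slab <- matrix(rep(grid$zc < z_top, each = grid$nx), grid$nx)
  state$theta2 <- f
  state$theta1[slab] <- 1 - f[slab]
  update_biofilm_mask(state)
}

#' Default superquadric patch set
#'
#' Four irregular species-2 clusters, numbered left to right, carved by
#' rotated superquadrics `|xi/a|^p + |zeta/b|^p <= 1`. The shapes are a
#' synthetic stand-in for confocal-image-like patch morphologies:
#' irregular blobs of varying roundness, size and orientation.
#'
#' @return A list of patch descriptors with fields `center`, `a`, `b`,
#'   `p`, `angle`.
#' @export
default_patches <- function() {
  list(
    list(center = c(0.125, 0.100), a = 0.070, b = 0.045, p = 2.5, angle = 0.4),
    list(center = c(0.375, 0.090), a = 0.060, b = 0.050, p = 4.0, angle = -0.3),
    list(center = c(0.625, 0.110), a = 0.075, b = 0.040, p = 3.0, angle = 0.9),
    list(center = c(0.875, 0.090), a = 0.055, b = 0.055, p = 2.0, angle = 0.0)
  )
}

#' Patch-shaped initial condition
#'
#' Species 2 (*Veillonella*) occupies pure (fraction one) patches
#' embedded in a pure species-1 matrix below the biofilm--fluid
#' interface, mimicking clusters of late colonizers inside an early
#' colonizer film. Each patch is a rotated superquadric
#' `|xi/a|^p + |zeta/b|^p <= 1` in its body frame.
#'
#' @param grid a [build_grid()] object.
#' @param patches list of patch descriptors (`center = c(x, z)`,
#'   semi-axes `a`, `b`, exponent `p`, rotation `angle`), or
#'   `"random"` to draw `n_patches` of them from documented ranges.
#' @param interface either a single height (flat interface) or a
#'   function of `X` returning the interface height.
#' @param n_patches,seed used only when `patches = "random"`: number of
#'   patches and the seed for their geometry (semi-axes 0.04--0.10,
#'   exponent 2--6, uniform rotation).
#' @return A `biofilm_state`.
#' @export
#' @examples
#' st <- init_patches(build_grid(50), interface = 0.2)
init_patches <- function(grid, patches = default_patches(),
                         interface = 0.2, n_patches = 4, seed = 1) {
  stopifnot(inherits(grid, "biofilm_grid"))
  hfun <- if (is.function(interface)) interface else function(X) {
    rep(interface, length(X))
  }
  h <- hfun(grid$xc)
  if (any(h <= 0) || any(h >= 1)) {
    stop("interface must lie strictly inside the domain", call. = FALSE)
  }
  if (identical(patches, "random")) {
    patches <- with_seed(seed, random_patches(n_patches, min(h)))
  }
  XX <- matrix(grid$xc, grid$nx, grid$nz)
  ZZ <- matrix(grid$zc, grid$nx, grid$nz, byrow = TRUE)
  inside_any <- matrix(FALSE, grid$nx, grid$nz)
  overlap <- FALSE
  for (pt in patches) {
    xi <- XX - pt$center[1]; ze <- ZZ - pt$center[2]
    c_ <- cos(pt$angle); s_ <- sin(pt$angle)
    bx <- c_ * xi + s_ * ze
    bz <- -s_ * xi + c_ * ze
    inside <- (abs(bx / pt$a)^pt$p + abs(bz / pt$b)^pt$p) <= 1
    top <- pt$center[2] + max(pt$a, pt$b)
    if (top > min(hfun(pmin(pmax(pt$center[1] + c(-1, 0, 1) * pt$a, 0), 1)))) {
      # conservative bound: the rotated patch could pierce the interface
      if (any(inside & (ZZ >= matrix(h, grid$nx, grid$nz)))) {
        stop("patch crosses the biofilm-fluid interface", call. = FALSE)
      }
    }
    if (overlap || any(inside & inside_any)) overlap <- TRUE
    inside_any <- inside_any | inside
  }
  if (overlap) warning("overlapping patches merged", call. = FALSE)
  below <- ZZ < matrix(h, grid$nx, grid$nz)
  state <- new_state(grid)
  state$theta2[inside_any & below] <- 1
  state$theta1[below & !inside_any] <- 1
  update_biofilm_mask(state)
}

random_patches <- function(n, h_min) {
  lapply(seq_len(n), function(i) {
    a <- stats::runif(1, 0.04, 0.10)
    b <- stats::runif(1, 0.04, 0.10)
    m <- max(a, b)
    list(center = c(stats::runif(1, m, 1 - m),
                    stats::runif(1, m, h_min - m - 0.01)),
         a = a, b = b,
         p = stats::runif(1, 2, 6),
         angle = stats::runif(1, 0, pi))
  })
}

#' Non-flat interface used by the patch scenario (case b)
#'
#' A gentle single-hump interface `Z = 0.25 + 0.05 sin(2 pi X + pi/2)`
#' staying above the default patch set everywhere.
#'
#' @return A function of `X`.
#' @export
wavy_patch_interface <- function() {
  function(X) 0.25 + 0.05 * sin(2 * pi * X + pi / 2)
}
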