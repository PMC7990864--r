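# Independent closed-form and brute-force oracles used by the solver
# tests. These never call the solver code paths they check.

# 1D column potential: chi'' = G on (0, h), chi'(0) = 0, chi(h) = 0
# => chi(Z) = G (Z^2 - h^2) / 2, u(Z) = chi' = G Z.
oracle_column_potential <- function(Z, G, h) G * (Z^2 - h^2) / 2
oracle_column_velocity <- function(Z, G) G * Z

# 1D saliva with first-order (linear) uptake phi^2 * S inside a slab
# 0 < Z < h, no biomass above, S(1) = 1, S'(0) = 0:
#   S = C cosh(phi Z)          in the slab
#   S = C cosh(phi h) + C phi sinh(phi h) (Z - h)   above
# with C fixed by S(1) = 1.
oracle_saliva_cosh <- function(Z, phi, h) {
  C <- 1 / (cosh(phi * h) + phi * sinh(phi * h) * (1 - h))
  ifelse(Z <= h,
         C * cosh(phi * Z),
         C * cosh(phi * h) + C * phi * sinh(phi * h) * (Z - h))
}

# 1D saliva with zeroth-order uptake r0 in the slab (S >> K):
# S'(Z) = r0 Z in the slab, r0 h above; S(1) = 1.
oracle_saliva_parabola <- function(Z, r0, h) {
  ifelse(Z <= h,
         1 - r0 * h * (1 - h) - r0 * (h^2 - Z^2) / 2,
         1 - r0 * h * (1 - Z))
}

# empirical e-folding correlation length of a field along x, averaged
# over rows (brute-force sample autocorrelation, periodic not assumed)
empirical_corr_length <- function(f, dx) {
  nx <- nrow(f)
  maxlag <- floor(nx / 2)
  ac <- vapply(seq_len(maxlag), function(r) {
    a <- f[seq_len(nx - r), , drop = FALSE]
    b <- f[r + seq_len(nx - r), , drop = FALSE]
    stats::cor(as.vector(a), as.vector(b))
  }, 0)
  ac <- c(1, ac)
  below <- which(ac < exp(-1))
  if (!length(below)) return(NA_real_)
  k <- below[1]
  # linear interpolation between lags k-2 and k-1 (0-based lags)
  f1 <- ac[k - 1]; f2 <- ac[k]
  ((k - 2) + (f1 - exp(-1)) / (f1 - f2)) * dx
}

# brute-force 4-connected component count of a logical matrix
count_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  for (i0 in seq_len(nrow(m))) for (j0 in seq_len(ncol(m))) {
    if (!m[i0, j0] || lab[i0, j0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            m[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  cur
}

mirror_x <- function(f) f[rev(seq_len(nrow(f))), , drop = FALSE]

# a uniform slab state: both species mixed 50/50 below z_top
make_slab_state <- function(grid, z_top = 0.2, frac1 = 0.5) {
  st <- new_state(grid)
  below <- matrix(rep(grid$zc < z_top, each = grid$nx), grid$nx)
  st$theta1[below] <- frac1
  st$theta2[below] <- 1 - frac1
  update_biofilm_mask(st)
}

table1_params <- function() biofilm_params()
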