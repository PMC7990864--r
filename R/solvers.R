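#' Solver settings
#'
#' @param dT dimensionless time step (default 1/200 of a day).
#' @param T_end final dimensionless time.
#' @param picard_tol relative-update tolerance of the Picard iteration
#'   for the nonlinear quasi-steady saliva solve.
#' @param picard_max maximum Picard sweeps before giving up.
#' @param cfl_max advective CFL bound per sub-step of the biomass
#'   transport (sub-stepping is automatic).
#' @param acid_bc `"noflow"` (batch system: acid accumulates) or
#'   `"dirichlet_top"` (acid removed instantly at the top boundary).
#' @param lin_tol tolerance used for residual sanity checks of the
#'   direct sparse linear solves.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dT = 1 / 200, T_end = 2,
                            picard_tol = 1e-8, picard_max = 100,
                            cfl_max = 0.5,
                            acid_bc = c("noflow", "dirichlet_top"),
                            lin_tol = 1e-10) {
  acid_bc <- match.arg(acid_bc)
  if (dT <= 0 || picard_tol <= 0 || lin_tol <= 0 ||
      cfl_max <= 0 || cfl_max > 1) {
    stop("invalid solver settings: dT and tolerances must be positive, cfl_max in (0, 1]",
         call. = FALSE)
  }
  structure(list(dT = dT, T_end = T_end, picard_tol = picard_tol,
                 picard_max = picard_max, cfl_max = cfl_max,
                 acid_bc = acid_bc, lin_tol = lin_tol),
            class = "solver_settings")
}

# ---- cached five-point Laplacian assembly -------------------------------

.lap_cache <- new.env(parent = emptyenv())

# Pure-Neumann negative Laplacian (-lap) on the full grid, plus the
# diagonal increment vector that turns the top edge into a Dirichlet
# boundary (ghost value at the boundary face, first/second order for a
# value imposed at the face center).
laplacian_parts <- function(grid) {
  key <- paste(grid$nx, grid$nz, sep = "x")
  if (!is.null(.lap_cache[[key]])) return(.lap_cache[[key]])
  nx <- grid$nx; nz <- grid$nz; n <- nx * nz
  ax <- 1 / grid$dx^2; az <- 1 / grid$dz^2
  idx <- matrix(seq_len(n), nx, nz)
  # x-direction interior faces
  kl <- as.vector(idx[-nx, ]); kr <- as.vector(idx[-1, ])
  # z-direction interior faces
  kb <- as.vector(idx[, -nz]); kt <- as.vector(idx[, -1])
  i <- c(kl, kr, kl, kr, kb, kt, kb, kt)
  j <- c(kl, kr, kr, kl, kb, kt, kt, kb)
  v <- c(rep(ax, 2 * length(kl)), rep(-ax, 2 * length(kl)),
         rep(az, 2 * length(kb)), rep(-az, 2 * length(kb)))
  L <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
  top_diag <- numeric(n)
  top_diag[idx[, nz]] <- 2 * az
  out <- list(L = L, top_diag = top_diag, idx = idx, n = n,
              ax = ax, az = az)
  .lap_cache[[key]] <- out
  out
}

solve_spd <- function(A, b) {
  as.numeric(Matrix::solve(Matrix::forceSymmetric(A), b))
}

# Direct sparse Cholesky with the symbolic factorization cached per
# sparsity pattern (the saliva and acid systems only change numerically
# between sweeps/steps). Falls back to a fresh analysis if the cached
# pattern no longer matches.
.fact_cache <- new.env(parent = emptyenv())

solve_spd_cached <- function(key, A, b) {
  A <- Matrix::forceSymmetric(A)
  ch <- .fact_cache[[key]]
  ch <- if (is.null(ch)) {
    Matrix::Cholesky(A, LDL = TRUE, super = TRUE, perm = TRUE)
  } else {
    tryCatch(update(ch, A),
             error = function(e) Matrix::Cholesky(A, LDL = TRUE, super = TRUE, perm = TRUE))
  }
  .fact_cache[[key]] <- ch
  as.numeric(Matrix::solve(ch, b))
}

# ---- quasi-steady saliva solve ------------------------------------------

#' Quasi-steady saliva (nutrient) solve
#'
#' Solves the stationary dimensionless diffusion--reaction equation
#' `-lap(S1) = -Theta11^2 theta1 F1 - Theta12^2 theta2 F2` with
#' `S1 = 1` on the top edge and no flux on the other three sides.
#' The Monod nonlinearity is resolved by Picard iteration: each sweep
#' freezes the saturation denominators at the previous iterate, which
#' makes the uptake linear in `S1` with a nonnegative coefficient and
#' preserves the discrete maximum principle (`0 <= S1 <= 1`).
#'
#' @param state a `biofilm_state` (uses `theta1`, `theta2`, `S2`; the
#'   stored `S1` warm-starts the iteration).
#' @param groups [nondimensionalize()] output.
#' @param grid,settings grid and [solver_settings()].
#' @param variant model variant (the acid factors enter the uptake).
#' @return The state with `S1` updated and `picard_iters` recorded.
#' @export
solve_saliva <- function(state, groups, grid, settings,
                         variant = "symbiotic") {
  lp <- laplacian_parts(grid)
  acid1 <- if (variant == "symbiotic") {
    groups$KL / (groups$KL + state$S2)
  } else 1
  acid2 <- if (variant == "symbiotic") {
    state$S2 / (groups$K22 + state$S2)
  } else 1
  c1 <- groups$Theta11_sq * state$theta1 * acid1
  c2 <- groups$Theta12_sq * state$theta2 * acid2
  b_dir <- lp$top_diag  # times the boundary value 1
  S <- as.vector(state$S1)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    q <- as.vector(c1 / (groups$K11 + S) + c2 / (groups$K21 + S))
    A <- lp$L + Matrix::Diagonal(lp$n, lp$top_diag + q)
    S_new <- solve_spd_cached(paste0("saliva_", grid$nx, "x", grid$nz), A, b_dir)
    rel <- sqrt(sum((S_new - S)^2)) / max(sqrt(sum(S_new^2)), 1e-300)
    S <- S_new
    if (rel < settings$picard_tol) break
    if (iter >= settings$picard_max) {
      stop(sprintf("saliva Picard iteration did not converge (last relative update %.3g)",
                   rel), call. = FALSE)
    }
  }
  if (min(S) < -1e-8 || max(S) > 1 + 1e-8) {
    stop("saliva solve violated the maximum principle [0, 1]", call. = FALSE)
  }
  state$S1 <- matrix(pmin(pmax(S, 0), 1), grid$nx, grid$nz)
  state$picard_iters <- iter
  state
}

# ---- growth potential and velocity --------------------------------------

#' Growth potential and velocity solve on the biofilm domain
#'
#' Solves the Poisson problem `lap(chi) = Psi1 theta1 F1 + Psi2 theta2
#' F2` on the biofilm cells only, with `chi = 0` imposed on the
#' biofilm--fluid interface (ghost value at the face between a biofilm
#' cell and a fluid cell) and zero normal derivative where the biofilm
#' touches the domain boundary. Face-normal velocities are the discrete
#' gradient of `chi` through each face, so the discrete divergence of
#' the velocity field equals the source cell by cell, which closes the
#' biomass ledger exactly. The velocity is identically zero outside the
#' biofilm.
#'
#' @inheritParams solve_saliva
#' @return The state with `chi`, `ux`, `uz` (cell-centered) and the
#'   face-velocity arrays `UxF` (`(nx+1) x nz`) and `UzF`
#'   (`nx x (nz+1)`) updated.
#' @export
solve_potential <- function(state, groups, grid, settings,
                            variant = "symbiotic") {
  nx <- grid$nx; nz <- grid$nz
  mask <- state$mask
  if (!any(mask)) {
    stop("degenerate domain: biofilm mask is empty", call. = FALSE)
  }
  mf <- monod_factors(state$S1, state$S2, groups, variant)
  src <- groups$Psi1 * state$theta1 * mf$F1 +
    groups$Psi2 * state$theta2 * mf$F2
  ax <- 1 / grid$dx^2; az <- 1 / grid$dz^2

  cells <- which(mask)                  # linear indices of biofilm cells
  m <- length(cells)
  loc <- integer(nx * nz); loc[cells] <- seq_len(m)
  ci <- (cells - 1L) %% nx + 1L         # x index
  cj <- (cells - 1L) %/% nx + 1L        # z index

  diagv <- numeric(m)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add_dir <- function(dix, diz, aa) {
    ni <- ci + dix; nj <- cj + diz
    inside <- ni >= 1L & ni <= nx & nj >= 1L & nj <= nz
    nk <- ifelse(inside, (nj - 1L) * nx + ni, NA_integer_)
    nb_in_mask <- inside & mask[pmax(nk, 1L)] & !is.na(nk)
    # neighbor in the biofilm: standard five-point coupling
    diagv[nb_in_mask] <<- diagv[nb_in_mask] + aa
    ii <<- c(ii, which(nb_in_mask))
    jj <<- c(jj, loc[nk[nb_in_mask]])
    vv <<- c(vv, rep(-aa, sum(nb_in_mask)))
    # neighbor is a fluid cell: interface face, chi = 0 at the face
    dirich <- inside & !nb_in_mask
    diagv[dirich] <<- diagv[dirich] + 2 * aa
    # neighbor outside the domain: no-flux (nothing to add)
    sum(dirich)
  }
  ndir <- add_dir(1L, 0L, ax) + add_dir(-1L, 0L, ax) +
    add_dir(0L, 1L, az) + add_dir(0L, -1L, az)
  if (ndir == 0L) {
    stop("topology error: biofilm mask touches no fluid interface",
         call. = FALSE)
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(m), ii), j = c(seq_len(m), jj),
                            x = c(diagv, vv), dims = c(m, m))
  chi_m <- solve_spd(A, -src[cells])    # -lap(chi) = -src
  chi <- matrix(0, nx, nz)
  chi[cells] <- chi_m

  # face-normal velocities u = grad(chi); zero on fluid-fluid and
  # domain-boundary faces
  UxF <- matrix(0, nx + 1, nz)
  UzF <- matrix(0, nx, nz + 1)
  mL <- mask[-nx, , drop = FALSE]; mR <- mask[-1, , drop = FALSE]
  gx <- matrix(0, nx - 1, nz)
  bb <- mL & mR
  gx[bb] <- (chi[-1, ][bb] - chi[-nx, ][bb]) / grid$dx
  lo <- mL & !mR   # interface on the right of a biofilm cell
  gx[lo] <- -2 * chi[-nx, ][lo] / grid$dx
  ro <- mR & !mL
  gx[ro] <- 2 * chi[-1, ][ro] / grid$dx
  UxF[2:nx, ] <- gx
  mB <- mask[, -nz, drop = FALSE]; mT <- mask[, -1, drop = FALSE]
  gz <- matrix(0, nx, nz - 1)
  bb <- mB & mT
  gz[bb] <- (chi[, -1][bb] - chi[, -nz][bb]) / grid$dz
  lo <- mB & !mT
  gz[lo] <- -2 * chi[, -nz][lo] / grid$dz
  ro <- mT & !mB
  gz[ro] <- 2 * chi[, -1][ro] / grid$dz
  UzF[, 2:nz] <- gz

  ux <- 0.5 * (UxF[-(nx + 1), ] + UxF[-1, ])
  uz <- 0.5 * (UzF[, -(nz + 1)] + UzF[, -1])
  ux[!mask] <- 0; uz[!mask] <- 0

  state$chi <- chi
  state$UxF <- UxF; state$UzF <- UzF
  state$ux <- ux; state$uz <- uz
  state
}

# Conservative first-order upwind flux divergence of a cell field given
# face velocities. Domain-boundary faces carry zero velocity (no-flow).
upwind_divergence <- function(f, UxF, UzF, grid) {
  nx <- grid$nx; nz <- grid$nz
  Fx <- matrix(0, nx + 1, nz)
  u <- UxF[2:nx, , drop = FALSE]
  Fx[2:nx, ] <- ifelse(u > 0, u * f[-nx, ], u * f[-1, ])
  Fz <- matrix(0, nx, nz + 1)
  w <- UzF[, 2:nz, drop = FALSE]
  Fz[, 2:nz] <- ifelse(w > 0, w * f[, -nz], w * f[, -1])
  (Fx[-1, ] - Fx[-(nx + 1), ]) / grid$dx +
    (Fz[, -1] - Fz[, -(nz + 1)]) / grid$dz
}

#' Biomass transport step
#'
#' Advances both volume fractions by one time step with conservative
#' first-order upwind advection by the growth flow and explicit Monod
#' growth sources. The step is automatically divided into sub-steps so
#' that each satisfies the CFL bound. Afterwards the fractions are
#' clipped to `[0, 1]` and, inside the biofilm, rescaled so their sum
#' does not exceed one; the applied correction is logged in the step
#' balance rather than hidden, and a correction beyond the overshoot
#' threshold aborts the run.
#'
#' @inheritParams solve_saliva
#' @return The state with `theta1`, `theta2` advanced and a `balance`
#'   record (mass change, integrated source, logged correction, per
#'   species) plus the step `cfl` attached.
#' @export
advance_biomass <- function(state, groups, grid, settings,
                            variant = "symbiotic") {
  dT <- settings$dT
  cfl <- dT * (max(abs(state$UxF)) / grid$dx + max(abs(state$UzF)) / grid$dz)
  nsub <- max(1, ceiling(cfl / settings$cfl_max))
  if (nsub > 1e6) {
    stop("advection blow-up: CFL sub-stepping exceeded 1e6 sub-steps",
         call. = FALSE)
  }
  dt <- dT / nsub
  t1 <- state$theta1; t2 <- state$theta2
  m1_0 <- field_integral(t1, grid); m2_0 <- field_integral(t2, grid)
  src1_int <- 0; src2_int <- 0
  for (s in seq_len(nsub)) {
    mf <- monod_factors(state$S1, state$S2, groups, variant)
    s1 <- groups$Psi1 * t1 * mf$F1
    s2 <- groups$Psi2 * t2 * mf$F2
    t1 <- t1 + dt * (s1 - upwind_divergence(t1, state$UxF, state$UzF, grid))
    t2 <- t2 + dt * (s2 - upwind_divergence(t2, state$UxF, state$UzF, grid))
    src1_int <- src1_int + dt * field_integral(s1, grid)
    src2_int <- src2_int + dt * field_integral(s2, grid)
  }
  # clip to [0, 1]; inside the biofilm rescale an excess sum back to one
  t1c <- pmin(pmax(t1, 0), 1)
  t2c <- pmin(pmax(t2, 0), 1)
  tot <- t1c + t2c
  over <- state$mask & (tot > 1)
  if (any(over)) {
    t1c[over] <- t1c[over] / tot[over]
    t2c[over] <- t2c[over] / tot[over]
  }
  corr_field <- abs(t1c - t1) + abs(t2c - t2)
  max_corr <- max(corr_field)
  # Cells on the interface band legitimately overfill as the front
  # sweeps through them (the logged fill-up correction); a correction
  # in the biofilm or fluid interior signals a genuine overshoot.
  core <- erode_mask(state$mask) | !dilate_mask(state$mask)
  max_core <- if (any(core)) max(corr_field[core]) else 0
  if (max_core > CLIP_ABORT) {
    stop(sprintf("advection overshoot: interior per-cell correction %.3g exceeds %g",
                 max_core, CLIP_ABORT), call. = FALSE)
  }
  corr1 <- field_integral(t1c - t1, grid)
  corr2 <- field_integral(t2c - t2, grid)
  state$theta1 <- t1c; state$theta2 <- t2c
  state$cfl <- cfl
  state$balance <- list(
    dm1 = field_integral(t1c, grid) - m1_0, src1 = src1_int, corr1 = corr1,
    dm2 = field_integral(t2c, grid) - m2_0, src2 = src2_int, corr2 = corr2,
    max_corr = max_corr
  )
  state
}

#' Lactic-acid transport step
#'
#' Advances the dimensionless acid concentration by one time step of
#' the advection--diffusion--reaction balance. Diffusion is implicit
#' (backward Euler; the acid diffusion number is large), advection by
#' the growth flow is explicit upwind, the production source
#' `Theta21^2 theta1 F1` is explicit, and the consumption sink is
#' linearized in the new concentration (`Theta22^2 theta2` times the
#' saliva Monod factor over the frozen saturation denominator), which
#' keeps the system an M-matrix and the concentration nonnegative at
#' the reference time step despite the stiffness of the sink. Boundary
#' conditions: no-flow on all four sides, or zero-value Dirichlet on
#' the top edge.
#'
#' @inheritParams solve_saliva
#' @return The state with `S2` advanced and an `acid_balance` record
#'   (mass change, production, consumption) attached.
#' @export
advance_acid <- function(state, groups, grid, settings,
                         variant = "symbiotic") {
  lp <- laplacian_parts(grid)
  dT <- settings$dT
  mf <- monod_factors(state$S1, state$S2, groups, variant)
  prod <- groups$Theta21_sq * state$theta1 * mf$F1
  cons_coef <- if (variant == "symbiotic") {
    groups$Theta22_sq * state$theta2 *
      (state$S1 / (groups$K21 + state$S1)) / (groups$K22 + state$S2)
  } else {
    matrix(0, grid$nx, grid$nz)   # r22 = 0: acid accumulates
  }
  adv <- upwind_divergence(state$S2, state$UxF, state$UzF, grid)
  diag_extra <- switch(settings$acid_bc,
                       noflow = 0,
                       dirichlet_top = lp$top_diag * groups$D2_star)
  A <- groups$D2_star * lp$L +
    Matrix::Diagonal(lp$n, 1 / dT + as.vector(cons_coef) + diag_extra)
  b <- as.vector(state$S2) / dT + as.vector(prod) - as.vector(adv)
  S2 <- solve_spd_cached(paste0("acid_", settings$acid_bc, "_", grid$nx, "x",
                                grid$nz), A, b)
  if (min(S2) < -1e-10) {
    stop(sprintf("acid positivity violated (min S2 = %.3g)", min(S2)),
         call. = FALSE)
  }
  S2m <- matrix(pmax(S2, 0), grid$nx, grid$nz)
  state$acid_balance <- list(
    dm = field_integral(S2m - state$S2, grid),
    prod = dT * field_integral(prod, grid),
    cons = dT * field_integral(cons_coef * S2m, grid)
  )
  state$S2 <- S2m
  state
}

#' One operator-split time step
#'
#' Advances the coupled system by one time step in a fixed order:
#' quasi-steady saliva solve, growth-potential/velocity solve, biomass
#' advection, biofilm-mask refresh, acid transport. The saliva solve
#' precedes the potential solve because the growth sources depend on
#' it; the acid step comes last because the updated acid only feeds
#' back on the kinetics at the next step.
#'
#' When the advective CFL number of the full step exceeds `cfl_max`,
#' the saliva/potential/biomass/mask sequence is subcycled at the CFL
#' bound, so the growth velocity field and the biofilm mask are
#' refreshed as the front advances; without the refresh, cells just
#' ahead of the front would have no outflow faces yet and overfill.
#' The acid transport is advanced once over the whole step.
#'
#' @inheritParams solve_saliva
#' @return The advanced state (`T` incremented by `dT`).
#' @export
step_biofilm <- function(state, groups, grid, settings,
                         variant = "symbiotic") {
  if (!any(state$mask)) {
    stop("degenerate domain: cannot step a state with no biofilm cells",
         call. = FALSE)
  }
  remaining <- settings$dT
  sub <- settings
  agg <- list(max_corr = 0, dm1 = 0, src1 = 0, corr1 = 0,
              dm2 = 0, src2 = 0, corr2 = 0)
  cfl_step <- 0
  picard_total <- 0L
  guard <- 0L
  while (remaining > 1e-14) {
    guard <- guard + 1L
    if (guard > 1e6) {
      stop("advection blow-up: step subcycling exceeded 1e6 sub-steps",
           call. = FALSE)
    }
    if (any(state$mask[, grid$nz])) break  # film reached the top boundary
    state <- solve_saliva(state, groups, grid, settings, variant)
    picard_total <- picard_total + state$picard_iters
    state <- solve_potential(state, groups, grid, settings, variant)
    speed <- max(abs(state$UxF)) / grid$dx + max(abs(state$UzF)) / grid$dz
    dt_sub <- if (speed > 0) min(remaining, settings$cfl_max / speed) else remaining
    sub$dT <- dt_sub
    state <- advance_biomass(state, groups, grid, sub, variant)
    state <- update_biofilm_mask(state)
    b <- state$balance
    agg$max_corr <- max(agg$max_corr, b$max_corr)
    for (nm in c("dm1", "src1", "corr1", "dm2", "src2", "corr2")) {
      agg[[nm]] <- agg[[nm]] + b[[nm]]
    }
    cfl_step <- max(cfl_step, state$cfl)
    remaining <- remaining - dt_sub
  }
  state$balance <- agg
  state$cfl <- cfl_step
  state$picard_iters <- picard_total
  state <- advance_acid(state, groups, grid, settings, variant)
  state$T <- state$T + settings$dT
  state
}

#' Run a full biofilm growth simulation
#'
#' Iterates [step_biofilm()] from an initial state to `T_end`,
#' recording a per-step time series and field snapshots at a fixed
#' cadence. Fully deterministic: the solver itself draws no random
#' numbers.
#'
#' @param init initial `biofilm_state` (see [init_mixed()],
#'   [init_random_field()], [init_patches()]).
#' @param params [biofilm_params()] object.
#' @param grid a [build_grid()] object matching `init`.
#' @param settings a [solver_settings()] object.
#' @param variant `"symbiotic"` or `"competitive"`.
#' @param cadence snapshot spacing in dimensionless time (snapshots are
#'   taken whenever `T` is within half a step of a multiple).
#' @param snapshots keep full field snapshots (set `FALSE` to retain
#'   only the time series and the final state).
#' @param verbose print a progress line per snapshot.
#' @return A `biofilm_trajectory`: list with `series` (data.frame of
#'   per-step diagnostics), `snapshots` (named list of states),
#'   `final`, and the run metadata.
#' @export
#' @examples
#' \donttest{
#' traj <- run_simulation(init_mixed(build_grid(32)),
#'                        settings = solver_settings(dT = 0.02, T_end = 0.1),
#'                        grid = build_grid(32))
#' summary(traj)
#' }
run_simulation <- function(init,
                           params = biofilm_params(),
                           grid = build_grid(200, 200),
                           settings = solver_settings(),
                           variant = "symbiotic",
                           cadence = 0.1,
                           snapshots = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(init, "biofilm_state"))
  variant <- model_variant(variant)
  groups <- nondimensionalize(params)
  state <- update_biofilm_mask(init)
  n_steps <- round(settings$T_end / settings$dT)
  rows <- vector("list", n_steps + 1L)
  snaps <- list()
  grab <- function(state) {
    if (snapshots) {
      snaps[[sprintf("T=%.6g", state$T)]] <<- state
      if (verbose) message(sprintf("snapshot at T = %.4g (thickness %.4g)",
                                   state$T,
                                   sum(state$mask) / length(state$mask)))
    }
  }
  series_row <- function(state) {
    data.frame(
      T = state$T,
      mean_thickness = sum(state$mask) * grid$dx * grid$dz,
      mass1 = field_integral(state$theta1, grid),
      mass2 = field_integral(state$theta2, grid),
      S2_max = max(state$S2),
      S2_mean = mean(state$S2),
      picard_iters = if (is.null(state$picard_iters)) NA_integer_ else state$picard_iters,
      cfl = if (is.null(state$cfl)) NA_real_ else state$cfl,
      clip = if (is.null(state$balance)) NA_real_ else state$balance$max_corr
    )
  }
  rows[[1L]] <- series_row(state)
  grab(state)
  near_multiple <- function(T, cad) {
    abs(T / cad - round(T / cad)) < 1e-9 && round(T / cad) > 0
  }
  terminated <- NULL
  for (k in seq_len(n_steps)) {
    if (any(state$mask[, grid$nz])) {
      # The biofilm has reached the nutrient boundary: the fluid layer
      # above the film -- and with it the free-boundary geometry the
      # model is built on -- no longer exists. Stop cleanly and return
      # the partial trajectory.
      terminated <- sprintf("biofilm reached the top boundary at T = %.5g",
                            state$T)
      break
    }
    state <- tryCatch(
      step_biofilm(state, groups, grid, settings, variant),
      error = function(e) {
        stop(sprintf("step %d (T = %.5g): %s", k,
                     (k - 1) * settings$dT, conditionMessage(e)),
             call. = FALSE)
      })
    rows[[k + 1L]] <- series_row(state)
    if (near_multiple(state$T, cadence)) grab(state)
  }
  structure(list(
    series = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
    snapshots = snaps,
    final = state,
    terminated = terminated,
    params = params, groups = groups, grid = grid,
    settings = settings, variant = variant
  ), class = "biofilm_trajectory")
}

#' @export
print.biofilm_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf("Biofilm trajectory (%s model): %d steps to T = %.4g on a %d x %d grid\n",
              x$variant, nrow(s) - 1L, max(s$T), x$grid$nx, x$grid$nz))
  if (!is.null(x$terminated)) cat("  terminated early:", x$terminated, "\n")
  cat(sprintf("  mean thickness %.4g -> %.4g\n",
              s$mean_thickness[1], s$mean_thickness[nrow(s)]))
  cat(sprintf("  species mass   %.4g/%.4g -> %.4g/%.4g (1/2)\n",
              s$mass1[1], s$mass2[1], s$mass1[nrow(s)], s$mass2[nrow(s)]))
  cat(sprintf("  %d snapshots retained\n", length(x$snapshots)))
  invisible(x)
}

#' @export
summary.biofilm_trajectory <- function(object, ...) {
  s <- object$series
  out <- list(
    variant = object$variant,
    T_end = max(s$T),
    thickness = range(s$mean_thickness),
    growth1 = s$mass1[nrow(s)] - s$mass1[1],
    growth2 = s$mass2[nrow(s)] - s$mass2[1],
    S2_max = max(s$S2_max),
    max_cfl = max(s$cfl, na.rm = TRUE),
    max_clip = max(s$clip, na.rm = TRUE),
    max_picard = max(s$picard_iters, na.rm = TRUE)
  )
  class(out) <- "summary.biofilm_trajectory"
  out
}

#' @export
print.summary.biofilm_trajectory <- function(x, ...) {
  cat(sprintf("%s run to T = %.4g\n", x$variant, x$T_end))
  cat(sprintf("  thickness %.4g -> %.4g\n", x$thickness[1], x$thickness[2]))
  cat(sprintf("  biomass gained: species 1 %.4g, species 2 %.4g\n",
              x$growth1, x$growth2))
  cat(sprintf("  peak acid %.4g; max CFL %.3g; max clip %.3g; max Picard sweeps %d\n",
              x$S2_max, x$max_cfl, x$max_clip, x$max_picard))
  invisible(x)
}

#' @export
plot.biofilm_trajectory <- function(x, which = c("thickness", "mass", "acid"),
                                    ...) {
  which <- match.arg(which)
  s <- x$series
  switch(which,
    thickness = graphics::plot(s$T, s$mean_thickness, type = "l",
                               xlab = "T", ylab = "mean thickness", ...),
    mass = {
      graphics::matplot(s$T, cbind(s$mass1, s$mass2), type = "l",
                        lty = 1, col = c(2, 3),
                        xlab = "T", ylab = "dimensionless mass", ...)
      graphics::legend("topleft", c("Streptococcus", "Veillonella"),
                       col = c(2, 3), lty = 1, bty = "n")
    },
    acid = graphics::plot(s$T, s$S2_max, type = "l",
                          xlab = "T", ylab = "max S2", ...))
  invisible(x)
}
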