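#' Homogenization mass-difference statistic
#'
#' Scaled distance between a scenario's *Veillonella* fraction field
#' and the evenly mixed reference: `(1/N) * ||theta2_mixed -
#' theta2_case||` with the Euclidean norm over the `N` cell values.
#' Both solutions live on the same fixed Eulerian grid over the whole
#' domain, which sidesteps the moving-domain mismatch. A decreasing
#' value means the heterogeneous solution approaches the homogenized
#' reference.
#'
#' @param theta2_case,theta2_mixed species-2 fraction fields on the
#'   same grid (matrices of identical shape).
#' @return Nonnegative scalar; zero iff the fields are identical.
#' @export
mass_difference <- function(theta2_case, theta2_mixed) {
  if (!identical(dim(theta2_case), dim(theta2_mixed))) {
    stop("fields must share the same grid shape", call. = FALSE)
  }
  sqrt(sum((theta2_mixed - theta2_case)^2)) / length(theta2_case)
}

#' Vertical profiles along a column
#'
#' Extracts the depth profiles of both volume fractions, their total,
#' and the acid concentration along the cell column nearest to `X`.
#'
#' @param state a `biofilm_state`.
#' @param grid its grid.
#' @param X horizontal coordinate in `(0, 1)`.
#' @return A data.frame with columns `Z`, `theta1`, `theta2`,
#'   `theta_total`, `S2`.
#' @export
profile_at_x <- function(state, grid, X = 0.5) {
  if (X <= 0 || X >= 1) stop("X must lie inside (0, 1)", call. = FALSE)
  i <- which.min(abs(grid$xc - X))
  data.frame(
    Z = grid$zc,
    theta1 = state$theta1[i, ],
    theta2 = state$theta2[i, ],
    theta_total = state$theta1[i, ] + state$theta2[i, ],
    S2 = state$S2[i, ]
  )
}

trajectory_thickness_at <- function(traj, T) {
  s <- traj$series
  k <- which(abs(s$T - T) < 1e-9)
  if (length(k) != 1L) {
    stop(sprintf("no recorded time matches T = %g", T), call. = FALSE)
  }
  s$mean_thickness[k]
}

#' Relative thickness reduction between two runs
#'
#' `100 * (h_ref(T) - h_alt(T)) / h_ref(T)` from the mean-thickness
#' series, e.g. to quantify how much slower the film grows when the
#' acid is removed at the top boundary instead of accumulating.
#'
#' @param traj_ref,traj_alt two `biofilm_trajectory` objects whose
#'   series contain the requested time.
#' @param T dimensionless time at which to compare.
#' @return Percentage (positive when the alternative film is thinner).
#' @export
thickness_reduction <- function(traj_ref, traj_alt, T) {
  h_ref <- trajectory_thickness_at(traj_ref, T)
  h_alt <- trajectory_thickness_at(traj_alt, T)
  100 * (h_ref - h_alt) / h_ref
}

#' Homogenization curve of a scenario against the mixed reference
#'
#' Evaluates [mass_difference()] at every snapshot time the two
#' trajectories share, and reports the first time the statistic drops
#' below a threshold (if one is given).
#'
#' @param traj_case,traj_mixed trajectories with matching snapshot
#'   cadence.
#' @param threshold optional homogenization threshold on the statistic.
#' @return A data.frame with columns `T`, `M_diff`; if `threshold` is
#'   given, the first-crossing time is attached as attribute
#'   `t_homogenized` (`NA` if never crossed).
#' @export
homogenization_curve <- function(traj_case, traj_mixed, threshold = NULL) {
  common <- intersect(names(traj_case$snapshots), names(traj_mixed$snapshots))
  if (length(common) == 0L) {
    stop("trajectories share no snapshot times", call. = FALSE)
  }
  Tvals <- vapply(common, function(nm) traj_case$snapshots[[nm]]$T, 0)
  ord <- order(Tvals)
  md <- vapply(common, function(nm) {
    mass_difference(traj_case$snapshots[[nm]]$theta2,
                    traj_mixed$snapshots[[nm]]$theta2)
  }, 0)
  out <- data.frame(T = Tvals[ord], M_diff = md[ord], row.names = NULL)
  if (!is.null(threshold)) {
    hit <- which(out$M_diff < threshold)
    attr(out, "t_homogenized") <- if (length(hit)) out$T[hit[1L]] else NA_real_
  }
  out
}

#' Closed-contour persistence of the species-2 fraction
#'
#' Reports whether closed level-set contours of the *Veillonella*
#' fraction survive in a state: a patch that has homogenized below the
#' level no longer supports a closed contour. Contours touching the
#' domain boundary are not counted as closed.
#'
#' @param state a `biofilm_state`.
#' @param grid its grid.
#' @param level contour level (default 0.6).
#' @return A list with `n_closed`, `n_total` and the contour polylines.
#' @export
contour_persistence <- function(state, grid, level = 0.6) {
  cl <- grDevices::contourLines(grid$xc, grid$zc, state$theta2,
                                levels = level)
  closed <- vapply(cl, function(s) {
    length(s$x) > 2 &&
      abs(s$x[1] - s$x[length(s$x)]) < 1e-12 &&
      abs(s$y[1] - s$y[length(s$y)]) < 1e-12
  }, TRUE)
  list(n_closed = sum(closed), n_total = length(cl),
       contours = lapply(cl, function(s) data.frame(X = s$x, Z = s$y)))
}

#' Maximum interface-normal growth speed and Péclet number
#'
#' The growth speed of the biofilm front is measured from the
#' mean-thickness series as the largest per-step advance rate
#' `dh/dT` over the run. The corresponding Péclet number for acid
#' transport is `Pe = u_max H / D2` with the dimensional speed
#' `u_max = U_max H / t_d`, i.e. `Pe = U_max / D2_star`.
#'
#' @param traj a `biofilm_trajectory`.
#' @param window width (in dimensionless time) of the differencing
#'   window; the mean thickness advances in whole-cell increments, so a
#'   one-step derivative only measures the grid quantization.
#' @return A list with `U_max` (dimensionless front speed), `u_max`
#'   (dimensional, m/s) and `Pe`.
#' @export
peclet_number <- function(traj, window = 0.1) {
  s <- traj$series
  k <- max(1L, round(window / mean(diff(s$T))))
  n <- nrow(s)
  if (n <= k) k <- n - 1L
  U_max <- max((s$mean_thickness[(1 + k):n] - s$mean_thickness[1:(n - k)]) /
                 (s$T[(1 + k):n] - s$T[1:(n - k)]))
  groups <- traj$groups
  p <- traj$params
  list(U_max = U_max,
       u_max = U_max * p$H / p$t_d,
       Pe = U_max / groups$D2_star)
}
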