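#' Build a cell-centered structured grid on the unit square
#'
#' The solver works entirely in dimensionless coordinates: the physical
#' domain is mapped to the unit square, `X` horizontal and `Z` vertical
#' (increasing upward, the nutrient boundary is the `Z = 1` edge).
#' Fields are stored as `nx` by `nz` matrices with the `X` index first.
#'
#' @param nx,nz number of cells in the `X` and `Z` direction (`>= 8`).
#' @return An object of class `biofilm_grid`: a list with `nx`, `nz`,
#'   spacings `dx = 1/nx`, `dz = 1/nz` and cell-center coordinate
#'   vectors `xc`, `zc`.
#' @export
#' @examples
#' g <- build_grid(200, 200)
#' g$dx            # 0.005
build_grid <- function(nx, nz = nx) {
  if (!is.numeric(nx) || !is.numeric(nz) || nx < 8 || nz < 8 ||
      nx != round(nx) || nz != round(nz)) {
    stop("nx and nz must be integers >= 8", call. = FALSE)
  }
  nx <- as.integer(nx); nz <- as.integer(nz)
  structure(list(
    nx = nx, nz = nz,
    dx = 1 / nx, dz = 1 / nz,
    xc = (seq_len(nx) - 0.5) / nx,
    zc = (seq_len(nz) - 0.5) / nz
  ), class = "biofilm_grid")
}

#' @export
print.biofilm_grid <- function(x, ...) {
  cat(sprintf("Structured grid: %d x %d cells on the unit square (dx = %g, dz = %g)\n",
              x$nx, x$nz, x$dx, x$dz))
  invisible(x)
}

# Tolerance on the sum-to-one constraint inside the biofilm; per-cell
# corrections above CLIP_ABORT signal an advection overshoot and abort.
EPS_SUM <- 1e-6
CLIP_ABORT <- 1e-3

#' Create an empty simulation state on a grid
#'
#' @param grid a [build_grid()] object.
#' @return A `biofilm_state`: matrices `theta1`, `theta2` (volume
#'   fractions), `S1`, `S2` (dimensionless concentrations), `chi`
#'   (growth potential), `ux`, `uz` (cell-centered velocity), logical
#'   `mask` (biofilm membership), and scalar time `T`.
#' @export
new_state <- function(grid) {
  stopifnot(inherits(grid, "biofilm_grid"))
  z <- matrix(0, grid$nx, grid$nz)
  structure(list(
    theta1 = z, theta2 = z,
    S1 = z + 1, S2 = z,
    chi = z, ux = z, uz = z,
    mask = z > 1,  # all FALSE
    T = 0
  ), class = "biofilm_state")
}

#' @export
print.biofilm_state <- function(x, ...) {
  cat(sprintf("Biofilm state at T = %.4g\n", x$T))
  cat(sprintf("  grid %d x %d, biofilm cells: %d (area %.4g)\n",
              nrow(x$theta1), ncol(x$theta1), sum(x$mask),
              sum(x$mask) / length(x$mask)))
  cat(sprintf("  theta1 in [%.3g, %.3g], theta2 in [%.3g, %.3g]\n",
              min(x$theta1), max(x$theta1), min(x$theta2), max(x$theta2)))
  cat(sprintf("  S1 in [%.3g, %.3g], S2 in [%.3g, %.3g]\n",
              min(x$S1), max(x$S1), min(x$S2), max(x$S2)))
  invisible(x)
}

#' Recompute the biofilm membership mask
#'
#' A cell belongs to the biofilm domain when its total biomass volume
#' fraction reaches one half; the complement is the bulk-fluid region.
#' The mask is refreshed after every biomass transport step so that
#' cells filled past the threshold by the growth flow join the biofilm.
#'
#' @param state a `biofilm_state`.
#' @return The state with an updated `mask`.
#' @export
update_biofilm_mask <- function(state) {
  state$mask <- (state$theta1 + state$theta2) >= 0.5
  state
}

#' Interface geometry and mean biofilm thickness
#'
#' Extracts the biofilm--fluid interface as the 0.5 level set of the
#' total volume fraction (sub-cell bilinear contouring) together with
#' per-column heights and the mean thickness, defined as the biofilm
#' area divided by the (unit) domain width so that it is exactly the
#' volume-equivalent thickness.
#'
#' @param state a `biofilm_state` with a non-empty mask.
#' @param grid the grid the state lives on.
#' @return A list of class `interface_geometry`: `polylines` (list of
#'   data.frames with `X`, `Z`), `height` (per-column interface height,
#'   length `nx`), `mean_thickness` (scalar).
#' @export
interface_geometry <- function(state, grid) {
  stopifnot(inherits(state, "biofilm_state"), inherits(grid, "biofilm_grid"))
  if (!any(state$mask)) {
    stop("degenerate domain: biofilm mask is empty", call. = FALSE)
  }
  tot <- state$theta1 + state$theta2
  cl <- grDevices::contourLines(grid$xc, grid$zc, tot, levels = 0.5)
  polylines <- lapply(cl, function(s) data.frame(X = s$x, Z = s$y))
  # per-column height: topmost 0.5 crossing, sub-cell linear interpolation
  height <- apply(tot, 1L, function(col) column_height(col, grid$zc, grid$dz))
  structure(list(
    polylines = polylines,
    height = height,
    mean_thickness = sum(state$mask) * grid$dx * grid$dz
  ), class = "interface_geometry")
}

column_height <- function(col, zc, dz) {
  above <- col >= 0.5
  if (!any(above)) return(0)
  j <- max(which(above))          # topmost cell still in the biofilm
  if (j == length(col)) return(1)
  # interpolate between cell centers j and j+1 for the 0.5 crossing
  f <- (col[j] - 0.5) / (col[j] - col[j + 1L])
  zc[j] + f * dz
}

# total dimensionless mass (area integral) of a field
field_integral <- function(f, grid) sum(f) * grid$dx * grid$dz

# 4-neighborhood erosion / dilation of a logical mask (domain-boundary
# neighbors treated as replicating the edge)
erode_mask <- function(m) {
  nx <- nrow(m); nz <- ncol(m)
  m & m[c(1, seq_len(nx - 1)), ] & m[c(seq_len(nx - 1) + 1, nx), ] &
    m[, c(1, seq_len(nz - 1))] & m[, c(seq_len(nz - 1) + 1, nz)]
}

dilate_mask <- function(m) {
  nx <- nrow(m); nz <- ncol(m)
  m | m[c(1, seq_len(nx - 1)), ] | m[c(seq_len(nx - 1) + 1, nx), ] |
    m[, c(1, seq_len(nz - 1))] | m[, c(seq_len(nz - 1) + 1, nz)]
}

#' Validate the physical bounds of a simulation state
#'
#' Checks the invariants that every state must satisfy: fractions in
#' `[0, 1]` with their sum at most one (up to a small tolerance), `S1`
#' in `[0, 1]`, `S2 >= 0`, and zero velocity outside the biofilm.
#'
#' @param state a `biofilm_state`.
#' @param tol slack on the bounds.
#' @return `TRUE` invisibly; stops with a diagnostic otherwise.
#' @export
check_state <- function(state, tol = EPS_SUM) {
  t1 <- state$theta1; t2 <- state$theta2
  if (min(t1) < -tol || max(t1) > 1 + tol ||
      min(t2) < -tol || max(t2) > 1 + tol) {
    stop("volume fraction out of [0, 1]", call. = FALSE)
  }
  if (max(t1 + t2) > 1 + tol) {
    stop("volume fractions exceed unit sum", call. = FALSE)
  }
  if (min(state$S1) < -1e-8 || max(state$S1) > 1 + 1e-8) {
    stop("S1 violates the maximum principle bounds [0, 1]", call. = FALSE)
  }
  if (min(state$S2) < -1e-10) {
    stop("S2 negative beyond tolerance", call. = FALSE)
  }
  out <- !state$mask
  if (any(abs(state$ux[out]) > 0) || any(abs(state$uz[out]) > 0)) {
    stop("nonzero velocity outside the biofilm domain", call. = FALSE)
  }
  invisible(TRUE)
}

#' Plot a simulation state
#'
#' Draws one of the state fields as a filled image with the
#' biofilm--fluid interface overlaid.
#'
#' @param x a `biofilm_state`.
#' @param grid the grid; reconstructed from the field shape if omitted.
#' @param field which field to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.biofilm_state <- function(x, grid = NULL,
                               field = c("theta2", "theta1", "S1", "S2",
                                         "total"),
                               ...) {
  field <- match.arg(field)
  if (is.null(grid)) grid <- build_grid(nrow(x$theta1), ncol(x$theta1))
  f <- switch(field, total = x$theta1 + x$theta2, x[[field]])
  graphics::image(grid$xc, grid$zc, f, xlab = "X", ylab = "Z",
                  main = sprintf("%s at T = %.3g", field, x$T),
                  useRaster = TRUE, ...)
  if (any(x$mask)) {
    ig <- interface_geometry(x, grid)
    for (p in ig$polylines) graphics::lines(p$X, p$Z, col = "white", lwd = 2)
  }
  invisible(x)
}
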