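# Run configuration: a single human-readable YAML file with SI units
# for the dimensional block; everything is nondimensionalized at the
# configuration boundary and the solver never sees dimensional values.

config_blocks <- c("parameters", "grid", "solver", "initial", "variant",
                   "output", "seed")

config_defaults <- function() {
  list(
    parameters = unclass(biofilm_params()),
    grid = list(nx = 200L, nz = 200L),
    solver = list(dT = 1 / 200, T_end = 2, picard_tol = 1e-8,
                  picard_max = 100L, cfl_max = 0.5, acid_bc = "noflow",
                  lin_tol = 1e-10),
    initial = list(variant = "mixed", mean = 0.1, amplitude = 0.05,
                   wavenumber = 4 * pi, phase = pi / 2, frac1 = 0.5),
    variant = "symbiotic",
    output = list(dir = "biofilm-out", cadence = 0.1, snapshots = TRUE,
                  formats = c("csv", "vtk", "json")),
    seed = 1L
  )
}

initial_keys <- list(
  mixed = c("variant", "mean", "amplitude", "wavenumber", "phase", "frac1"),
  random_field = c("variant", "corr_len", "z_top"),
  patches = c("variant", "interface", "patches", "n_patches")
)

merge_block <- function(default, given, block) {
  if (is.null(given)) return(default)
  unknown <- setdiff(names(given), names(default))
  if (length(unknown)) {
    stop(sprintf("unknown key%s in '%s' block: %s",
                 if (length(unknown) > 1) "s" else "", block,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  utils::modifyList(default, given)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, applies the documented defaults, rejects
#' unknown keys, validates every field (the physical block through
#' [biofilm_params()], the solver block through [solver_settings()])
#' and returns a fully resolved configuration. The shipped default file
#' (`system.file("extdata", "baseline.yaml", package = "symbiofilm")`)
#' reproduces the reference setup: the default parameter table, the
#' sinusoidal evenly mixed initial condition, a 200 x 200 grid, a time
#' step of 1/200 day, the symbiotic variant and the no-flow acid
#' boundary.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `biofilm_config`: the normalized
#'   configuration list plus constructed `params` and `settings`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), config_blocks)
  if (length(unknown)) {
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  def <- config_defaults()
  cfg <- def
  cfg$parameters <- merge_block(def$parameters, raw$parameters, "parameters")
  cfg$grid <- merge_block(def$grid, raw$grid, "grid")
  cfg$solver <- merge_block(def$solver, raw$solver, "solver")
  if (!is.null(raw$variant)) cfg$variant <- model_variant(raw$variant)
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  if (!is.null(raw$output)) {
    cfg$output <- merge_block(def$output, raw$output, "output")
  }
  iv <- if (is.null(raw$initial$variant)) "mixed" else raw$initial$variant
  if (!iv %in% names(initial_keys)) {
    stop("initial.variant must be one of: ",
         paste(names(initial_keys), collapse = ", "), call. = FALSE)
  }
  init_def <- switch(iv,
    mixed = def$initial,
    random_field = list(variant = "random_field", corr_len = 0.02,
                        z_top = 0.2),
    patches = list(variant = "patches", interface = 0.2,
                   patches = "default", n_patches = 4L))
  cfg$initial <- merge_block(init_def, raw$initial, "initial")
  cfg$initial$variant <- iv

  params <- tryCatch(do.call(biofilm_params, cfg$parameters),
                     error = function(e) {
                       stop("invalid 'parameters' block: ",
                            conditionMessage(e), call. = FALSE)
                     })
  settings <- do.call(solver_settings,
                      cfg$solver[setdiff(names(cfg$solver), character(0))])
  structure(list(raw = cfg, params = params, settings = settings),
            class = "biofilm_config")
}

#' Serialize a configuration back to YAML
#'
#' Writing and re-reading a configuration is the identity on the
#' normalized representation (round-trip contract).
#'
#' @param config a `biofilm_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "biofilm_config"))
  yaml::write_yaml(config$raw, path, precision = 15L)
  invisible(path)
}

#' Build the initial state described by a configuration
#'
#' @param config a `biofilm_config`.
#' @param grid optional pre-built grid (defaults to the configured one).
#' @return A `biofilm_state`.
#' @export
initial_state_from_config <- function(config, grid = NULL) {
  stopifnot(inherits(config, "biofilm_config"))
  ic <- config$raw$initial
  if (is.null(grid)) {
    grid <- build_grid(config$raw$grid$nx, config$raw$grid$nz)
  }
  switch(ic$variant,
    mixed = init_mixed(grid, mean = ic$mean, amplitude = ic$amplitude,
                       wavenumber = ic$wavenumber, phase = ic$phase,
                       frac1 = ic$frac1),
    random_field = init_random_field(grid, corr_len = ic$corr_len,
                                     seed = config$raw$seed,
                                     z_top = ic$z_top),
    patches = {
      iface <- ic$interface
      if (identical(iface, "wavy")) iface <- wavy_patch_interface()
      patches <- ic$patches
      if (identical(patches, "default")) patches <- default_patches()
      init_patches(grid, patches = patches, interface = iface,
                   n_patches = ic$n_patches, seed = config$raw$seed)
    })
}

#' Run the simulation described by a configuration
#'
#' @param config a `biofilm_config` (see [load_config()]).
#' @param snapshots,verbose passed to [run_simulation()].
#' @return A `biofilm_trajectory`.
#' @export
run_config <- function(config, snapshots = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "biofilm_config"))
  grid <- build_grid(config$raw$grid$nx, config$raw$grid$nz)
  init <- initial_state_from_config(config, grid)
  run_simulation(init, params = config$params, grid = grid,
                 settings = config$settings, variant = config$raw$variant,
                 cadence = config$raw$output$cadence,
                 snapshots = snapshots, verbose = verbose)
}

#' Write a state as a legacy-ASCII VTK structured-points file
#'
#' One file per snapshot; scalar fields `theta1`, `theta2`, `S1`, `S2`,
#' `chi` and the cell-centered velocity vector.
#'
#' @param state a `biofilm_state`.
#' @param grid its grid.
#' @param path output file (conventionally `.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("biofilm state T=%.8g", state$T),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$nz),
               sprintf("ORIGIN %.10g %.10g 0", grid$dx / 2, grid$dz / 2),
               sprintf("SPACING %.10g %.10g 1", grid$dx, grid$dz),
               sprintf("POINT_DATA %d", grid$nx * grid$nz)), con)
  scalar <- function(name, f) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(f), digits = 10, scientific = TRUE,
                      trim = TRUE), con)
  }
  scalar("theta1", state$theta1)
  scalar("theta2", state$theta2)
  scalar("S1", state$S1)
  scalar("S2", state$S2)
  scalar("chi", state$chi)
  writeLines("VECTORS velocity double", con)
  writeLines(paste(format(as.vector(state$ux), digits = 10, trim = TRUE),
                   format(as.vector(state$uz), digits = 10, trim = TRUE),
                   "0"), con)
  invisible(path)
}

#' Export interface polylines as CSV
#'
#' @param state,grid state and grid.
#' @param path output CSV (columns `piece`, `X`, `Z`).
#' @return `path`, invisibly.
#' @export
write_interface_csv <- function(state, grid, path) {
  ig <- interface_geometry(state, grid)
  pieces <- mapply(function(p, k) cbind(piece = k, p),
                   ig$polylines, seq_along(ig$polylines), SIMPLIFY = FALSE)
  utils::write.csv(do.call(rbind, pieces), path, row.names = FALSE)
  invisible(path)
}
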