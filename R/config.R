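# Model and runtime parameters. Symbols follow the field's convention for this
# class of colony models: f is the aspartate-to-nitrogen budgeting fraction of
# dark (gluconeogenic) blocks, AspU the aspartate uptake rate relative to the
# maximal trehalose uptake Cmax, Y the aspartate-carbon conversion yield, Pf
# the secreted fraction of the internal carbon pool, ExN the extra nitrogen
# requirement of light (glycolytic) blocks.

.config_defaults <- function() {
  list(
    f                  = 0.125,
    AspU               = 4.0,
    Y                  = 0.31,
    Pf                 = 0.049,
    secretion_cap      = 0.12,
    ExN                = 4.0,
    g                  = 0.04,
    Cmax               = 0.05,
    T_DL               = 1.5,
    P_DL               = 0.5,
    T_LD               = 1e-4,
    P_LD               = 1e-4,
    D_eff              = 0.24,
    grid_shape         = c(201L, 201L),
    n_steps            = 750L,
    seed               = 1L,
    init_radius        = 20,
    init_dark_fraction = 0.97,
    boundary_condition = "no_flux",
    light_rule         = "extra_N",
    on_boundary_contact = "warn"
  )
}

#' Construct a simulation configuration
#'
#' Builds the full parameter set for a colony simulation. Unspecified
#' parameters take the model defaults (the wild-type parameterization).
#' The returned object is validated; see [validate_config()] for the
#' admissible ranges.
#'
#' @param ... named parameter overrides. Model parameters: `f` (fraction of
#'   dark-block aspartate flux allocated to the nitrogen pool, in \[0,1\]),
#'   `AspU` (aspartate uptake relative to `Cmax`, >= 0), `Y` (aspartate-carbon
#'   yield, in (0,1\]), `Pf` (fraction of the internal C pool secreted as
#'   trehalose per step), `secretion_cap` (absolute per-block secretion limit,
#'   trehalose units per step), `ExN` (multiplier on the light-block minimum
#'   nitrogen reserve, >= 1), `g` (division probability per step once reserves
#'   suffice), `Cmax` (maximal trehalose consumed by a light block per step),
#'   `T_DL`/`P_DL` (dark-to-light switching threshold and probability),
#'   `T_LD`/`P_LD` (light-to-dark switching threshold and probability),
#'   `D_eff` (scaled trehalose diffusion constant, squared grid lengths per
#'   step). Runtime parameters: `grid_shape` (two positive integers),
#'   `n_steps`, `seed`, `init_radius` (grid lengths), `init_dark_fraction`
#'   (probability each initial block is dark), `boundary_condition`
#'   (`"no_flux"` or `"absorbing"`), `light_rule` (`"extra_N"` for the
#'   C >= 1, N >= ExN light division requirement; `"swapped"` for the
#'   C >= ExN, N >= 1 variant), `on_boundary_contact` (`"warn"` or `"abort"`
#'   when the colony reaches the outermost grid ring).
#' @return a validated `sim_config` object (a named list).
#' @examples
#' cfg <- sim_config()                # wild-type defaults
#' cfg_hi_n <- sim_config(f = 0.5)    # shift aspartate flux towards nitrogen
#' @export
sim_config <- function(...) {
  overrides <- list(...)
  cfg <- .config_defaults()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("all configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  cfg$n_steps <- as.integer(cfg$n_steps)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

.check_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("configuration field '", field, "' must be a single finite number",
         call. = FALSE)
  invisible(x)
}

.check_range <- function(x, field, lo = -Inf, hi = Inf,
                         lo_open = FALSE, hi_open = FALSE) {
  .check_scalar(x, field)
  ok_lo <- if (lo_open) x > lo else x >= lo
  ok_hi <- if (hi_open) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop(sprintf("configuration field '%s' = %g is outside its admissible range %s%g, %g%s",
                 field, x, if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

#' Validate a simulation configuration
#'
#' Checks every parameter against its admissible range and the FTCS stability
#' criterion `D_eff * dt / dx^2 <= 1/4` (with unit grid spacing and time
#' step). Returns the configuration unchanged when all invariants hold.
#'
#' @param cfg a `sim_config` object (or a bare named list with the same
#'   fields).
#' @return `cfg`, invisibly classed as `sim_config`.
#' @export
validate_config <- function(cfg) {
  required <- names(.config_defaults())
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("configuration is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  .check_range(cfg$f, "f", 0, 1)
  .check_range(cfg$AspU, "AspU", 0, Inf)
  .check_range(cfg$Y, "Y", 0, 1, lo_open = TRUE)
  .check_range(cfg$Pf, "Pf", 0, 1)
  .check_range(cfg$secretion_cap, "secretion_cap", 0, Inf, lo_open = TRUE)
  .check_range(cfg$ExN, "ExN", 1, Inf)
  .check_range(cfg$g, "g", 0, 1)
  .check_range(cfg$Cmax, "Cmax", 0, Inf, lo_open = TRUE)
  .check_range(cfg$P_DL, "P_DL", 0, 1)
  .check_range(cfg$P_LD, "P_LD", 0, 1)
  .check_range(cfg$T_DL, "T_DL", 0, Inf, lo_open = TRUE)
  .check_range(cfg$T_LD, "T_LD", 0, Inf, lo_open = TRUE)
  if (cfg$T_DL <= cfg$T_LD)
    stop("switching thresholds must satisfy T_DL > T_LD (got T_DL = ",
         cfg$T_DL, ", T_LD = ", cfg$T_LD, ")", call. = FALSE)
  .check_range(cfg$D_eff, "D_eff", 0, Inf)
  if (cfg$D_eff > 0.25)
    stop("FTCS stability violated: D_eff * dt/dx^2 = ", cfg$D_eff,
         " exceeds 1/4 (unit spacing); the explicit diffusion scheme diverges",
         call. = FALSE)

  gs <- cfg$grid_shape
  if (length(gs) != 2L || anyNA(gs) || any(gs < 1L))
    stop("configuration field 'grid_shape' must be two positive integers",
         call. = FALSE)
  .check_range(cfg$n_steps, "n_steps", 0, Inf)
  .check_scalar(cfg$seed, "seed")
  .check_range(cfg$init_radius, "init_radius", 0, Inf)
  .check_range(cfg$init_dark_fraction, "init_dark_fraction", 0, 1)

  if (!cfg$boundary_condition %in% c("no_flux", "absorbing"))
    stop("configuration field 'boundary_condition' must be \"no_flux\" or \"absorbing\"",
         call. = FALSE)
  if (!cfg$light_rule %in% c("extra_N", "swapped"))
    stop("configuration field 'light_rule' must be \"extra_N\" or \"swapped\"",
         call. = FALSE)
  if (!cfg$on_boundary_contact %in% c("warn", "abort"))
    stop("configuration field 'on_boundary_contact' must be \"warn\" or \"abort\"",
         call. = FALSE)

  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Colony simulation configuration\n")
  cat(sprintf("  budgeting      f = %g, AspU = %g, Y = %g\n", x$f, x$AspU, x$Y))
  cat(sprintf("  secretion      Pf = %g (cap %g units/step)\n",
              x$Pf, x$secretion_cap))
  cat(sprintf("  division       g = %g, ExN = %g, Cmax = %g\n",
              x$g, x$ExN, x$Cmax))
  cat(sprintf("  switching      T_DL = %g (P = %g), T_LD = %g (P = %g)\n",
              x$T_DL, x$P_DL, x$T_LD, x$P_LD))
  cat(sprintf("  diffusion      D_eff = %g, boundary = %s\n",
              x$D_eff, x$boundary_condition))
  cat(sprintf("  runtime        %d x %d grid, %d steps, seed %d, init radius %g (%.0f%% dark)\n",
              x$grid_shape[1], x$grid_shape[2], x$n_steps, x$seed,
              x$init_radius, 100 * x$init_dark_fraction))
  invisible(x)
}
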