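# Observables and parameter sweeps. All metrics are pure functions of
# trajectories, summary records or states.

#' Light-block fraction of a summary record
#'
#' @param record a single summary row (one-row data frame or list) with
#'   `n_dark` and `n_light` counts.
#' @return `n_light / (n_dark + n_light)`.
#' @export
light_fraction <- function(record) {
  n <- record$n_dark + record$n_light
  if (length(n) != 1L) stop("'record' must be a single summary row", call. = FALSE)
  if (n == 0L) stop("light_fraction is undefined for an empty colony", call. = FALSE)
  record$n_light / n
}

#' Radial profile of block states
#'
#' Bins the blocks of a colony state by Euclidean distance from the grid
#' center into `n_bins` equal-width annuli spanning \[0, colony radius\] and
#' counts dark and light blocks per annulus. This is the model analog of a
#' radial fluorescence profile across a real colony: light blocks
#' concentrating in the outer annuli reproduce the bright colony rim.
#'
#' @param state a non-empty `colony_state` (e.g. `trajectory$state` or a
#'   snapshot read back with [read_snapshot()]).
#' @param n_bins number of annuli (>= 1).
#' @return data frame with columns `bin`, `r_inner`, `r_outer`, `n_dark`,
#'   `n_light`. Counts sum to the state's block count.
#' @export
radial_state_profile <- function(state, n_bins) {
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  n <- n_blocks(state)
  if (n == 0L) stop("radial profile is undefined for an empty colony", call. = FALSE)
  ctr <- .grid_center(state$shape)
  r <- sqrt((state$x - ctr[1])^2 + (state$y - ctr[2])^2)
  rmax <- max(r)
  breaks <- seq(0, max(rmax, .Machine$double.eps), length.out = n_bins + 1L)
  bin <- findInterval(r, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  data.frame(bin = seq_len(n_bins),
             r_inner = breaks[-(n_bins + 1L)],
             r_outer = breaks[-1L],
             n_dark = tabulate(bin[state$state == STATE_DARK], n_bins),
             n_light = tabulate(bin[state$state == STATE_LIGHT], n_bins))
}

#' Inter-division interval statistics
#'
#' Mean and spread of the number of steps between consecutive divisions of
#' a lineage, separately for dark and light blocks. An interval is recorded
#' each time a block that has divided before divides again. Dark blocks,
#' which must first build their carbon pool from the budgeted aspartate
#' flux, divide more slowly than trehalose-fed light blocks under default
#' parameters.
#'
#' @param trajectory a `colony_trajectory`.
#' @return data frame with columns `state`, `n_intervals`, `mean_interval`,
#'   `sd_interval`; a state with no recorded intervals is omitted.
#' @export
division_interval_stats <- function(trajectory) {
  rows <- lapply(c("dark", "light"), function(s) {
    iv <- trajectory$division_intervals[[s]]
    if (length(iv) == 0L) return(NULL)
    data.frame(state = s, n_intervals = length(iv),
               mean_interval = mean(iv),
               sd_interval = if (length(iv) > 1L) stats::sd(iv) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(state = character(0), n_intervals = integer(0),
                      mean_interval = numeric(0), sd_interval = numeric(0))
  out
}

#' Fraction of dark blocks secreting at the cap
#'
#' Share of dark blocks whose per-step trehalose secretion was limited by
#' the absolute cap rather than the fractional rule `Pf * C`. The cap
#' exists to keep long-undivided blocks from dumping trehalose; under
#' default parameters only a negligible fraction of blocks ever reach it.
#'
#' @param record a single summary row with `n_blocks_at_secretion_cap` and
#'   `n_dark`.
#' @return fraction in \[0,1\], or `NA` if the record has no dark blocks.
#' @export
secretion_cap_fraction <- function(record) {
  if (length(record$n_dark) != 1L)
    stop("'record' must be a single summary row", call. = FALSE)
  if (record$n_dark == 0L) return(NA_real_)
  record$n_blocks_at_secretion_cap / record$n_dark
}

#' Parameter sweep over seeded replicate simulations
#'
#' Runs one full simulation per (parameter value, seed) pair, holding every
#' other parameter at `cfg` and using the same seeds and step count across
#' values so comparisons are paired, and aggregates final-state summaries.
#'
#' @param cfg the base [sim_config()].
#' @param param name of the parameter to vary (e.g. `"f"` or `"AspU"`).
#' @param values numeric parameter values to sweep.
#' @param seeds integer seeds; each value is run once per seed.
#' @param quiet passed to [simulate_colony()].
#' @return a `sweep_result`: list with `param`, `values`, `seeds`,
#'   `results` (one row per run: `param_value`, `seed`, `final_n_dark`,
#'   `final_n_light`, `final_total_trehalose`, `colony_radius`,
#'   `total_divisions_dark`, `total_divisions_light`) and `summary`
#'   (per-value mean and sd of the final block count and light fraction).
#' @export
sweep_param <- function(cfg, param, values, seeds, quiet = TRUE) {
  cfg <- validate_config(cfg)
  if (!param %in% names(.config_defaults()))
    stop("unknown sweep parameter: ", param, call. = FALSE)
  rows <- list()
  for (v in values) {
    for (s in seeds) {
      run_cfg <- unclass(cfg)
      run_cfg[[param]] <- v
      run_cfg$seed <- as.integer(s)
      run_cfg <- validate_config(run_cfg)
      traj <- simulate_colony(run_cfg, quiet = quiet)
      fin <- traj$records[nrow(traj$records), ]
      rows[[length(rows) + 1L]] <- data.frame(
        param_value = v, seed = as.integer(s),
        final_n_dark = fin$n_dark, final_n_light = fin$n_light,
        final_total_trehalose = fin$total_trehalose,
        colony_radius = fin$colony_radius,
        total_divisions_dark = sum(traj$records$n_divisions_dark),
        total_divisions_light = sum(traj$records$n_divisions_light))
    }
  }
  results <- do.call(rbind, rows)
  n_final <- results$final_n_dark + results$final_n_light
  lf <- results$final_n_light / n_final
  summary <- do.call(rbind, lapply(split(seq_len(nrow(results)),
                                         results$param_value), function(i) {
    data.frame(param_value = results$param_value[i[1]],
               mean_n_blocks = mean(n_final[i]),
               sd_n_blocks = stats::sd(n_final[i]),
               mean_light_fraction = mean(lf[i]),
               sd_light_fraction = stats::sd(lf[i]))
  }))
  summary <- summary[order(summary$param_value), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(param = param, values = values, seeds = seeds,
                 results = results, summary = summary),
            class = "sweep_result")
}

#' Sweep the aspartate budgeting fraction f
#'
#' Varies the fraction of dark-block aspartate flux allocated to nitrogen.
#' Large `f` starves the carbon branch: dark blocks stop dividing and
#' secrete little trehalose, so few light blocks arise; at `f = 1` no
#' trehalose is ever produced.
#'
#' @inheritParams sweep_param
#' @param values fractions in \[0,1\] (default covers the full range).
#' @export
sweep_f <- function(cfg = sim_config(), values = c(0, 0.125, 0.25, 0.5, 0.75, 1),
                    seeds = 1:5, quiet = TRUE) {
  sweep_param(cfg, "f", values, seeds, quiet = quiet)
}

#' Sweep the relative aspartate uptake AspU
#'
#' Varies the aspartate uptake rate relative to the maximal trehalose
#' uptake. Larger `AspU` feeds both pools faster and yields larger
#' colonies; small `AspU` leaves colonies small and predominantly dark.
#'
#' @inheritParams sweep_param
#' @param values uptake ratios (default spans roughly one order of
#'   magnitude).
#' @export
sweep_aspu <- function(cfg = sim_config(), values = c(1, 2, 4, 6, 8),
                       seeds = 1:5, quiet = TRUE) {
  sweep_param(cfg, "AspU", values, seeds, quiet = quiet)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parameter sweep over %s: %d values x %d seeds\n",
              x$param, length(x$values), length(x$seeds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Render a colony state as a raster image
#'
#' Writes a PNG with one pixel block per lattice site: empty sites in the
#' background color, dark blocks in a dark red, light blocks in a bright
#' green, echoing the dark/bright appearance of the two cell states in
#' colony images.
#'
#' @param state a `colony_state`.
#' @param path output PNG path.
#' @param scale integer pixel-block edge per lattice site (default 2).
#' @param colors named list with `background`, `dark`, `light` entries, each
#'   an RGB triple in \[0,1\].
#' @return `path`, invisibly.
#' @export
render_colony <- function(state, path, scale = 2L,
                          colors = list(background = c(0.05, 0.05, 0.08),
                                        dark = c(0.55, 0.10, 0.10),
                                        light = c(0.55, 0.95, 0.35))) {
  shape <- state$shape
  img <- array(0, dim = c(shape[1], shape[2], 3))
  for (ch in 1:3) img[, , ch] <- colors$background[ch]
  if (n_blocks(state) > 0L) {
    idx <- cbind(state$x + 1L, state$y + 1L)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- ifelse(state$state == STATE_DARK,
                           colors$dark[ch], colors$light[ch])
      img[, , ch] <- plane
    }
  }
  scale <- as.integer(scale)
  if (scale > 1L) {
    img <- img[rep(seq_len(shape[1]), each = scale),
               rep(seq_len(shape[2]), each = scale), , drop = FALSE]
  }
  png::writePNG(img, target = path)
  invisible(path)
}
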