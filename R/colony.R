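# Colony state container. Blocks are stored as parallel vectors (structure of
# arrays) rather than a list of objects: the engine updates all pools with
# vectorized arithmetic. `occ` is the occupancy matrix mapping each lattice
# site to the index of the block sitting on it (0 = empty); `field` is the
# extracellular trehalose concentration per site. Lattice coordinates are
# 0-based; site (x, y) lives at occ[x + 1, y + 1].

STATE_DARK <- 1L
STATE_LIGHT <- 2L

.state_labels <- c("dark", "light")

new_colony_state <- function(x, y, state, C, N, last_div, occ, field) {
  structure(
    list(x = as.integer(x), y = as.integer(y), state = as.integer(state),
         C = as.numeric(C), N = as.numeric(N),
         last_div = as.integer(last_div),
         occ = occ, field = field,
         shape = dim(occ), boundary_warned = FALSE),
    class = "colony_state")
}

#' Number of cell blocks in a colony state
#' @param state a `colony_state`.
#' @return integer block count.
#' @export
n_blocks <- function(state) length(state$x)

.grid_center <- function(shape) (shape - 1) / 2

#' Lattice sites of a centered disk
#'
#' Enumerates the integer lattice sites within Euclidean distance `radius`
#' of the grid center, the footprint of the initial colony.
#'
#' @param shape two positive integers, the grid dimensions.
#' @param radius non-negative disk radius in grid lengths.
#' @return integer matrix with columns `x`, `y` (0-based coordinates).
#' @export
disk_sites <- function(shape, radius) {
  ctr <- .grid_center(shape)
  # restrict the scan to the disk's bounding box
  x_rng <- max(0, floor(ctr[1] - radius)):min(shape[1] - 1, ceiling(ctr[1] + radius))
  y_rng <- max(0, floor(ctr[2] - radius)):min(shape[2] - 1, ceiling(ctr[2] + radius))
  sites <- as.matrix(expand.grid(x = x_rng, y = y_rng))
  d2 <- (sites[, 1] - ctr[1])^2 + (sites[, 2] - ctr[2])^2
  sites <- sites[d2 <= radius^2, , drop = FALSE]
  storage.mode(sites) <- "integer"
  sites
}

#' Initialize a colony
#'
#' Places one cell block at every lattice site within `init_radius` grid
#' lengths of the grid center (an approximately circular seed colony; the
#' default radius of 20 gives 1257 blocks). Each block is independently dark
#' with probability `init_dark_fraction`, otherwise light. All internal
#' carbon and nitrogen pools start at zero, as does the extracellular
#' trehalose field: the colony must accumulate reserves before any division
#' and secrete trehalose before any switching can occur.
#'
#' Uses the current R random number stream; [simulate_colony()] seeds it from
#' `cfg$seed` before calling this.
#'
#' @param cfg a validated [sim_config()].
#' @return a `colony_state` with block vectors `x`, `y`, `state`, `C`, `N`,
#'   `last_div`, the occupancy matrix `occ` and the trehalose field `field`.
#' @export
initialize_colony <- function(cfg) {
  cfg <- validate_config(cfg)
  shape <- cfg$grid_shape
  ctr <- .grid_center(shape)
  r <- cfg$init_radius
  if (ctr[1] - r < 0 || ctr[1] + r > shape[1] - 1 ||
      ctr[2] - r < 0 || ctr[2] + r > shape[2] - 1)
    stop("initial colony of radius ", r, " does not fit inside a ",
         shape[1], " x ", shape[2], " grid", call. = FALSE)

  sites <- disk_sites(shape, r)
  n <- nrow(sites)
  state <- ifelse(stats::runif(n) < cfg$init_dark_fraction,
                  STATE_DARK, STATE_LIGHT)
  occ <- matrix(0L, shape[1], shape[2])
  occ[cbind(sites[, 1] + 1L, sites[, 2] + 1L)] <- seq_len(n)
  field <- matrix(0, shape[1], shape[2])
  new_colony_state(sites[, 1], sites[, 2], state,
                   C = numeric(n), N = numeric(n),
                   last_div = rep(NA_integer_, n),
                   occ = occ, field = field)
}

#' Colony radius
#'
#' Maximum Euclidean distance of any block from the grid center, in grid
#' lengths.
#'
#' @param state a `colony_state`.
#' @return numeric radius (0 for a single centered block; `-Inf` for an
#'   empty state).
#' @export
colony_radius <- function(state) {
  if (n_blocks(state) == 0L) return(-Inf)
  ctr <- .grid_center(state$shape)
  sqrt(max((state$x - ctr[1])^2 + (state$y - ctr[2])^2))
}

#' Extract the agent table of a colony state
#'
#' @param state a `colony_state`.
#' @param step time step to record in the `step` column (default 0).
#' @return data frame with columns `step`, `x`, `y`, `state` (`"dark"` or
#'   `"light"`), `C`, `N`.
#' @export
agent_table <- function(state, step = 0L) {
  data.frame(step = as.integer(step), x = state$x, y = state$y,
             state = .state_labels[state$state],
             C = state$C, N = state$N, stringsAsFactors = FALSE)
}

#' @export
print.colony_state <- function(x, ...) {
  n <- n_blocks(x)
  cat(sprintf("Colony state: %d blocks (%d dark, %d light) on a %d x %d grid\n",
              n, sum(x$state == STATE_DARK), sum(x$state == STATE_LIGHT),
              x$shape[1], x$shape[2]))
  cat(sprintf("  radius %.2f grid lengths, extracellular trehalose %.4g units\n",
              colony_radius(x), sum(x$field)))
  invisible(x)
}
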