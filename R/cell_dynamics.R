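# Per-block update rules. Two implementations coexist deliberately:
#  * the exported scalar functions below, written as straight-line
#    transcriptions of the per-block algorithm, operating on a single
#    `cell_block`;
#  * vectorized internals (suffix `_vec`) used by the simulation engine.
# The test suite checks bit-for-bit agreement between the two routes on
# randomized inputs.

#' Construct a single cell block
#'
#' A cell block is the model's agent unit: a lattice-site-occupying proxy for
#' a small group of cells, in either the dark (gluconeogenic, trehalose
#' secreting) or light (glycolytic, trehalose consuming) state, carrying
#' internal carbon and nitrogen pools.
#'
#' @param state `"dark"` or `"light"`.
#' @param x,y 0-based lattice coordinates.
#' @param C,N non-negative internal carbon and nitrogen pools.
#' @param last_division_step integer step of the block's most recent
#'   division, or `NA` if it has never divided.
#' @return a `cell_block` object.
#' @export
cell_block <- function(state = c("dark", "light"), x = 0L, y = 0L,
                       C = 0, N = 0, last_division_step = NA_integer_) {
  state <- match.arg(state)
  stopifnot(C >= 0, N >= 0)
  structure(list(state = state, x = as.integer(x), y = as.integer(y),
                 C = as.numeric(C), N = as.numeric(N),
                 last_division_step = as.integer(last_division_step)),
            class = "cell_block")
}

#' @export
print.cell_block <- function(x, ...) {
  cat(sprintf("<%s cell block at (%d, %d): C = %.4g, N = %.4g>\n",
              x$state, x$x, x$y, x$C, x$N))
  invisible(x)
}

#' Dark-to-light switching attempt
#'
#' A dark block switches to the light state when the local extracellular
#' trehalose exceeds the threshold `T_DL`, with probability `P_DL` per time
#' step. Internal pools are retained unchanged across the switch. A block
#' that switches takes no further action this time step.
#'
#' @param block a dark `cell_block`.
#' @param local_trehalose trehalose concentration at the block's site.
#' @param cfg a [sim_config()].
#' @param u uniform(0,1) draw deciding the switch (exposed for testing;
#'   defaults to a fresh draw).
#' @return list with elements `block` (possibly switched) and `switched`
#'   (logical).
#' @export
try_switch_dark_to_light <- function(block, local_trehalose, cfg,
                                     u = stats::runif(1)) {
  stopifnot(block$state == "dark")
  switched <- local_trehalose > cfg$T_DL && u < cfg$P_DL
  if (switched) block$state <- "light"
  list(block = block, switched = switched)
}

#' Light-to-dark switching attempt
#'
#' A light block reverts to the dark state when local trehalose falls below
#' the threshold `T_LD`, with probability `P_LD` per time step.
#'
#' @inheritParams try_switch_dark_to_light
#' @param block a light `cell_block`.
#' @return list with elements `block` and `switched`.
#' @export
try_switch_light_to_dark <- function(block, local_trehalose, cfg,
                                     u = stats::runif(1)) {
  stopifnot(block$state == "light")
  switched <- local_trehalose < cfg$T_LD && u < cfg$P_LD
  if (switched) block$state <- "dark"
  list(block = block, switched = switched)
}

#' Dark-block metabolic update
#'
#' One time step of dark-block metabolism: the block consumes `AspU * Cmax`
#' units of aspartate, allocates the fraction `f` of that flux to its
#' nitrogen pool, converts the remaining `1 - f` to carbon with yield `Y`,
#' and then secretes the fraction `Pf` of its (post-addition) carbon pool as
#' extracellular trehalose, capped at `secretion_cap` units per step. The
#' secreted amount is deducted from the pool; the caller adds it to the
#' field at the block's site.
#'
#' @param block a dark `cell_block` that did not switch this step.
#' @param cfg a [sim_config()].
#' @return list with elements `block` (updated pools) and `secreted`
#'   (trehalose units released this step).
#' @export
dark_metabolic_update <- function(block, cfg) {
  stopifnot(block$state == "dark")
  asp <- cfg$AspU * cfg$Cmax
  block$N <- block$N + cfg$f * asp
  c_tmp <- block$C + (1 - cfg$f) * asp * cfg$Y
  secreted <- cfg$Pf * c_tmp
  if (secreted > cfg$secretion_cap) secreted <- cfg$secretion_cap
  block$C <- c_tmp - secreted
  list(block = block, secreted = secreted)
}

#' Light-block metabolic update
#'
#' One time step of light-block metabolism: the block consumes all the
#' trehalose at its site up to `Cmax` units, adding it to its carbon pool,
#' and takes up `AspU * Cmax` units of (non-limiting) aspartate into its
#' nitrogen pool. The caller removes the consumed amount from the field.
#'
#' @param block a light `cell_block` that did not switch this step.
#' @param local_trehalose trehalose available at the block's site.
#' @param cfg a [sim_config()].
#' @return list with elements `block` and `consumed` (trehalose units taken
#'   from the site).
#' @export
light_metabolic_update <- function(block, local_trehalose, cfg) {
  stopifnot(block$state == "light")
  consumed <- local_trehalose
  if (consumed > cfg$Cmax) consumed <- cfg$Cmax
  block$C <- block$C + consumed
  block$N <- block$N + cfg$AspU * cfg$Cmax
  list(block = block, consumed = consumed)
}

#' Division eligibility
#'
#' Both cell types must accumulate a minimum carbon reserve of 1.0 units
#' before division. Dark blocks additionally need 1.0 units of nitrogen;
#' light blocks, reflecting their higher nucleotide-synthesis rate, need
#' `ExN` times that nitrogen reserve (default `light_rule = "extra_N"`).
#' The `"swapped"` rule (C >= ExN, N >= 1) is available for sensitivity
#' checks.
#'
#' @param block a `cell_block` with this step's pools.
#' @param cfg a [sim_config()].
#' @return logical: may the block attempt division this step?
#' @export
eligible_to_divide <- function(block, cfg) {
  if (block$state == "dark") return(block$C >= 1 && block$N >= 1)
  if (cfg$light_rule == "swapped") block$C >= cfg$ExN && block$N >= 1
  else block$C >= 1 && block$N >= cfg$ExN
}

.neighbor_sites <- function(x, y) {
  cbind(x = c(x - 1L, x + 1L, x, x), y = c(y, y, y - 1L, y + 1L))
}

.count_occupied_neighbors <- function(x, y, occ) {
  nb <- .neighbor_sites(x, y)
  shape <- dim(occ)
  inside <- nb[, 1] >= 0L & nb[, 1] < shape[1] & nb[, 2] >= 0L & nb[, 2] < shape[2]
  nb <- nb[inside, , drop = FALSE]
  sum(occ[cbind(nb[, 1] + 1L, nb[, 2] + 1L)] > 0L)
}

#' Choose a division site
#'
#' Among the empty sites of the 4-neighborhood
#' \{(x-1,y), (x+1,y), (x,y-1), (x,y+1)\} of `position`, picks the one with
#' the most occupied 4-neighbors (daughters preferentially fill crowded
#' gaps, keeping the colony compact); ties are broken uniformly at random.
#' Off-grid sites are never candidates and count as unoccupied neighbors.
#'
#' @param position integer `c(x, y)`, the mother block's (0-based) site.
#' @param occ occupancy matrix (0 = empty site).
#' @return integer `c(x, y)` of the chosen empty neighbor, or `NULL` if the
#'   whole neighborhood is occupied (division is then skipped).
#' @export
choose_division_site <- function(position, occ) {
  nb <- .neighbor_sites(position[1], position[2])
  shape <- dim(occ)
  inside <- nb[, 1] >= 0L & nb[, 1] < shape[1] & nb[, 2] >= 0L & nb[, 2] < shape[2]
  nb <- nb[inside, , drop = FALSE]
  empty <- nb[occ[cbind(nb[, 1] + 1L, nb[, 2] + 1L)] == 0L, , drop = FALSE]
  if (nrow(empty) == 0L) return(NULL)
  counts <- vapply(seq_len(nrow(empty)), function(i)
    .count_occupied_neighbors(empty[i, 1], empty[i, 2], occ), integer(1))
  best <- which(counts == max(counts))
  pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
  as.integer(empty[pick, ])
}

#' Perform a cell-block division
#'
#' Splits the mother block: the mother stays at its site, the daughter is
#' placed at `site`, and each inherits half of the mother's pre-division
#' carbon and nitrogen pools (pool totals are conserved exactly). Both share
#' the mother's state and have `last_division_step` set to `step`.
#'
#' @param block the mother `cell_block` (eligibility and the division
#'   probability draw have already passed).
#' @param site integer `c(x, y)`, an empty neighboring site.
#' @param step current time step.
#' @param occ optional occupancy matrix; when supplied, the target site is
#'   checked to be empty.
#' @return list with elements `mother` and `daughter`.
#' @export
perform_division <- function(block, site, step, occ = NULL) {
  if (!is.null(occ) && occ[site[1] + 1L, site[2] + 1L] != 0L)
    stop("division target site (", site[1], ", ", site[2], ") is occupied",
         call. = FALSE)
  half_C <- block$C / 2
  half_N <- block$N / 2
  mother <- block
  mother$C <- half_C; mother$N <- half_N
  mother$last_division_step <- as.integer(step)
  daughter <- cell_block(mother$state, site[1], site[2], half_C, half_N,
                         last_division_step = step)
  list(mother = mother, daughter = daughter)
}

# ---- vectorized internals (engine path) -------------------------------------

# Dark metabolism over pool vectors; returns updated pools, per-block
# secretion and whether the secretion cap bound.
dark_update_vec <- function(C, N, cfg) {
  asp <- cfg$AspU * cfg$Cmax
  c_tmp <- C + (1 - cfg$f) * asp * cfg$Y
  raw <- cfg$Pf * c_tmp
  capped <- raw > cfg$secretion_cap
  secreted <- ifelse(capped, cfg$secretion_cap, raw)
  list(C = c_tmp - secreted, N = N + cfg$f * asp,
       secreted = secreted, capped = capped)
}

# Light metabolism over pool vectors given local field values.
light_update_vec <- function(C, N, local, cfg) {
  consumed <- pmin(local, cfg$Cmax)
  list(C = C + consumed, N = N + cfg$AspU * cfg$Cmax, consumed = consumed)
}

# Switching decisions over all blocks given local field values and one
# uniform draw per block.
switch_vec <- function(state, local, u, cfg) {
  dl <- state == STATE_DARK & local > cfg$T_DL & u < cfg$P_DL
  ld <- state == STATE_LIGHT & local < cfg$T_LD & u < cfg$P_LD
  list(dark_to_light = dl, light_to_dark = ld)
}

# Division eligibility over pool vectors.
eligible_vec <- function(state, C, N, cfg) {
  if (cfg$light_rule == "swapped")
    light_ok <- C >= cfg$ExN & N >= 1
  else
    light_ok <- C >= 1 & N >= cfg$ExN
  ifelse(state == STATE_DARK, C >= 1 & N >= 1, light_ok)
}
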