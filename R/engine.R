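# Simulation engine. Each time step:
#   1. draw a fresh random processing order over the blocks present at the
#      start of the step (daughters born this step are appended but not
#      processed until the next step);
#   2. switching checks (dark->light above T_DL, light->dark below T_LD);
#      a block that switches takes no further action this step;
#   3. metabolism: dark blocks budget the aspartate flux and secrete
#      trehalose at their own site; light blocks consume the trehalose at
#      their own site (up to Cmax) and take up aspartate;
#   4. division: eligible blocks that pass the g-draw divide, in processing
#      order, into the empty 4-neighbor with the most occupied neighbors;
#   5. one FTCS diffusion step on the field.
# Because a site holds at most one block and secretion/consumption act only
# at a block's own site, steps 2-3 are order-independent and vectorize; the
# processing order only matters when two dividing blocks compete for the
# same empty site. Draw order per step is fixed (permutation, switch draws,
# g-draws, site tie-breaks), so a seeded run is byte-reproducible.

#' Advance a colony state by one time step
#'
#' Applies the full per-step update (switching, metabolism, division,
#' diffusion) to `state`. Uses the current R random number stream.
#'
#' @param state a `colony_state`.
#' @param cfg a validated [sim_config()].
#' @param step integer index of this time step (used for division
#'   bookkeeping).
#' @return list with elements `state` (the advanced state) and `diag`, a
#'   list of per-step diagnostics: `n_divisions_dark`, `n_divisions_light`,
#'   `n_blocks_at_secretion_cap`, `n_active_dark`, `total_secreted`,
#'   `total_consumed`, `division_intervals_dark`, `division_intervals_light`.
#' @export
step_colony <- function(state, cfg, step = 1L) {
  n0 <- n_blocks(state)
  field <- state$field

  diag <- list(n_divisions_dark = 0L, n_divisions_light = 0L,
               n_blocks_at_secretion_cap = 0L, n_active_dark = 0L,
               total_secreted = 0, total_consumed = 0,
               division_intervals_dark = integer(0),
               division_intervals_light = integer(0))

  if (n0 > 0L) {
    perm <- sample.int(n0)           # processing order for this step
    rank <- integer(n0); rank[perm] <- seq_len(n0)

    site_idx <- cbind(state$x + 1L, state$y + 1L)
    local <- field[site_idx]

    # -- switching ------------------------------------------------------
    u_switch <- stats::runif(n0)
    sw <- switch_vec(state$state, local, u_switch, cfg)
    state$state[sw$dark_to_light] <- STATE_LIGHT
    state$state[sw$light_to_dark] <- STATE_DARK
    switched <- sw$dark_to_light | sw$light_to_dark

    # -- metabolism (blocks that switched skip the rest of the step) ----
    act_dark <- which(state$state == STATE_DARK & !switched)
    act_light <- which(state$state == STATE_LIGHT & !switched)
    diag$n_active_dark <- length(act_dark)

    if (length(act_dark)) {
      upd <- dark_update_vec(state$C[act_dark], state$N[act_dark], cfg)
      state$C[act_dark] <- upd$C
      state$N[act_dark] <- upd$N
      field[site_idx[act_dark, , drop = FALSE]] <-
        field[site_idx[act_dark, , drop = FALSE]] + upd$secreted
      diag$n_blocks_at_secretion_cap <- sum(upd$capped)
      diag$total_secreted <- sum(upd$secreted)
    }
    if (length(act_light)) {
      upd <- light_update_vec(state$C[act_light], state$N[act_light],
                              local[act_light], cfg)
      state$C[act_light] <- upd$C
      state$N[act_light] <- upd$N
      field[site_idx[act_light, , drop = FALSE]] <-
        field[site_idx[act_light, , drop = FALSE]] - upd$consumed
      diag$total_consumed <- sum(upd$consumed)
    }

    # -- division -------------------------------------------------------
    u_div <- stats::runif(n0)
    elig <- eligible_vec(state$state, state$C, state$N, cfg) & !switched
    dividers <- which(elig & u_div < cfg$g)
    if (length(dividers)) {
      dividers <- dividers[order(rank[dividers])]
      nd <- length(dividers)
      d_x <- integer(nd); d_y <- integer(nd); d_state <- integer(nd)
      d_C <- numeric(nd); d_N <- numeric(nd)
      k <- 0L
      for (i in dividers) {
        site <- choose_division_site(c(state$x[i], state$y[i]), state$occ)
        if (is.null(site)) next      # neighborhood fully occupied
        k <- k + 1L
        st <- state$state[i]
        half_C <- state$C[i] / 2; half_N <- state$N[i] / 2
        state$C[i] <- half_C; state$N[i] <- half_N
        if (!is.na(state$last_div[i])) {
          iv <- as.integer(step) - state$last_div[i]
          if (st == STATE_DARK)
            diag$division_intervals_dark <- c(diag$division_intervals_dark, iv)
          else
            diag$division_intervals_light <- c(diag$division_intervals_light, iv)
        }
        state$last_div[i] <- as.integer(step)
        d_x[k] <- site[1]; d_y[k] <- site[2]; d_state[k] <- st
        d_C[k] <- half_C; d_N[k] <- half_N
        state$occ[site[1] + 1L, site[2] + 1L] <- n0 + k
        if (st == STATE_DARK)
          diag$n_divisions_dark <- diag$n_divisions_dark + 1L
        else
          diag$n_divisions_light <- diag$n_divisions_light + 1L
      }
      if (k > 0L) {
        idx <- seq_len(k)
        state$x <- c(state$x, d_x[idx])
        state$y <- c(state$y, d_y[idx])
        state$state <- c(state$state, d_state[idx])
        state$C <- c(state$C, d_C[idx])
        state$N <- c(state$N, d_N[idx])
        state$last_div <- c(state$last_div, rep(as.integer(step), k))
      }
    }
  }

  # -- diffusion --------------------------------------------------------
  state$field <- ftcs_step(field, cfg$D_eff, cfg$boundary_condition)

  # -- boundary contact -------------------------------------------------
  if (n_blocks(state) > 0L) {
    shape <- state$shape
    at_edge <- any(state$x == 0L | state$x == shape[1] - 1L |
                   state$y == 0L | state$y == shape[2] - 1L)
    if (at_edge) {
      if (cfg$on_boundary_contact == "abort")
        stop("colony reached the outermost grid ring at step ", step,
             "; enlarge grid_shape or reduce n_steps", call. = FALSE)
      if (!isTRUE(state$boundary_warned)) {
        warning("colony reached the outermost grid ring at step ", step,
                "; growth and diffusion are now boundary-limited",
                call. = FALSE)
        state$boundary_warned <- TRUE
      }
    }
  }

  list(state = state, diag = diag)
}

.summary_record <- function(step, state, diag) {
  data.frame(step = as.integer(step),
             n_dark = sum(state$state == STATE_DARK),
             n_light = sum(state$state == STATE_LIGHT),
             total_trehalose = sum(state$field),
             colony_radius = colony_radius(state),
             n_divisions_dark = diag$n_divisions_dark,
             n_divisions_light = diag$n_divisions_light,
             n_blocks_at_secretion_cap = diag$n_blocks_at_secretion_cap)
}

.empty_diag <- function() {
  list(n_divisions_dark = 0L, n_divisions_light = 0L,
       n_blocks_at_secretion_cap = 0L, n_active_dark = 0L,
       total_secreted = 0, total_consumed = 0,
       division_intervals_dark = integer(0),
       division_intervals_light = integer(0))
}

#' Run a full colony simulation
#'
#' Seeds the random number generator from `cfg$seed`, initializes the
#' colony ([initialize_colony()]) and advances it `cfg$n_steps` time steps,
#' recording a per-step summary (block counts by state, total extracellular
#' trehalose, colony radius, divisions by state, blocks at the secretion
#' cap). Identical configurations and seeds yield identical trajectories.
#'
#' @param cfg a [sim_config()].
#' @param snapshot_every if positive, keep a full snapshot (agent table +
#'   field matrix) every this many steps (step 0 included). 0 (default)
#'   keeps none; the final state is always retained.
#' @param quiet if `FALSE`, print a progress line every 100 steps.
#' @return a `colony_trajectory`: list with `config`, `seed`, `records`
#'   (data frame of `n_steps + 1` summary rows, including step 0),
#'   `division_intervals` (per-state vectors of steps between consecutive
#'   divisions of a lineage), `snapshots` (list of `list(step, agents,
#'   field)`), and `state` (the final `colony_state`).
#' @examples
#' \donttest{
#' traj <- simulate_colony(sim_config(n_steps = 50, seed = 7))
#' tail(traj$records)
#' }
#' @export
simulate_colony <- function(cfg, snapshot_every = 0L, quiet = TRUE) {
  cfg <- validate_config(cfg)
  set.seed(cfg$seed)
  state <- initialize_colony(cfg)

  records <- vector("list", cfg$n_steps + 1L)
  records[[1L]] <- .summary_record(0L, state, .empty_diag())
  snapshots <- list()
  take_snap <- function(step, state) {
    snapshots[[length(snapshots) + 1L]] <<-
      list(step = as.integer(step), agents = agent_table(state, step),
           field = state$field)
  }
  if (snapshot_every > 0L) take_snap(0L, state)

  iv_dark <- integer(0); iv_light <- integer(0)
  for (t in seq_len(cfg$n_steps)) {
    res <- step_colony(state, cfg, step = t)
    state <- res$state
    records[[t + 1L]] <- .summary_record(t, state, res$diag)
    iv_dark <- c(iv_dark, res$diag$division_intervals_dark)
    iv_light <- c(iv_light, res$diag$division_intervals_light)
    if (snapshot_every > 0L && t %% snapshot_every == 0L) take_snap(t, state)
    if (!quiet && t %% 100L == 0L) {
      r <- records[[t + 1L]]
      message(sprintf("step %d: %d dark, %d light, radius %.1f",
                      t, r$n_dark, r$n_light, r$colony_radius))
    }
  }

  structure(list(config = cfg, seed = cfg$seed,
                 records = do.call(rbind, records),
                 division_intervals = list(dark = iv_dark, light = iv_light),
                 snapshots = snapshots, state = state),
            class = "colony_trajectory")
}

#' @export
print.colony_trajectory <- function(x, ...) {
  fin <- x$records[nrow(x$records), ]
  cat(sprintf("Colony trajectory: %d steps, seed %d\n",
              max(x$records$step), x$seed))
  cat(sprintf("  final: %d dark + %d light blocks, radius %.1f, %.3g units extracellular trehalose\n",
              fin$n_dark, fin$n_light, fin$colony_radius, fin$total_trehalose))
  cat(sprintf("  divisions recorded: %d dark, %d light; %d snapshots kept\n",
              sum(x$records$n_divisions_dark), sum(x$records$n_divisions_light),
              length(x$snapshots)))
  invisible(x)
}
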