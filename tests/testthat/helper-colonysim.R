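# Shared fixtures and independent oracles.

# Brute-force lattice-disk enumerator, independent of disk_sites(): counts
# integer offsets (i, j) in the bounding square with i^2 + j^2 <= r^2.
brute_force_disk_count <- function(radius) {
  r <- ceiling(radius)
  n <- 0L
  for (i in -r:r)
    for (j in -r:r)
      if (i^2 + j^2 <= radius^2) n <- n + 1L
  n
}

# Straight-line reference implementation of one block update (no grid):
# switching, then metabolism for the surviving state. The production engine
# must agree with this bit-for-bit.
ref_update_block <- function(state, C, N, local, u_switch, cfg) {
  switched <- FALSE
  if (state == "dark") {
    if (local > cfg$T_DL && u_switch < cfg$P_DL) { state <- "light"; switched <- TRUE }
  } else {
    if (local < cfg$T_LD && u_switch < cfg$P_LD) { state <- "dark"; switched <- TRUE }
  }
  secreted <- 0; consumed <- 0
  if (!switched && state == "dark") {
    N <- N + cfg$f * cfg$AspU * cfg$Cmax
    C <- C + (1 - cfg$f) * cfg$AspU * cfg$Cmax * cfg$Y
    secreted <- min(cfg$Pf * C, cfg$secretion_cap)
    C <- C - secreted
  } else if (!switched) {
    consumed <- min(local, cfg$Cmax)
    C <- C + consumed
    N <- N + cfg$AspU * cfg$Cmax
  }
  list(state = state, C = C, N = N,
       secreted = secreted, consumed = consumed, switched = switched)
}

# One shared wild-type 750-step run (the long fixture several tests read).
.run_cache <- new.env(parent = emptyenv())
get_default_run <- function() {
  if (is.null(.run_cache$traj))
    .run_cache$traj <- simulate_colony(sim_config(seed = 42))
  .run_cache$traj
}

# Small colony state built directly from block coordinates (0-based), for
# geometric fixtures.
make_state <- function(x, y, state, C = 0, N = 0, shape = c(21L, 21L),
                       field = matrix(0, shape[1], shape[2])) {
  n <- length(x)
  occ <- matrix(0L, shape[1], shape[2])
  occ[cbind(x + 1L, y + 1L)] <- seq_len(n)
  colonysim:::new_colony_state(
    x, y, ifelse(state == "dark", 1L, 2L),
    C = rep_len(as.numeric(C), n), N = rep_len(as.numeric(N), n),
    last_div = rep(NA_integer_, n), occ = occ, field = field)
}
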