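# Explicit FTCS (forward-time, centered-space) diffusion of the
# extracellular trehalose field. With unit grid spacing and time step the
# update is u' = u + D_eff * (u_E + u_W + u_N + u_S - 4 u); the scheme is
# stable (and positivity-preserving) iff D_eff <= 1/4.

#' One FTCS diffusion step
#'
#' Advances a scalar concentration field by one explicit forward-time
#' centered-space step of the 2D diffusion equation with unit grid spacing
#' and time step. Boundary handling: `"no_flux"` replicates edge values into
#' ghost cells (zero normal gradient, conserving total mass exactly), the
#' physically sensible choice for an agar plate that neither feeds nor
#' drains trehalose at its rim; `"absorbing"` uses zero ghost cells, so mass
#' leaks out across the boundary.
#'
#' @param field numeric matrix of non-negative concentrations.
#' @param D_eff scaled diffusion constant (squared grid lengths per time
#'   step); must satisfy the stability criterion `D_eff <= 1/4`.
#' @param boundary `"no_flux"` (default) or `"absorbing"`.
#' @return the diffused field, same dimensions.
#' @examples
#' u <- matrix(0, 5, 5); u[3, 3] <- 1
#' ftcs_step(u, D_eff = 0.24)   # center keeps 0.04, each neighbor gets 0.24
#' @export
ftcs_step <- function(field, D_eff, boundary = c("no_flux", "absorbing")) {
  boundary <- match.arg(boundary)
  if (D_eff > 0.25)
    stop("FTCS stability violated: D_eff * dt/dx^2 = ", D_eff,
         " exceeds 1/4 (unit spacing); the explicit diffusion scheme diverges",
         call. = FALSE)
  if (D_eff < 0) stop("D_eff must be non-negative", call. = FALSE)
  nr <- nrow(field); nc <- ncol(field)
  if (boundary == "no_flux") {
    xm <- field[c(1L, seq_len(nr - 1L)), , drop = FALSE]
    xp <- field[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
    ym <- field[, c(1L, seq_len(nc - 1L)), drop = FALSE]
    yp <- field[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  } else {
    zr <- matrix(0, 1L, nc)
    zc <- matrix(0, nr, 1L)
    xm <- rbind(zr, field[seq_len(nr - 1L), , drop = FALSE])
    xp <- rbind(field[seq_len(nr - 1L) + 1L, , drop = FALSE], zr)
    ym <- cbind(zc, field[, seq_len(nc - 1L), drop = FALSE])
    yp <- cbind(field[, seq_len(nc - 1L) + 1L, drop = FALSE], zc)
  }
  field + D_eff * (xm + xp + ym + yp - 4 * field)
}

#' Total mass of a concentration field
#'
#' Sum of all entries; a conservation diagnostic (constant under no-flux
#' FTCS steps, decreasing under absorbing boundaries).
#'
#' @param field numeric matrix.
#' @return scalar total.
#' @export
total_mass <- function(field) sum(field)
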