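cfg <- sim_config()

test_that("dark-to-light switching is gated by threshold and probability", {
  b <- cell_block("dark", C = 0.3, N = 0.2)
  res <- try_switch_dark_to_light(b, local_trehalose = 1.6, cfg, u = 0.3)
  expect_true(res$switched)
  expect_identical(res$block$state, "light")
  # pools carried across the switch unchanged
  expect_identical(res$block$C, 0.3)
  expect_identical(res$block$N, 0.2)

  expect_false(try_switch_dark_to_light(b, 1.4, cfg, u = 0)$switched)   # below T_DL
  expect_false(try_switch_dark_to_light(b, 1.6, cfg, u = 0.9)$switched) # draw >= P_DL
  expect_false(try_switch_dark_to_light(b, 1.5, cfg, u = 0)$switched)   # threshold is strict
})

test_that("light-to-dark switching requires near-zero trehalose and a rare draw", {
  b <- cell_block("light")
  expect_true(try_switch_light_to_dark(b, 0, cfg, u = 5e-5)$switched)
  expect_false(try_switch_light_to_dark(b, 0.01, cfg, u = 0)$switched)
  expect_false(try_switch_light_to_dark(b, 0, cfg, u = 0.5)$switched)
})

test_that("dark metabolism budgets aspartate between N and C and secretes a carbon fraction", {
  res <- dark_metabolic_update(cell_block("dark"), cfg)
  # hand arithmetic from the defaults:
  # N gain = f*AspU*Cmax = 0.125*0.2; C before secretion = 0.875*0.2*0.31
  expect_equal(res$block$N, 0.025)
  expect_equal(res$secreted, 0.00265825)
  expect_equal(res$block$C, 0.05425 - 0.00265825)
  expect_equal(res$block$C + res$secreted, 0.05425)  # carbon conserved

  # with f = 1 the whole flux goes to nitrogen; secretion only drains the
  # pre-existing pool
  cfg_f1 <- sim_config(f = 1)
  res <- dark_metabolic_update(cell_block("dark", C = 0.5), cfg_f1)
  expect_equal(res$block$C + res$secreted, 0.5)
  expect_equal(res$secreted, 0.049 * 0.5)
  expect_equal(res$block$N, 0.2)
})

test_that("the secretion cap binds for large carbon pools", {
  res <- dark_metabolic_update(cell_block("dark", C = 10), cfg)
  expect_identical(res$secreted, 0.12)
  expect_equal(res$block$C, 10 + 0.875 * 0.2 * 0.31 - 0.12)
})

test_that("light metabolism consumes local trehalose up to Cmax and aspartate unconditionally", {
  res <- light_metabolic_update(cell_block("light"), 0.03, cfg)
  expect_identical(res$consumed, 0.03)
  expect_equal(res$block$C, 0.03)

  res <- light_metabolic_update(cell_block("light"), 0.2, cfg)
  expect_identical(res$consumed, 0.05)
  expect_equal(res$block$N, 0.2)   # AspU * Cmax, independent of the field

  res <- light_metabolic_update(cell_block("light"), 0, cfg)
  expect_identical(res$consumed, 0)
  expect_equal(res$block$N, 0.2)   # aspartate is non-limiting
})

test_that("division eligibility respects the per-state reserve minima", {
  expect_true(eligible_to_divide(cell_block("dark", C = 1, N = 1), cfg))
  expect_false(eligible_to_divide(cell_block("dark", C = 0.99, N = 5), cfg))
  expect_false(eligible_to_divide(cell_block("light", C = 1, N = 3.9), cfg))
  expect_true(eligible_to_divide(cell_block("light", C = 2, N = 4), cfg))
  expect_true(eligible_to_divide(cell_block("light", C = 1, N = 4), cfg))

  # the swapped reading exchanges the two light minima
  cfg_sw <- sim_config(light_rule = "swapped")
  expect_true(eligible_to_divide(cell_block("light", C = 4, N = 1), cfg_sw))
  expect_false(eligible_to_divide(cell_block("light", C = 1, N = 4), cfg_sw))

  # monotonicity: adding reserves never revokes eligibility
  set.seed(11)
  for (i in 1:200) {
    b <- cell_block(sample(c("dark", "light"), 1),
                    C = runif(1, 0, 6), N = runif(1, 0, 6))
    if (eligible_to_divide(b, cfg)) {
      b2 <- b; b2$C <- b$C + runif(1, 0, 3); b2$N <- b$N + runif(1, 0, 3)
      expect_true(eligible_to_divide(b2, cfg))
    }
  }
})

test_that("division sites prefer crowded empty neighbors and respect full neighborhoods", {
  occ <- matrix(0L, 7L, 7L)
  set_occ <- function(x, y) occ[x + 1L, y + 1L] <<- 1L
  set_occ(3, 3)                       # mother at (3,3)

  # exactly one empty neighbor
  set_occ(2, 3); set_occ(4, 3); set_occ(3, 2)
  expect_identical(choose_division_site(c(3L, 3L), occ), c(3L, 4L))

  # two empty neighbors: (3,4) has 3 occupied neighbors, (3,2) only 1
  occ[] <- 0L
  set_occ(3, 3); set_occ(2, 3); set_occ(4, 3)
  set_occ(2, 4); set_occ(4, 4)                  # make (3,4) the crowded gap
  expect_identical(choose_division_site(c(3L, 3L), occ), c(3L, 4L))

  # saturated neighborhood: no site
  occ[] <- 0L
  set_occ(3, 3); set_occ(2, 3); set_occ(4, 3); set_occ(3, 2); set_occ(3, 4)
  expect_null(choose_division_site(c(3L, 3L), occ))

  # corner mother: off-grid sites are never candidates
  occ[] <- 0L
  set_occ(0, 0)
  site <- choose_division_site(c(0L, 0L), occ)
  expect_true(all(site >= 0L))
  expect_true(all(site %in% c(0L, 1L)))
})

test_that("division halves the reserves exactly and preserves the state", {
  m <- cell_block("dark", x = 3, y = 3, C = 1.2, N = 1.0)
  res <- perform_division(m, c(3L, 4L), step = 17L)
  expect_identical(res$mother$C, 0.6)
  expect_identical(res$daughter$C, 0.6)
  expect_identical(res$mother$N, 0.5)
  expect_identical(res$daughter$N, 0.5)
  expect_identical(res$mother$C + res$daughter$C, 1.2)
  expect_identical(res$daughter$state, "dark")
  expect_identical(res$daughter$x, 3L)
  expect_identical(res$daughter$y, 4L)
  expect_identical(res$mother$last_division_step, 17L)
  expect_identical(res$daughter$last_division_step, 17L)

  lm <- cell_block("light", C = 2, N = 8)
  expect_identical(perform_division(lm, c(1L, 0L), 1L)$daughter$state, "light")

  occ <- matrix(1L, 3L, 3L)
  expect_error(perform_division(m, c(1L, 1L), 1L, occ = occ), "occupied")
})

test_that("the engine's vectorized update agrees bit-for-bit with the straight-line reference", {
  set.seed(202)
  n <- 1e4
  states <- sample(c("dark", "light"), n, replace = TRUE)
  C <- runif(n, 0, 30)                       # large pools exercise the cap
  N <- runif(n, 0, 8)
  local <- ifelse(runif(n) < 0.3, 0, runif(n, 0, 3))  # crosses both thresholds
  u <- runif(n)

  ref <- lapply(seq_len(n), function(i)
    ref_update_block(states[i], C[i], N[i], local[i], u[i], cfg))
  ref_C <- vapply(ref, `[[`, numeric(1), "C")
  ref_N <- vapply(ref, `[[`, numeric(1), "N")
  ref_state <- vapply(ref, `[[`, character(1), "state")
  ref_sec <- vapply(ref, `[[`, numeric(1), "secreted")
  ref_con <- vapply(ref, `[[`, numeric(1), "consumed")

  # production route: the vectorized internals the engine composes
  st_int <- ifelse(states == "dark", 1L, 2L)
  sw <- colonysim:::switch_vec(st_int, local, u, cfg)
  st2 <- st_int
  st2[sw$dark_to_light] <- 2L
  st2[sw$light_to_dark] <- 1L
  switched <- sw$dark_to_light | sw$light_to_dark
  out_C <- C; out_N <- N
  sec <- numeric(n); con <- numeric(n)
  dk <- which(st2 == 1L & !switched)
  lt <- which(st2 == 2L & !switched)
  du <- colonysim:::dark_update_vec(C[dk], N[dk], cfg)
  out_C[dk] <- du$C; out_N[dk] <- du$N; sec[dk] <- du$secreted
  lu <- colonysim:::light_update_vec(C[lt], N[lt], local[lt], cfg)
  out_C[lt] <- lu$C; out_N[lt] <- lu$N; con[lt] <- lu$consumed

  expect_identical(out_C, ref_C)
  expect_identical(out_N, ref_N)
  expect_identical(sec, ref_sec)
  expect_identical(con, ref_con)
  expect_identical(c("dark", "light")[st2], ref_state)

  # the exported scalar rules are the same update, one block at a time
  idx <- sample(n, 200)
  for (i in idx) {
    b <- cell_block(states[i], C = C[i], N = N[i])
    if (states[i] == "dark") {
      s <- try_switch_dark_to_light(b, local[i], cfg, u = u[i])
    } else {
      s <- try_switch_light_to_dark(b, local[i], cfg, u = u[i])
    }
    if (!s$switched && s$block$state == "dark") {
      r <- dark_metabolic_update(s$block, cfg)
      expect_identical(r$block$C, ref_C[i])
      expect_identical(r$secreted, ref_sec[i])
    } else if (!s$switched) {
      r <- light_metabolic_update(s$block, local[i], cfg)
      expect_identical(r$block$C, ref_C[i])
      expect_identical(r$consumed, ref_con[i])
    }
    expect_identical(s$block$state, ref_state[i])
  }
})
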