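test_that("six transitions cycle every protomer through the seam once", {
  p <- motor_params()
  st <- init_motor_state(rep(FALSE, 6), seam = 2)
  start_rank <- st$rank
  seams <- integer(6)
  for (i in 1:6) {
    seams[i] <- seam_protomer(st)
    st <- advance_motor(st, p)$state
  }
  expect_setequal(seams, 1:6)
  expect_equal(st$rank, start_rank)
  # direction is strictly one-way: the seam hands to its cyclic predecessor
  expect_equal(seams, ((2 - (0:5) - 1) %% 6) + 1)
})

test_that("one step advances by 13 angstrom and 2 residues and costs 2 ATP", {
  p <- motor_params()
  out <- advance_motor(init_motor_state(rep(FALSE, 6)), p)
  expect_equal(out$event, "transition")
  expect_equal(out$state$translocated_A, 13)
  expect_equal(out$state$translocated_res, 2)
  expect_equal(out$state$atp_hydrolyzed, 2)
})

test_that("a dead seam protomer stalls the motor without consuming ATP", {
  p <- motor_params()
  dead <- c(TRUE, rep(FALSE, 5))
  st <- init_motor_state(dead, seam = 1)  # dead protomer already at the seam
  out <- advance_motor(st, p)
  expect_equal(out$event, "stall")
  expect_true(out$state$stalled)
  expect_equal(out$state$atp_hydrolyzed, 0)
  expect_error(advance_motor(out$state, p), "stalled|engaged")
})

test_that("with one dead protomer the motor stalls within one revolution from any phase", {
  for (dead_pos in 1:6) {
    dead <- rep(FALSE, 6); dead[dead_pos] <- TRUE
    for (seam in 1:6) {
      s <- steps_to_stall(dead, seam)
      expect_lte(s, 5)
      # exact count: transitions until the dead protomer reaches the seam
      expect_equal(s, (seam - dead_pos) %% 6)
    }
  }
})

test_that("more dead protomers can only shorten the run before stalling", {
  one_dead <- mean(vapply(1:6, function(pos) {
    dead <- rep(FALSE, 6); dead[pos] <- TRUE
    mean(vapply(1:6, function(s) steps_to_stall(dead, s), numeric(1)))
  }, numeric(1)))
  pairs <- utils::combn(6, 2)
  two_dead <- mean(apply(pairs, 2, function(pp) {
    dead <- rep(FALSE, 6); dead[pp] <- TRUE
    mean(vapply(1:6, function(s) steps_to_stall(dead, s), numeric(1)))
  }))
  expect_lte(two_dead, one_dead)
})

test_that("trajectories are seed-reproducible with consistent counters", {
  p <- motor_params(k_escape = 2, k_reengage = 3, substrate_length = 20)
  dead <- c(FALSE, TRUE, rep(FALSE, 4))
  t1 <- simulate_motor(p, dead, t_end = 50, seed = 42)
  t2 <- simulate_motor(p, dead, t_end = 50, seed = 42)
  expect_identical(t1$event_times, t2$event_times)
  expect_identical(t1$event_kinds, t2$event_kinds)
  expect_identical(t1$final_state, t2$final_state)

  expect_true(all(diff(t1$event_times) > 0))
  prod <- sum(t1$event_kinds %in% c("transition", "substrate_complete"))
  expect_equal(t1$final_state$atp_hydrolyzed, p$atp_per_step * prod)
  expect_equal(t1$n_transitions, prod)
  # ranks stay a permutation with a single seam
  expect_setequal(t1$final_state$rank, 0:5)
})

test_that("long-run ATPase rate of an active hexamer matches the Poisson mean", {
  p <- motor_params(k_step = 1)
  rates <- vapply(1:40, function(i) {
    simulate_motor(p, rep(FALSE, 6), t_end = 250, seed = 1000 + i,
                   record = FALSE)$final_state$atp_hydrolyzed / 250
  }, numeric(1))
  expected <- p$atp_per_step * p$k_step
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), 3 * se)
})

test_that("a permanently stalled motor hydrolyzes no further ATP", {
  p <- motor_params(k_escape = 0)
  dead <- c(TRUE, rep(FALSE, 5))
  tr <- simulate_motor(p, dead, t_end = 1000, seed = 7, seam = 3)
  # at most one revolution of transitions, then silence until t_end
  expect_lte(tr$n_transitions, 5)
  expect_true(tr$final_state$stalled)
})

test_that("ATP per completed substrate follows the step-count argument", {
  L <- 30  # residues; 2 residues/step -> 15 steps/substrate
  p <- motor_params(substrate_length = L)
  tr <- simulate_motor(p, rep(FALSE, 6), t_end = 400, seed = 99, record = FALSE)
  done <- tr$final_state$substrates_completed
  expect_gt(done, 10)
  steps_per_substrate <- ceiling(L / p$step_residues)
  atp_for_completed <- p$atp_per_step * steps_per_substrate * done
  expect_lte(atp_for_completed, tr$final_state$atp_hydrolyzed)
  expect_lt(tr$final_state$atp_hydrolyzed - atp_for_completed,
            p$atp_per_step * steps_per_substrate)
})

test_that("escape events release and re-engage with fresh substrate progress", {
  p <- motor_params(k_escape = 5, k_reengage = 5)
  dead <- c(TRUE, rep(FALSE, 5))
  tr <- simulate_motor(p, dead, t_end = 200, seed = 21)
  kinds <- tr$event_kinds
  expect_true("stall" %in% kinds && "escape" %in% kinds &&
              "reengage" %in% kinds)
  # every escape is preceded by a stall
  esc <- which(kinds == "escape")
  expect_true(all(kinds[esc - 1L] == "stall"))
  # escape lets a doped motor keep hydrolyzing past one revolution
  expect_gt(tr$n_transitions, 5)
})
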