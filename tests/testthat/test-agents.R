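test_that("agent initialization is seed-reproducible and covers all sign patterns", {
  p <- agent_params()
  d0 <- arrowhead(10, 20, 30, shape = 2, color = 3)
  set.seed(5)
  a1 <- init_agent(p, d0)
  set.seed(5)
  a2 <- init_agent(p, d0)
  expect_identical(a1$directions, a2$directions)
  expect_identical(a1$design, d0)
  expect_true(is.na(a1$prev_score))
  # the direction memory is one of the 8 sign patterns, all of which occur
  pats <- replicate(300, {
    paste(init_agent(p, d0)$directions, collapse = ",")
  })
  expect_equal(length(unique(pats)), 8)
})

test_that("Win-Stay keeps the direction when the score does not decrease, flips otherwise", {
  l <- one_d_landscape(optimum = 57, noise_sd = 0)
  p <- agent_params()
  set.seed(1)
  state <- init_agent(p, arrowhead(30, 50, 50))
  state$directions[["length"]] <- 1
  state$prev_score <- expected_fitness(arrowhead(30, 50, 50), l)
  up <- win_stay_step(state, l, attributes = "length")
  expect_equal(up$state$design$length, 35)  # moved toward the optimum
  expect_false(up$record$flipped)
  expect_equal(up$state$directions[["length"]], 1)

  state$directions[["length"]] <- -1  # away from the optimum: score falls
  down <- win_stay_step(state, l, attributes = "length")
  expect_equal(down$state$design$length, 25)
  expect_true(down$record$flipped)
  expect_equal(down$state$directions[["length"]], 1)
})

test_that("first trial stores the score without flipping", {
  l <- one_d_landscape(optimum = 57, noise_sd = 0)
  set.seed(2)
  state <- init_agent(agent_params(), arrowhead(90, 50, 50))
  state$directions[["length"]] <- 1  # away from optimum; would flip if scored
  step <- win_stay_step(state, l, attributes = "length")
  expect_false(step$record$flipped)
  expect_equal(step$state$prev_score, step$record$perceived_score)
})

test_that("a 30-trial noise-free 1-D trajectory equals the brute-force reference", {
  l <- one_d_landscape(optimum = 57, noise_sd = 0)
  set.seed(3)
  state <- init_agent(agent_params(step_size = 5), arrowhead(10, 50, 50))
  state$directions[["length"]] <- 1
  traj <- numeric(30)
  for (t in 1:30) {
    step <- win_stay_step(state, l, attributes = "length")
    state <- step$state
    traj[t] <- state$design$length
  }
  expect_equal(traj, brute_force_win_stay_1d(10, 1, 30, l, step = 5))
  expect_lte(abs(traj[30] - 57), 5)
})

test_that("noise-free 1-D Win-Stay converges near the optimum from every start", {
  l <- one_d_landscape(optimum = 57, noise_sd = 0)
  p <- agent_params(step_size = 5, flip_at_wall = TRUE)
  for (start in 1:100) {
    for (dir in c(-1, 1)) {
      set.seed(start)
      state <- init_agent(p, arrowhead(start, 50, 50))
      state$directions[["length"]] <- dir
      for (t in 1:30) {
        state <- win_stay_step(state, l, attributes = "length")$state
      }
      # after convergence the agent oscillates in a small band around the peak
      expect_lte(abs(state$design$length - 57), 2 * 5)
    }
  }
})

test_that("CSI applies all hunter deltas at once; Reverse negates them", {
  ref <- arrowhead(50, 50, 50)
  deltas <- c(length = 5, width = -5, thickness = 5)
  expect_equal(continuous_values(csi_update(ref, deltas)),
               c(length = 55, width = 45, thickness = 55))
  expect_equal(continuous_values(reverse_update(ref, deltas)),
               c(length = 45, width = 55, thickness = 45))
  zero <- c(length = 0, width = 0, thickness = 0)
  expect_identical(csi_update(ref, zero), ref)
  set.seed(4)
  for (i in 1:25) {
    d <- setNames(sample(-20:20, 3, TRUE), c("length", "width", "thickness"))
    expect_identical(reverse_update(ref, d), csi_update(ref, -d))
  }
  expect_error(csi_update(ref, c(length = 5, width = 5)), "exactly once")
  expect_error(csi_update(ref, c(length = 5, length = 1, width = 0,
                                 thickness = 0)), "exactly once")
})

test_that("updates always keep designs inside the attribute bounds", {
  set.seed(8)
  for (i in 1:50) {
    ref <- arrowhead(sample(1:100, 1), sample(1:100, 1), sample(1:100, 1))
    d <- setNames(sample(-150:150, 3, TRUE), c("length", "width", "thickness"))
    for (upd in list(csi_update(ref, d), reverse_update(ref, d))) {
      v <- continuous_values(upd)
      expect_true(all(v >= 1 & v <= 100))
    }
  }
})

test_that("combining improving single-attribute deltas dominates every single hunter", {
  # additivity implies the combined design beats each single-delta design
  set.seed(9)
  n_checked <- 0
  for (i in 1:200) {
    l <- random_calibrated_landscape()
    v <- sapply(c("length", "width", "thickness"),
                function(a) sample(15:85, 1))
    ref <- arrowhead(v[1], v[2], v[3])
    base <- expected_fitness(ref, l)
    # find an improving delta per attribute (skip attributes at their peak)
    deltas <- sapply(c("length", "width", "thickness"), function(a) {
      sgn <- choose_sign(ref, a, magnitude = sample(3:12, 1), l, "positive")
      if (is.na(sgn)) 0 else sgn * sample(3:12, 1)
    })
    cand <- sapply(c("length", "width", "thickness"), function(a) {
      attribute_contribution(l, a, min(max(v[[a]] + deltas[[a]], 1), 100)) -
        attribute_contribution(l, a, v[[a]])
    })
    deltas[cand < 0] <- 0  # keep only genuinely improving moves
    if (all(deltas == 0)) next
    combined <- expected_fitness(csi_update(ref, deltas), l)
    singles <- sapply(c("length", "width", "thickness"), function(a) {
      one <- setNames(numeric(3), c("length", "width", "thickness"))
      one[a] <- deltas[[a]]
      expected_fitness(csi_update(ref, one), l)
    })
    expect_gte(combined, max(singles) - 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("reversing worsening deltas improves fitness away from the optimum", {
  set.seed(10)
  wins <- 0; total <- 0
  for (i in 1:200) {
    l <- random_calibrated_landscape()
    # place the reference well off every optimum and away from the bounds
    v <- sapply(c("length", "width", "thickness"), function(a) {
      o <- l$optima[[a]]
      min(max(if (o < 50) o + sample(15:25, 1) else o - sample(15:25, 1), 10), 90)
    })
    ref <- arrowhead(v[1], v[2], v[3])
    deltas <- sapply(c("length", "width", "thickness"), function(a) {
      sgn <- choose_sign(ref, a, magnitude = 8, l, "negative")
      if (is.na(sgn)) 0 else sgn * 8
    })
    if (all(deltas == 0)) next
    total <- total + 1
    res <- expected_fitness(reverse_update(ref, deltas), l)
    if (res >= expected_fitness(ref, l)) wins <- wins + 1
  }
  # exceptions can occur when the reversed step overshoots a nearby peak
  expect_gt(wins / total, 0.9)
})
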