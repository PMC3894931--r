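# Fixed-step engine: closed-form oracle, determinism, R/C++ parity,
# termination semantics, and per-frame invariants.

test_that("a lone informed agent matches the straight-line closed form", {
  arena <- build_small_arena()
  ag <- lone_agent(target = 1L, speed = 0.4)
  # one step moves the agent 0.4/(0.05*60) px towards the target
  set.seed(51)
  st <- sim_step(new_sim_state(ag, arena))
  expect_equal(st$agents$y, 0.4 / 3, tolerance = 1e-12)
  expect_equal(st$agents$x, 0, tolerance = 1e-12)
  # full run: 5 m at 0.4 m/s = 12.5 s, within one frame
  set.seed(51)
  res <- run_simulation(ag, arena)
  expect_lte(abs(res$time - 12.5), 1 / 60 + 1e-9)
  expect_equal(res$number_reached, 1L)
  expect_true(res$accurate)
})

test_that("two distant agents outside mutual range move like lone agents", {
  arena <- build_large_arena()
  # informed pair far apart (beyond repulsion), same target; single-agent
  # worlds give the reference trajectories
  two <- data.frame(id = 1:2, letter = NA_character_,
                    x = c(0, 60), y = c(0, 0), hx = 1, hy = 0,
                    speed = 0.4, informed = TRUE, target = 5L)
  set.seed(52)
  r2 <- run_simulation(two, arena, max_time = 2, engine = "cpp",
                       log_every = 1)
  set.seed(52)
  r1 <- run_simulation(two[1, ], arena, max_time = 2, engine = "cpp",
                       log_every = 1)
  expect_equal(r2$trajectory$positions[, 1, ],
               r1$trajectory$positions[, 1, ], tolerance = 1e-12)
})

test_that("identical seeds reproduce a run bit-for-bit", {
  arena <- build_small_arena()
  tr <- treatment("small", informed = c("J", "E"), target = 9)
  set.seed(53); ag <- initialise_agents(arena, tr)
  set.seed(99); a <- run_simulation(ag, arena)
  set.seed(99); b <- run_simulation(ag, arena)
  expect_identical(a$time, b$time)
  expect_identical(a$number_reached, b$number_reached)
  expect_identical(a$arrived, b$arrived)
})

test_that("compiled and reference engines produce the same trajectories", {
  arena <- build_small_arena()
  tr <- treatment("small", informed = c("J", "E"), target = 5)
  for (wb in c("anchored", "realised")) {
    p <- default_params(wander_base = wb)
    set.seed(54); ag <- initialise_agents(arena, tr)
    set.seed(77)
    rc <- run_simulation(ag, arena, p, max_time = 1.5, engine = "cpp",
                         log_every = 1)
    set.seed(77)
    rr <- run_simulation(ag, arena, p, max_time = 1.5, engine = "r",
                         log_every = 1)
    expect_equal(rc$trajectory$positions, rr$trajectory$positions,
                 tolerance = 1e-9)
  }
})

test_that("per-frame displacement obeys the triangle inequality bound", {
  arena <- build_small_arena()
  set.seed(55)
  ag <- random_agents(8, k = 2, target = 3, radius = 30)
  st <- new_sim_state(ag, arena)
  for (step in 1:20) {
    before <- cbind(st$agents$x, st$agents$y)
    es <- speed_to_es(st$agents$speed)
    D <- as.matrix(stats::dist(before))
    st <- sim_step(st)
    after <- cbind(st$agents$x, st$agents$y)
    disp <- sqrt(rowSums((after - before)^2))
    for (a in seq_len(nrow(ag))) {
      # one active behaviour of magnitude E_s plus the repulsion sum
      bound <- es[a] * (1 + sum(g_linear(D[a, -a]))) + 1e-9
      expect_lte(disp[a], bound)
    }
  }
})

test_that("termination ties break to the lower number index", {
  arena <- build_small_arena()
  # exact tie: replace two cards so the centroid is FP-equidistant
  arena$number_positions[1, ] <- c(110, 10)
  arena$number_positions[2, ] <- c(110, -10)
  ag <- lone_agent()
  ag$x <- 110; ag$y <- 0    # beyond the circle, equidistant from both cards
  st <- new_sim_state(ag, arena)
  rec <- check_termination(st, policy = "centroid")
  expect_equal(rec$number_reached, 1L)
})

test_that("centroid inside the circle does not terminate; timeout is flagged", {
  arena <- build_small_arena()
  ag <- lone_agent()
  ag$x <- 99; ag$y <- 0
  expect_null(check_termination(new_sim_state(ag, arena), policy = "centroid"))
  set.seed(56)
  res <- run_simulation(lone_agent(), arena, max_time = 0.05)
  expect_false(res$terminated)
  expect_true(is.na(res$time))
  expect_true(is.na(res$number_reached))
})

test_that("number capture ends a run only within the capture radius", {
  arena <- build_small_arena()
  p <- default_params(termination = "number_capture", capture_radius = 10)
  ag <- lone_agent()
  # 12 px from card 1 at (0, 100): not yet captured
  ag$x <- 0; ag$y <- 88
  st <- new_sim_state(ag, arena, p)
  expect_null(check_termination(st))
  ag$y <- 92   # 8 px away: captured
  st <- new_sim_state(ag, arena, p)
  rec <- check_termination(st)
  expect_equal(rec$number_reached, 1L)
})

test_that("arrival flags mark agents within the arrival band", {
  arena <- build_small_arena()
  ag <- rbind(lone_agent(), lone_agent())
  ag$id <- 1:2
  ag$x <- c(0, 0); ag$y <- c(130, 70)   # centroid at 100: terminated
  st <- new_sim_state(ag, arena)
  rec <- check_termination(st)
  expect_equal(rec$arrived, c(TRUE, FALSE))  # 70 px is outside the 20 px band
})

test_that("small groups stay cohesive under the default rules", {
  arena <- build_small_arena()
  tr <- treatment("small", informed = c("J", "E"), target = 11)
  frac <- numeric(0)
  for (seed in 57:59) {
    set.seed(seed)
    ag <- initialise_agents(arena, tr)
    res <- run_simulation(ag, arena, log_every = 6)
    span <- apply(res$trajectory$positions, 1, function(P) {
      max(stats::dist(P))
    })
    frac <- c(frac, mean(span <= default_params()$group_range))
  }
  # max pairwise spread rarely exceeds the 5 m group range
  expect_gt(mean(frac), 0.95)
})
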