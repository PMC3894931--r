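# Arena geometry and initial placement.

test_that("small arena has the documented geometry", {
  a <- build_small_arena()
  num <- a$number_positions
  expect_equal(nrow(num), 16)
  expect_equal(a$outer_radius, 100)        # 10 m diameter at 0.05 m/px
  expect_equal(a$inner_radius, 20)         # 2 m diameter
  # all numbers on the outer circle
  expect_equal(unname(sqrt(num[, 1]^2 + num[, 2]^2)), rep(100, 16))
  # equally spaced: all consecutive angular gaps equal 2*pi/16
  ang <- atan2(num[, 2], num[, 1])
  gaps <- unname(diff(ang) %% (2 * pi))
  expect_equal(gaps, rep(gaps[1], 15), tolerance = 1e-12)
  # chord between adjacent numbers: 2 * 100 * sin(pi/16) ~ 39.0 px ~ 1.95 m
  chord <- sqrt(sum((num[1, ] - num[2, ])^2))
  expect_equal(chord, 2 * 100 * sin(pi / 16), tolerance = 1e-12)
  expect_equal(chord, 39.018, tolerance = 1e-4)
})

test_that("start letters sit on the inner circle with I and J at the centre", {
  a <- build_small_arena()
  lp <- a$letter_positions
  expect_equal(rownames(lp), LETTERS[1:10])
  r <- sqrt(lp[, 1]^2 + lp[, 2]^2)
  expect_equal(unname(r[1:8]), rep(20, 8))        # A-H at 1 m radius
  expect_true(all(r <= a$inner_radius + 1e-9))    # all within the inner circle
  # I and J occupy the centre exactly an arm's length (0.7 m = 14 px) apart
  expect_equal(sqrt(sum((lp["I", ] - lp["J", ])^2)), 14)
})

test_that("large arena fixes the 12 m inner circle and validates the outer", {
  a <- build_large_arena()
  expect_equal(a$inner_radius, 120)
  expect_equal(a$outer_radius, 300)
  expect_equal(nrow(a$number_positions), 16)
  a2 <- build_large_arena(50)
  expect_equal(a2$inner_radius, 120)
  expect_equal(a2$outer_radius, 500)
  expect_error(build_large_arena(10), "exceed")
})

test_that("small-arena initialisation puts informed flags on the treatment letters", {
  a <- build_small_arena()
  set.seed(31)
  ag <- initialise_agents(a, treatment("small", informed = c("J", "E"),
                                       target = 3))
  expect_equal(nrow(ag), 10)
  expect_equal(ag$letter[ag$informed], c("E", "J"))
  expect_equal(unique(ag$target[ag$informed]), 3L)
  expect_true(all(is.na(ag$target[!ag$informed])))
  # agents stand exactly on their letters
  expect_equal(cbind(ag$x, ag$y), unname(a$letter_positions))
  ag4 <- initialise_agents(a, treatment("small", informed = c("I", "J"),
                                        target = 1))
  expect_equal(ag4$letter[ag4$informed], c("I", "J"))
})

test_that("every initial heading points at one of the 16 numbers", {
  a <- build_small_arena()
  set.seed(32)
  ag <- initialise_agents(a, treatment("small", informed = c("I", "J"),
                                       target = 1))
  for (i in seq_len(nrow(ag))) {
    units <- t(apply(a$number_positions, 1, function(p) {
      v <- p - c(ag$x[i], ag$y[i]); v / sqrt(sum(v^2))
    }))
    err <- apply(units, 1, function(u) sum(abs(u - c(ag$hx[i], ag$hy[i]))))
    expect_lt(min(err), 1e-9)
    expect_equal(sqrt(ag$hx[i]^2 + ag$hy[i]^2), 1, tolerance = 1e-12)
  }
})

test_that("per-agent speeds are jittered once within +/- 10%", {
  a <- build_small_arena()
  set.seed(33)
  ag <- initialise_agents(a, treatment("small", informed = c("I", "J"),
                                       target = 1, speed = 0.4))
  expect_true(all(ag$speed >= 0.9 * 0.4 & ag$speed <= 1.1 * 0.4))
  expect_gt(length(unique(ag$speed)), 1)
})

test_that("large-arena initialisation respects count, bounds and separation", {
  a <- build_large_arena()
  set.seed(34)
  ag <- initialise_agents(a, treatment("large", informed_percentage = 0.15,
                                       target = 7))
  expect_equal(nrow(ag), 200)
  expect_equal(sum(ag$informed), round(0.15 * 200))  # 30 informed
  r <- sqrt(ag$x^2 + ag$y^2)
  expect_true(all(r <= a$inner_radius))
  D <- as.matrix(stats::dist(cbind(ag$x, ag$y)))
  diag(D) <- Inf
  expect_gte(min(D), 7)
  # reproducible bit-for-bit under the same seed
  set.seed(34)
  ag2 <- initialise_agents(a, treatment("large", informed_percentage = 0.15,
                                        target = 7))
  expect_identical(ag, ag2)
})

test_that("infeasible placement separation raises a placement error", {
  a <- build_large_arena()
  set.seed(35)
  tr <- treatment("large", informed_percentage = 0.05, target = 1,
                  min_separation = 30, max_attempts = 50)
  expect_error(initialise_agents(a, tr), "could not place")
})

test_that("treatment validation rejects inconsistent configurations", {
  expect_error(treatment("small", informed = c("Z")), "A..J")
  expect_error(treatment("large", informed_percentage = 1.5), "0, 1")
  expect_error(treatment("small", informed = "A", target = 17), "1..16")
  a <- build_small_arena()
  expect_error(initialise_agents(a, treatment("large",
                                              informed_percentage = 0.1,
                                              target = 1)),
               "disagree")
})
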