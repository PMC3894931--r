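# Behaviour-effect kernels: worked examples, degenerate branches, and the
# algebraic properties every rule inherits from the core kernel.

test_that("speed conversion gives pixels per frame at the simulation scale", {
  expect_equal(speed_to_es(0.4, 0.05, 60), 0.4 / 3, tolerance = 1e-12)
  expect_equal(speed_to_es(0.4, 0.05, 60), 0.13333333, tolerance = 1e-6)
  expect_equal(speed_to_es(0.05 * 60, 0.05, 60), 1)
  expect_equal(speed_to_es(1.2, 0.05, 60), 0.4)
  expect_error(speed_to_es(-1), "positive")
  expect_error(speed_to_es(0.4, 0), "positive")
})

test_that("core effect matches hand-computed examples", {
  expect_equal(core_effect(c(0, 0), c(10, 0), e_s = 1), c(1, 0))
  expect_equal(core_effect(c(0, 0), c(10, 0), e_s = 1, alpha = pi), c(-1, 0),
               tolerance = 1e-12)
  # normalise (3,4) -> (0.6, 0.8), scale by 2 * 0.5
  expect_equal(core_effect(c(0, 0), c(3, 4), e_s = 2, f_a = 0.5), c(0.6, 0.8))
  expect_error(core_effect(c(1, 1), c(1, 1), e_s = 1),
               class = "crowd_degenerate_error")
})

test_that("core effect magnitude equals E_s * F_a * F_t * F_d (property)", {
  set.seed(401)
  for (i in 1:200) {
    p_a <- runif(2, -50, 50)
    p_t <- runif(2, -50, 50)
    if (sqrt(sum((p_t - p_a)^2)) < 1e-6) next
    es <- runif(1, 0.01, 5)
    fa <- runif(1, 0, 2); ft <- runif(1, 0, 2); fd <- runif(1, 0, 2)
    al <- runif(1, -pi, pi)
    eff <- core_effect(p_a, p_t, es, fa, ft, fd, al)
    expect_equal(sqrt(sum(eff^2)), es * fa * ft * fd, tolerance = 1e-10)
  }
})

test_that("rotations compose additively and alpha = 0 is the identity", {
  set.seed(402)
  for (i in 1:50) {
    v <- runif(2, -3, 3)
    a1 <- runif(1, -pi, pi); a2 <- runif(1, -pi, pi)
    expect_equal(rotate_vec(v, 0), v)
    expect_equal(rotate_vec(rotate_vec(v, a1), a2), rotate_vec(v, a1 + a2),
                 tolerance = 1e-12)
  }
})

test_that("seek-to points straight at the target with magnitude E_s*F_a*F_t", {
  expect_equal(seek_to(c(0, 0), c(0, 5), e_s = 0.4 / 3), c(0, 0.4 / 3))
  expect_equal(seek_to(c(1, 1), c(1, 2), e_s = 1), c(0, 1))
  set.seed(403)
  for (i in 1:50) {
    p_a <- runif(2, -20, 20); p_t <- runif(2, -20, 20)
    if (sqrt(sum((p_t - p_a)^2)) < 1e-6) next
    eff <- seek_to(p_a, p_t, e_s = 0.7)
    d <- p_t - p_a
    # collinear, same sense
    expect_equal(eff / sqrt(sum(eff^2)), d / sqrt(sum(d^2)), tolerance = 1e-10)
  }
})

test_that("wander keeps the heading with turn probability 0 and conserves speed", {
  st <- wander_state(c(1, 0), turn_probability = 0)
  w <- wander(st, e_s = 0.25, f_a = 2)
  expect_equal(w$effect, c(0.5, 0))
  expect_equal(w$state$heading, c(1, 0))
  # magnitude law holds whatever angle is drawn
  set.seed(404)
  st <- wander_state(c(0, 1), turn_probability = 1)
  for (i in 1:50) {
    w <- wander(st, e_s = 0.13)
    st <- w$state
    expect_equal(sqrt(sum(w$effect^2)), 0.13, tolerance = 1e-12)
    expect_equal(sqrt(sum(st$heading^2)), 1, tolerance = 1e-12)
  }
})

test_that("wander turn angles are uniform on [-theta, +theta]", {
  set.seed(405)
  n <- 1e5
  angles <- numeric(n)
  for (i in seq_len(n)) {
    w <- wander(wander_state(c(1, 0), turn_probability = 1), e_s = 1)
    angles[i] <- atan2(w$effect[2], w$effect[1])
  }
  expect_true(all(angles >= -0.5 & angles <= 0.5))
  expect_lt(abs(mean(angles)), 3 * 0.5 / sqrt(3) / sqrt(n))
  ks <- suppressWarnings(stats::ks.test(angles, "punif", -0.5, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("keep-in-group combines cohesion and alignment as documented", {
  # mean neighbour position directly above the agent -> cohesion = (0, 1)
  pos <- rbind(c(0, 0), c(2, 0))
  ori <- rbind(c(1, 0), c(1, 0))
  eff <- keep_in_group(c(1, -1), pos, ori, e_s = 1)
  # cohesion (0,1) + alignment (1,0), renormalised
  expect_equal(eff, c(1, 1) / sqrt(2), tolerance = 1e-12)
  # alignment equal to the cohesion direction adds nothing new
  eff2 <- keep_in_group(c(1, -1), pos, rbind(c(0, 1), c(0, 1)), e_s = 2)
  expect_equal(eff2, c(0, 2), tolerance = 1e-12)
  # agent at the mean position -> pure alignment
  eff3 <- keep_in_group(c(1, 0), pos, ori, e_s = 1)
  expect_equal(eff3, c(1, 0), tolerance = 1e-12)
  # magnitude law
  expect_equal(sqrt(sum(eff^2)), 1, tolerance = 1e-12)
  expect_error(keep_in_group(c(0, 0), pos[0, , drop = FALSE],
                             ori[0, , drop = FALSE], 1),
               class = "crowd_no_neighbours_error")
})

test_that("crowd repulsion has the documented support and magnitudes", {
  # everyone beyond the threshold -> exactly zero
  far <- rbind(c(20, 0), c(0, -30), c(14, 0))
  expect_equal(crowd_repulsion(c(0, 0), far, e_s = 1), c(0, 0))
  # symmetric pair cancels
  expect_equal(crowd_repulsion(c(0, 0), rbind(c(5, 0), c(-5, 0)), e_s = 1),
               c(0, 0))
  # single pair against a hand-computed g: g(5) = (14-5)/14
  eff <- crowd_repulsion(c(0, 0), rbind(c(5, 0)), e_s = 0.4 / 3)
  expect_equal(eff, c(-(0.4 / 3) * (14 - 5) / 14, 0), tolerance = 1e-12)
  # invariant to adding any agent at distance >= threshold
  set.seed(406)
  for (i in 1:30) {
    crowd <- matrix(runif(10, -10, 10), ncol = 2)
    base <- crowd_repulsion(c(0, 0), crowd, e_s = 1)
    ang <- runif(1, 0, 2 * pi)
    extra <- (14 + runif(1, 0, 30)) * c(cos(ang), sin(ang))
    expect_equal(crowd_repulsion(c(0, 0), rbind(crowd, extra), e_s = 1), base)
  }
})

test_that("g_linear is a continuous non-increasing ramp hitting 0 at threshold", {
  expect_equal(g_linear(0), 1)
  expect_equal(g_linear(7), 0.5)
  expect_equal(g_linear(14), 0)
  expect_equal(g_linear(100), 0)
  d <- seq(0.1, 13.9, by = 0.1)
  expect_true(all(diff(g_linear(d)) < 0))
})

test_that("effects combine by Euclidean addition", {
  expect_equal(combine_effects(list(c(1, 0), c(0, 1))), c(1, 1))
  expect_equal(combine_effects(list(c(1, 0), c(-1, 0))), c(0, 0))
  expect_equal(combine_effects(list()), c(0, 0))
})

test_that("all kernels are isotropic (rotating the world rotates the output)", {
  set.seed(407)
  for (i in 1:25) {
    b <- runif(1, -pi, pi)
    p_a <- runif(2, -20, 20)
    p_t <- runif(2, -20, 20)
    crowd <- matrix(runif(12, -8, 8), ncol = 2)
    ori <- t(apply(matrix(runif(6, 0, 2 * pi), ncol = 1), 1,
                   function(a) c(cos(a), sin(a))))
    rot_m <- function(M) t(apply(M, 1, rot2, a = b))
    expect_equal(core_effect(rot2(p_a, b), rot2(p_t, b), 1, alpha = 0.3),
                 rot2(core_effect(p_a, p_t, 1, alpha = 0.3), b),
                 tolerance = 1e-10)
    expect_equal(crowd_repulsion(rot2(p_a, b), rot_m(crowd), 1),
                 rot2(crowd_repulsion(p_a, crowd, 1), b),
                 tolerance = 1e-10)
    expect_equal(keep_in_group(rot2(p_a, b), rot_m(crowd), rot_m(ori), 1),
                 rot2(keep_in_group(p_a, crowd, ori, 1), b),
                 tolerance = 1e-10)
  }
})
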