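# Behaviour-effect kernels.
#
# Every behaviour rule is derived from one core kernel: take the unit vector
# from the agent towards a (possibly virtual) target, rotate it by alpha
# (anti-clockwise), and scale by E_s * F_a * F_t * F_d.  The result, the
# "behaviour effect", is the displacement (in pixels) that the behaviour
# contributes over one update interval, i.e. an average velocity times the
# frame period.  Effects from several behaviours are combined by plain
# Euclidean vector addition.

#' Convert a walking speed to a per-frame base movement effect
#'
#' The base movement effect `E_s` is the distance, in pixels, an agent
#' walking at `speed` covers in one update interval.
#'
#' @param speed Walking speed in m/s; strictly positive.
#' @param unit_scale Metres per pixel; default 0.05 (1 px = 5 cm).
#' @param frame_rate Simulation update rate in frames per second; default 60.
#' @return Base movement effect in pixels per frame:
#'   `speed / (unit_scale * frame_rate)`.
#' @examples
#' speed_to_es(0.4)        # 0.1333... px/frame at the default scale
#' speed_to_es(1.2)        # 0.4 px/frame
#' @export
speed_to_es <- function(speed, unit_scale = 0.05, frame_rate = 60) {
  args <- c(speed, unit_scale, frame_rate)
  if (!all(is.finite(args)) || any(args <= 0)) {
    stop("speed, unit_scale and frame_rate must all be finite and strictly positive")
  }
  speed / (unit_scale * frame_rate)
}

#' Core behaviour-effect kernel
#'
#' Returns `E_s * F_a * F_t * F_d * Rotate(Normalise(p_t - p_a), alpha)`.
#' All specific behaviour rules are parameterisations of this kernel, so the
#' magnitude of any (single-target) behaviour effect is exactly
#' `e_s * f_a * f_t * f_d`.
#'
#' @param p_a Agent position, numeric length-2 (pixels).
#' @param p_t Target position, numeric length-2 (pixels).
#' @param e_s Base movement effect (pixels/frame), see [speed_to_es()].
#' @param f_a Influence coefficient of the agent itself (default 1).
#' @param f_t Influence coefficient of the target (default 1).
#' @param f_d Influence coefficient of distance (default 1).
#' @param alpha Anti-clockwise rotation angle in radians (default 0).
#' @return Behaviour effect, numeric length-2 (pixels/frame).
#' @examples
#' core_effect(c(0, 0), c(10, 0), e_s = 1)                # (1, 0)
#' core_effect(c(0, 0), c(10, 0), e_s = 1, alpha = pi)    # (-1, 0)
#' @export
core_effect <- function(p_a, p_t, e_s, f_a = 1, f_t = 1, f_d = 1, alpha = 0) {
  d <- c(p_t[1] - p_a[1], p_t[2] - p_a[2])
  if (vec_norm(d) < .eps) {
    stop_degenerate("agent and target coincide: behaviour direction undefined")
  }
  (e_s * f_a * f_t * f_d) * rotate_vec(normalise_vec(d), alpha)
}

#' Seek-to behaviour effect
#'
#' Moves the agent straight towards the target: the core kernel with
#' `alpha = 0` and `f_d = 1` (the effect is independent of distance).
#'
#' @inheritParams core_effect
#' @return Behaviour effect pointing from `p_a` towards `p_t`, magnitude
#'   `e_s * f_a * f_t`.
#' @export
seek_to <- function(p_a, p_t, e_s, f_a = 1, f_t = 1) {
  core_effect(p_a, p_t, e_s, f_a = f_a, f_t = f_t, f_d = 1, alpha = 0)
}

#' Construct a wandering state
#'
#' @param heading Current unit heading, numeric length-2.
#' @param theta_max Half-range of the random turn in radians (default 0.5).
#' @param turn_probability Probability of redrawing the heading per update
#'   interval (default 0.05).
#' @return An object of class `wander_state`.
#' @export
wander_state <- function(heading, theta_max = 0.5, turn_probability = 0.05) {
  if (theta_max <= 0) stop("theta_max must be > 0")
  if (turn_probability < 0 || turn_probability > 1) {
    stop("turn_probability must lie in [0, 1]")
  }
  if (abs(vec_norm(heading) - 1) > 1e-8) {
    stop("heading must be a unit vector")
  }
  structure(list(heading = heading, theta_max = theta_max,
                 turn_probability = turn_probability),
            class = "wander_state")
}

#' Wandering behaviour effect
#'
#' With probability `turn_probability`, rotates the heading by an angle drawn
#' uniformly from `[-theta_max, +theta_max]`; otherwise keeps it.  The effect
#' is a full step of magnitude `e_s * f_a` along the (possibly rotated)
#' heading -- the agent seeks a virtual target in front of itself, so the
#' wander trajectory is smooth rather than twitchy.  Consumes one or two
#' draws from the R RNG stream.
#'
#' @param state A [wander_state()].
#' @param e_s Base movement effect (pixels/frame).
#' @param f_a Influence coefficient of the agent itself (default 1).
#' @return A list with elements `effect` (length-2 numeric) and `state`
#'   (the updated `wander_state`).
#' @export
wander <- function(state, e_s, f_a = 1) {
  h <- state$heading
  u <- runif(1)
  if (u < state$turn_probability) {
    ang <- runif(1, -state$theta_max, state$theta_max)
    h <- rotate_vec(h, ang)
  }
  state$heading <- h
  list(effect = (e_s * f_a) * h, state = state)
}

#' Keep-in-group behaviour effect
#'
#' Combines (a) a cohesion effect seeking the mean position of the nearby
#' group members with (b) an alignment effect adjusting towards their mean
#' heading.  Each component is unit-normalised, the two are summed and
#' re-normalised, and the result is scaled by `e_s * f_a`, preserving the
#' model-wide magnitude law.  Degenerate cases: if the agent already sits at
#' the neighbours' mean position the effect is pure alignment; if the mean
#' orientation vanishes the effect is pure cohesion; if the two unit
#' components cancel exactly, cohesion wins.
#'
#' @param p_a Agent position, numeric length-2 (pixels).
#' @param neighbour_pos Matrix (m x 2) of neighbour positions; m >= 1.
#' @param neighbour_ori Matrix (m x 2) of neighbour unit headings.
#' @param e_s Base movement effect (pixels/frame).
#' @param f_a Influence coefficient of the agent itself (default 1).
#' @return Behaviour effect of magnitude `e_s * f_a`.
#' @export
keep_in_group <- function(p_a, neighbour_pos, neighbour_ori, e_s, f_a = 1) {
  neighbour_pos <- rbind(neighbour_pos)
  neighbour_ori <- rbind(neighbour_ori)
  dimnames(neighbour_pos) <- NULL
  dimnames(neighbour_ori) <- NULL
  p_a <- unname(p_a)
  m <- nrow(neighbour_pos)
  if (m == 0L) {
    stop_no_neighbours("keep_in_group requires at least one neighbour")
  }
  mean_pos <- colMeans(neighbour_pos)
  mean_ori <- colMeans(neighbour_ori)
  coh <- c(mean_pos[1] - p_a[1], mean_pos[2] - p_a[2])
  nc <- vec_norm(coh)
  no <- vec_norm(mean_ori)
  if (nc < .eps) {
    if (no < .eps) {
      stop_degenerate("cohesion and alignment directions both undefined")
    }
    dir <- mean_ori / no
  } else if (no < .eps) {
    dir <- coh / nc
  } else {
    c1 <- coh / nc
    o1 <- mean_ori / no
    s <- c1 + o1
    ns <- vec_norm(s)
    dir <- if (ns < .eps) c1 else s / ns
  }
  (e_s * f_a) * dir
}

#' Linear distance-weight for the crowd repulsion rule
#'
#' The piecewise distance function g(d): a linear ramp from 1 at contact to 0
#' at the threshold, and exactly 0 at or beyond it.  Continuous at the
#' threshold, non-increasing on (0, threshold].
#'
#' @param d Distance(s) in pixels.
#' @param threshold Distance (pixels) at which repulsion ceases; default 14
#'   (0.7 m, an arm's length).
#' @return Weight(s) in \[0, 1\].
#' @export
g_linear <- function(d, threshold = 14) {
  ifelse(d >= threshold, 0, (threshold - d) / threshold)
}

#' Crowd repulsion behaviour effect
#'
#' Vector sum, over every other agent closer than the threshold, of the core
#' kernel with `alpha = pi` (pointing away from that agent) and
#' `f_d = g(d)`.  Agents at or beyond the threshold contribute exactly zero.
#' Coincident agents (d = 0) contribute a uniformly random direction at full
#' weight instead of crashing.
#'
#' @param p_a Agent position, numeric length-2 (pixels).
#' @param crowd_pos Matrix (m x 2) of the other agents' positions; may have
#'   zero rows.
#' @param e_s Base movement effect (pixels/frame).
#' @param f_a Influence coefficient of the agent itself (default 1).
#' @param threshold Repulsion onset distance in pixels (default 14).
#' @param strength Distance-weight function `g(d, threshold)`; default
#'   [g_linear()].
#' @return Combined repulsive effect, numeric length-2; `c(0, 0)` when no
#'   agent is within the threshold.
#' @export
crowd_repulsion <- function(p_a, crowd_pos, e_s, f_a = 1, threshold = 14,
                            strength = g_linear) {
  crowd_pos <- rbind(crowd_pos)
  dimnames(crowd_pos) <- NULL
  p_a <- unname(p_a)
  acc <- c(0, 0)
  m <- nrow(crowd_pos)
  if (m == 0L) return(acc)
  for (i in seq_len(m)) {
    v <- c(p_a[1] - crowd_pos[i, 1], p_a[2] - crowd_pos[i, 2])
    d <- vec_norm(v)
    if (d < threshold) {
      w <- strength(d, threshold)
      dir <- if (d < .eps) random_unit() else v / d
      acc <- acc + w * dir
    }
  }
  (e_s * f_a) * acc
}

#' Combine behaviour effects by Euclidean vector addition
#'
#' @param effects A list of length-2 numeric vectors (possibly empty).
#' @return Component-wise sum; `c(0, 0)` for an empty list.
#' @export
combine_effects <- function(effects) {
  if (length(effects) == 0L) return(c(0, 0))
  Reduce(`+`, effects)
}
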