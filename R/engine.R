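# Fixed-step simulation engine.
#
# The compiled loop (crowd_run_cpp) carries batch workloads; sim_step() is
# the pure-R reference implementation of one frame, used for inspection and
# for the parity test that pins the two to identical trajectories.  Both
# consume the R RNG stream in the same order, so either path is
# bit-reproducible under set.seed().

#' Engine parameters
#'
#' All distances are in pixels (1 px = `unit_scale` metres).
#'
#' @param unit_scale Metres per pixel (default 0.05).
#' @param frame_rate Updates per second (default 60); the update interval is
#'   `1/frame_rate` s.
#' @param arms_length Arm's-length distance in px (default 14 = 0.7 m); both
#'   the group-membership trigger and the repulsion onset distance.
#' @param group_range Group perception range in px (default 100 = 5 m).
#' @param repulsion_threshold Repulsion onset distance in px (default 14).
#' @param theta_max Wandering half-turn angle in radians (default 0.5).
#' @param turn_probability Wandering turn probability per frame (default 0.05).
#' @param arrival_band Band inside the periphery (px) within which an agent
#'   counts as individually arrived (default 20 = 1 m).
#' @param policy Behaviour-selection policy, see [select_behaviours()].
#' @param wander_base Base direction the wandering turn applies to:
#'   `"anchored"` (default: straight lines between turns, each turn
#'   re-anchors to the realised heading), `"persistent"` (the wander
#'   heading evolves only through the turns) or `"realised"` (re-anchored
#'   every frame).
#' @param group_status How "in the group" is decided: `"component"`
#'   (default: membership of the largest arm's-length-connected component)
#'   or `"nearest"` (any other agent within arm's length).
#' @param termination `"centroid"` (default) ends a run when the group
#'   centroid crosses the outer circle; `"number_capture"` ends it when the
#'   centroid comes within `capture_radius` of a number card.
#' @param capture_radius Capture distance in px for the `"number_capture"`
#'   policy (default 10 = 0.5 m).
#' @return A named list of engine parameters.
#' @export
default_params <- function(unit_scale = 0.05, frame_rate = 60,
                           arms_length = 14, group_range = 100,
                           repulsion_threshold = 14, theta_max = 0.5,
                           turn_probability = 0.05, arrival_band = 20,
                           policy = c("strict_flowchart", "blend"),
                           wander_base = c("anchored", "persistent", "realised"),
                           group_status = c("component", "nearest"),
                           termination = c("centroid", "number_capture"),
                           capture_radius = 10) {
  policy <- match.arg(policy)
  wander_base <- match.arg(wander_base)
  group_status <- match.arg(group_status)
  termination <- match.arg(termination)
  list(unit_scale = unit_scale, frame_rate = frame_rate, dt = 1 / frame_rate,
       arms_length = arms_length, group_range = group_range,
       repulsion_threshold = repulsion_threshold, theta_max = theta_max,
       turn_probability = turn_probability, arrival_band = arrival_band,
       policy = policy, wander_base = wander_base,
       group_status = group_status, termination = termination,
       capture_radius = capture_radius)
}

#' Create a simulation state
#'
#' @param agents Agent data frame from [initialise_agents()].
#' @param arena A `crowd_arena`.
#' @param params Engine parameters from [default_params()].
#' @return An object of class `sim_state` at time 0.
#' @export
new_sim_state <- function(agents, arena, params = default_params()) {
  structure(list(time = 0, frame = 0L, agents = agents, arena = arena,
                 params = params, terminated = FALSE,
                 termination_record = NULL,
                 wander_h = cbind(agents$hx, agents$hy),
                 wandered = rep(FALSE, nrow(agents)),
                 crossing_time = NA_real_),
            class = "sim_state")
}

# In-group flags for all agents: either nearest-neighbour arm's length, or
# membership of the largest arm's-length-connected component (so a pair that
# drifts off together still counts as having left the group).
group_flags <- function(D, arms_length, mode) {
  n <- nrow(D)
  if (n == 1L) return(TRUE)
  if (mode == "nearest") {
    Dx <- D
    diag(Dx) <- Inf
    return(apply(Dx, 1, min) <= arms_length)
  }
  adj <- D <= arms_length
  diag(adj) <- FALSE
  comp <- integer(n)
  for (a in seq_len(n)) {
    if (comp[a] != 0L) next
    queue <- a
    comp[a] <- a  # label = smallest member index
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- a
      queue <- c(queue, nb)
    }
  }
  sizes <- table(comp)
  main <- as.integer(names(sizes)[which.max(sizes)])  # ties: smallest label
  comp == main
}

run_target_xy <- function(agents, arena) {
  tg <- unique(agents$target[!is.na(agents$target)])
  if (length(tg) == 0L) return(list(target = NA_integer_, xy = c(0, 0)))
  if (length(tg) > 1L) stop("informed agents disagree on the target")
  list(target = as.integer(tg), xy = unname(arena$number_positions[tg, ]))
}

#' Advance the simulation by one frame (reference implementation)
#'
#' Computes every agent's behaviour effects from the current frame's state,
#' applies all displacements synchronously, sets each heading to the
#' direction of its realised displacement (kept when the displacement is
#' zero), and advances time by one update interval.  Termination is the
#' caller's job via [check_termination()].
#'
#' @param state A `sim_state`.
#' @return The updated `sim_state`.
#' @export
sim_step <- function(state) {
  if (state$terminated) stop("cannot step a terminated simulation")
  p <- state$params
  ag <- state$agents
  n <- nrow(ag)
  pos <- cbind(ag$x, ag$y)
  hed <- cbind(ag$hx, ag$hy)
  es <- speed_to_es(ag$speed, p$unit_scale, p$frame_rate)
  tgt <- run_target_xy(ag, state$arena)

  D <- if (n > 1L) as.matrix(dist(pos)) else matrix(0, 1, 1)
  disp <- matrix(0, n, 2)
  in_group_all <- group_flags(D, p$arms_length, p$group_status)

  for (a in seq_len(n)) {
    da <- D[a, ]
    da[a] <- Inf
    in_group <- n == 1L || in_group_all[a]
    behaviours <- select_behaviours(ag$informed[a], in_group, p$policy)
    did_wander <- FALSE
    eff <- c(0, 0)
    for (b in behaviours) {
      if (b == "seek_to") {
        v <- tgt$xy - pos[a, ]
        eff <- eff + if (vec_norm(v) < .eps) {
          es[a] * random_unit()
        } else {
          seek_to(pos[a, ], tgt$xy, es[a])
        }
      } else if (b == "wander") {
        did_wander <- TRUE
        if (p$wander_base == "realised") {
          h <- hed[a, ]
        } else {
          if (!state$wandered[a]) state$wander_h[a, ] <- hed[a, ]
          h <- state$wander_h[a, ]
        }
        u <- runif(1)
        if (u < p$turn_probability) {
          if (p$wander_base == "anchored") h <- hed[a, ]
          ang <- runif(1, -p$theta_max, p$theta_max)
          h <- rotate_vec(h, ang)
        }
        if (p$wander_base != "realised") state$wander_h[a, ] <- h
        eff <- eff + es[a] * h
      } else if (b == "keep_in_group") {
        nb <- which(da <= p$group_range)
        if (length(nb) == 0L) nb <- setdiff(seq_len(n), a)
        eff <- eff + if (length(nb) == 0L) {
          c(0, 0)
        } else {
          tryCatch(
            keep_in_group(pos[a, ], pos[nb, , drop = FALSE],
                          hed[nb, , drop = FALSE], es[a]),
            crowd_degenerate_error = function(e) es[a] * random_unit())
        }
      } else if (b == "crowd_repulsion") {
        eff <- eff + crowd_repulsion(pos[a, ],
                                     pos[-a, , drop = FALSE], es[a],
                                     threshold = p$repulsion_threshold)
      }
    }
    state$wandered[a] <- did_wander
    disp[a, ] <- eff
  }

  newpos <- pos + disp
  for (a in seq_len(n)) {
    nd <- vec_norm(disp[a, ])
    if (nd > .eps) hed[a, ] <- disp[a, ] / nd
  }
  if (any(!is.finite(newpos))) {
    stop(sprintf("numerical failure: non-finite position at frame %d",
                 state$frame + 1L))
  }
  ag$x <- newpos[, 1]
  ag$y <- newpos[, 2]
  ag$hx <- hed[, 1]
  ag$hy <- hed[, 2]
  state$agents <- ag
  state$frame <- state$frame + 1L
  state$time <- state$frame * p$dt
  state
}

#' Check whether the group has reached the periphery
#'
#' Under the default `"number_capture"` policy the run ends when the group
#' centroid first comes within `capture_radius` of one of the 16 number
#' cards; that card is the number reached.  Under the `"centroid"` policy
#' the run ends as soon as the centroid's radius reaches the outer circle,
#' and the number reached is the card nearest the crossing point (exact
#' ties break to the lower index).  Per-agent flags mark agents within
#' `arrival_band` of the periphery.
#'
#' @param state A `sim_state`.
#' @param policy Termination policy, `"number_capture"` or `"centroid"`.
#' @return `NULL` while the run continues, otherwise a list with
#'   `number_reached`, `time`, `centroid` and `arrived` (per-agent logical).
#' @export
check_termination <- function(state, policy = state$params$termination) {
  ag <- state$agents
  ctr <- c(mean(ag$x), mean(ag$y))
  num <- state$arena$number_positions
  dd <- (num[, 1] - ctr[1])^2 + (num[, 2] - ctr[2])^2
  reached <- NULL
  if (policy == "number_capture") {
    k <- unname(which.min(dd))
    if (dd[k] <= state$params$capture_radius^2) reached <- k
  } else if (policy == "centroid") {
    if (sqrt(sum(ctr^2)) >= state$arena$outer_radius) {
      reached <- unname(which.min(dd))  # first minimum = lower index on ties
    }
  } else {
    stop("unknown termination policy: ", policy)
  }
  if (is.null(reached)) return(NULL)
  r_ag <- sqrt(ag$x^2 + ag$y^2)
  list(number_reached = reached,
       time = state$time,
       centroid = ctr,
       arrived = r_ag >= state$arena$outer_radius - state$params$arrival_band)
}

#' Run one simulation to termination or timeout
#'
#' @param agents Agent data frame from [initialise_agents()].
#' @param arena A `crowd_arena`.
#' @param params Engine parameters from [default_params()].
#' @param max_time Wall-clock cap of the simulated run in seconds (default
#'   300); a run that has not reached the periphery by then is returned as
#'   a timeout, never an error.
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (the
#'   [sim_step()] reference loop); both consume the RNG identically.
#' @param log_every Log agent positions every this many frames (0 = no
#'   trajectory log).  Frame 0 and the crossing frame are always included
#'   when logging is on.
#' @return An object of class `run_result`: a list with `target`,
#'   `number_reached` (`NA` on timeout), `accurate`, `plus1` (reached
#'   within one number of the target), `time` (periphery arrival time, s;
#'   `NA` on timeout), `crossing_time` (first centroid crossing of the
#'   outer circle, s), `terminated`, `frames`, `arrived` (per-agent
#'   logical), `arrived_fraction`, `informed`, `n_agents`, and
#'   `trajectory` (`NULL` unless logging).
#' @export
run_simulation <- function(agents, arena, params = default_params(),
                           max_time = 300, engine = c("cpp", "r"),
                           log_every = 0) {
  engine <- match.arg(engine)
  if (max_time <= 0) stop("max_time must be positive")
  p <- params
  tgt <- run_target_xy(agents, arena)
  max_frames <- as.integer(ceiling(max_time * p$frame_rate))

  if (engine == "cpp") {
    out <- crowd_run_cpp(
      cbind(agents$x, agents$y), cbind(agents$hx, agents$hy),
      speed_to_es(agents$speed, p$unit_scale, p$frame_rate),
      agents$informed, tgt$xy, unname(arena$number_positions),
      arena$outer_radius, p$arms_length, p$group_range,
      p$repulsion_threshold, p$theta_max, p$turn_probability, p$dt,
      p$arrival_band, max_frames, as.integer(log_every),
      as.integer(p$policy == "blend"),
      match(p$wander_base, c("realised", "persistent", "anchored")) - 1L,
      as.integer(identical(p$group_status, "component")),
      as.integer(identical(p$termination, "number_capture")),
      p$capture_radius)
    traj <- NULL
    if (log_every > 0 && !is.null(out$trajectory)) {
      n <- nrow(agents)
      lp <- out$trajectory$positions  # n_logs x 2n, row = (x1,y1,x2,y2,...)
      traj <- list(frames = out$trajectory$frames,
                   positions = aperm(array(t(lp), dim = c(2, n, nrow(lp))),
                                     c(3, 2, 1)))  # [log, agent, coord]
    }
    res <- list(terminated = out$terminated,
                frames = out$frames,
                time = out$time,
                crossing_time = out$crossing_time,
                number_reached = if (out$terminated) out$number_reached else NA_integer_,
                arrived = out$arrived,
                trajectory = traj)
  } else {
    state <- new_sim_state(agents, arena, p)
    traj_frames <- integer(0)
    traj_list <- list()
    log_positions <- function(st) {
      traj_frames[[length(traj_frames) + 1L]] <<- st$frame
      traj_list[[length(traj_list) + 1L]] <<- cbind(st$agents$x, st$agents$y)
    }
    if (log_every > 0) log_positions(state)
    rec <- NULL
    while (state$frame < max_frames) {
      state <- sim_step(state)
      if (log_every > 0 && state$frame %% log_every == 0) log_positions(state)
      if (is.na(state$crossing_time)) {
        ctr <- c(mean(state$agents$x), mean(state$agents$y))
        if (sqrt(sum(ctr^2)) >= arena$outer_radius) {
          state$crossing_time <- state$time
        }
      }
      rec <- check_termination(state)
      if (!is.null(rec)) {
        if (log_every > 0 && state$frame %% log_every != 0) log_positions(state)
        break
      }
    }
    traj <- NULL
    if (log_every > 0) {
      n <- nrow(agents)
      pos_arr <- array(NA_real_, dim = c(length(traj_list), n, 2))
      for (k in seq_along(traj_list)) pos_arr[k, , ] <- traj_list[[k]]
      traj <- list(frames = traj_frames, positions = pos_arr)
    }
    ag <- state$agents
    r_ag <- sqrt(ag$x^2 + ag$y^2)
    res <- list(terminated = !is.null(rec),
                frames = state$frame,
                time = if (is.null(rec)) NA_real_ else rec$time,
                crossing_time = state$crossing_time,
                number_reached = if (is.null(rec)) NA_integer_ else rec$number_reached,
                arrived = r_ag >= arena$outer_radius - p$arrival_band,
                trajectory = traj)
  }

  dev <- number_deviation(res$number_reached, tgt$target)
  structure(list(
    n_agents = nrow(agents),
    target = tgt$target,
    target_xy = tgt$xy,
    number_reached = res$number_reached,
    accurate = isTRUE(dev == 0),
    plus1 = isTRUE(dev <= 1),
    time = res$time,
    crossing_time = res$crossing_time,
    terminated = res$terminated,
    frames = res$frames,
    arrived = res$arrived,
    arrived_fraction = mean(res$arrived),
    informed = agents$informed,
    trajectory = res$trajectory,
    params = p,
    max_time = max_time), class = "run_result")
}

#' Circular deviation between two periphery numbers
#'
#' @param a,b Number indices 1..16 (either may be `NA`).
#' @param n_numbers Number of periphery positions (default 16).
#' @return The shorter circular index distance, or `NA`.
#' @export
number_deviation <- function(a, b, n_numbers = 16) {
  if (is.na(a) || is.na(b)) return(NA_integer_)
  d <- abs(a - b) %% n_numbers
  as.integer(min(d, n_numbers - d))
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>\n")
  cat(sprintf("  agents: %d (informed: %d)\n", x$n_agents, sum(x$informed)))
  if (x$terminated) {
    cat(sprintf("  reached number %d (target %s) at t = %.2f s\n",
                x$number_reached,
                ifelse(is.na(x$target), "none", x$target), x$time))
  } else {
    cat(sprintf("  timeout after %.1f s without reaching the periphery\n",
                x$frames * x$params$dt))
  }
  cat(sprintf("  agents within arrival band: %.0f%%\n",
              100 * x$arrived_fraction))
  invisible(x)
}
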