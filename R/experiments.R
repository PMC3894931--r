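# Batch experiment runners.
#
# Every single run is reproducible in isolation: its seed is derived from
# the batch base seed together with the treatment id, target, replicate and
# speed, so re-running one (treatment, target, replicate) cell reproduces
# that run bit-for-bit without re-running the batch.

#' Derive a per-run seed from a base seed and integer labels
#'
#' Deterministic integer mixing (31-multiplier polynomial hash modulo
#' 2^31 - 1), so the result is always a valid 32-bit seed.
#'
#' @param base_seed Integer base seed.
#' @param ... Further integer labels (treatment, target, replicate, ...).
#' @return A single integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(base_seed, ...) {
  xs <- c(base_seed, ...)
  h <- 0
  for (x in xs) {
    h <- (h * 31 + (round(as.numeric(x)) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

#' The four small-group informed-position treatments
#'
#' Start letters of the two informed agents per treatment: 1 = J & E (one
#' core, one peripheral), 2 = C & D (adjacent peripheral pair), 3 = B & F
#' (opposite peripheral pair), 4 = I & J (both core).
#'
#' @return A data frame with columns `treatment`, `letters` (list column)
#'   and `description`.
#' @export
small_group_treatments <- function() {
  data.frame(
    treatment = 1:4,
    letters = I(list(c("J", "E"), c("C", "D"), c("B", "F"), c("I", "J"))),
    description = c("Core and periphery", "Close periphery (adjacent pair)",
                    "Far periphery (opposite pair)", "Two cores"))
}

run_result_row <- function(res, seed) {
  data.frame(seed = seed,
             target = res$target,
             number_reached = if (is.na(res$number_reached)) NA_integer_ else res$number_reached,
             time = res$time,
             crossing_time = res$crossing_time,
             accurate = res$accurate,
             plus1 = res$plus1,
             timeout = !res$terminated,
             arrived_fraction = res$arrived_fraction)
}

#' Run one small-group treatment over targets and replicates
#'
#' @param treatment_id Treatment index 1-4 (see [small_group_treatments()]),
#'   used for labelling and seed derivation.
#' @param informed_letters Two start letters; defaults to the treatment's
#'   letters.
#' @param targets Periphery numbers to simulate (default 1:16).
#' @param replicates_per_target Replicates per target.
#' @param speed Base walking speed in m/s (default 0.4).
#' @param base_seed Batch base seed.
#' @param params Engine parameters.
#' @param max_time Per-run timeout in seconds (default 300).
#' @param engine `"cpp"` or `"r"`.
#' @return A batch data frame, one row per run, with columns `treatment`,
#'   `target`, `replicate`, `seed`, `speed`, `number_reached`, `time`,
#'   `crossing_time`, `accurate`, `plus1`, `timeout`, `arrived_fraction`.
#' @export
run_small_group_batch <- function(treatment_id, informed_letters = NULL,
                                  targets = 1:16, replicates_per_target = 100,
                                  speed = 0.4, base_seed = 1,
                                  params = default_params(), max_time = 300,
                                  engine = "cpp") {
  if (is.null(informed_letters)) {
    informed_letters <- small_group_treatments()$letters[[treatment_id]]
  }
  arena <- build_small_arena()
  rows <- vector("list", length(targets) * replicates_per_target)
  k <- 0L
  for (target in targets) {
    for (rep in seq_len(replicates_per_target)) {
      seed <- derive_seed(base_seed, treatment_id, target, rep,
                          round(speed * 1000))
      set.seed(seed)
      tr <- treatment("small", informed = informed_letters, target = target,
                      speed = speed)
      agents <- initialise_agents(arena, tr)
      res <- run_simulation(agents, arena, params, max_time, engine)
      row <- run_result_row(res, seed)
      row$treatment <- treatment_id
      row$replicate <- rep
      row$speed <- speed
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  batch <- do.call(rbind, rows)
  batch[c("treatment", "target", "replicate", "seed", "speed",
          "number_reached", "time", "crossing_time", "accurate", "plus1",
          "timeout", "arrived_fraction")]
}

#' Run the full small-group suite (four treatments x 16 targets)
#'
#' @inheritParams run_small_group_batch
#' @param treatments Which treatments to run (default 1:4).
#' @return A named list `treatment_1` .. `treatment_4` of batch data frames.
#' @export
run_small_group_suite <- function(replicates_per_target = 100, speed = 0.4,
                                  base_seed = 1, treatments = 1:4,
                                  targets = 1:16, params = default_params(),
                                  max_time = 300, engine = "cpp") {
  out <- lapply(treatments, function(t_id) {
    run_small_group_batch(t_id, targets = targets,
                          replicates_per_target = replicates_per_target,
                          speed = speed, base_seed = base_seed,
                          params = params, max_time = max_time,
                          engine = engine)
  })
  names(out) <- paste0("treatment_", treatments)
  out
}

#' Walking-speed sweep of one treatment
#'
#' Repeats one small-group treatment at each speed in the sweep; the default
#' speeds are the six used for the speed-accuracy trade-off.
#'
#' @inheritParams run_small_group_batch
#' @param speeds Speeds in m/s (default `c(0.3, 0.4, 0.55, 0.8, 1.0, 1.25)`).
#' @return A named list (one batch per speed, names are the speeds).
#' @export
run_speed_sweep <- function(speeds = c(0.3, 0.4, 0.55, 0.8, 1.0, 1.25),
                            treatment_id = 1, replicates_per_target = 100,
                            base_seed = 1, targets = 1:16,
                            params = default_params(), max_time = 300,
                            engine = "cpp") {
  if (length(speeds) == 0L || any(speeds <= 0)) {
    stop("speeds must be a non-empty vector of positive values")
  }
  out <- lapply(speeds, function(s) {
    run_small_group_batch(treatment_id,
                          targets = targets,
                          replicates_per_target = replicates_per_target,
                          speed = s, base_seed = base_seed, params = params,
                          max_time = max_time, engine = engine)
  })
  names(out) <- as.character(speeds)
  out
}

#' Run one large-group cell (percentage x speed)
#'
#' Each replicate draws its own target number uniformly from 1-16, places
#' `n_agents` agents in the 12 m inner circle with the informed subset
#' sampled at the given percentage, and runs to the centroid-crossing
#' termination.
#'
#' @param informed_percentage Fraction of informed agents, e.g. 0.15.
#' @param speed Base walking speed in m/s.
#' @param replicates Number of replicates.
#' @param n_agents Group size (default 200).
#' @param outer_diameter_m Outer-circle diameter in metres (default 30).
#' @param base_seed Batch base seed.
#' @param params Engine parameters.
#' @param max_time Per-run timeout in seconds (default 300).
#' @param engine `"cpp"` or `"r"`.
#' @param log_every Trajectory decimation in frames (0 = none); when
#'   positive the individual `run_result`s are kept in the `"runs"`
#'   attribute for leadership analysis.
#' @return A batch data frame (one row per replicate) with columns
#'   `percentage`, `n_informed`, `speed`, `replicate`, `seed`, `target`,
#'   `number_reached`, `time`, `crossing_time`, `accurate`, `plus1`,
#'   `timeout`, `arrived_fraction`.
#' @export
run_large_group_batch <- function(informed_percentage, speed,
                                  replicates = 100, n_agents = 200,
                                  outer_diameter_m = 30, base_seed = 1,
                                  params = default_params(), max_time = 300,
                                  engine = "cpp", log_every = 0) {
  arena <- build_large_arena(outer_diameter_m)
  rows <- vector("list", replicates)
  runs <- if (log_every > 0) vector("list", replicates) else NULL
  for (rep in seq_len(replicates)) {
    seed <- derive_seed(base_seed, round(informed_percentage * 1000),
                        round(speed * 1000), rep)
    set.seed(seed)
    target <- sample.int(16, 1)
    tr <- treatment("large", informed_percentage = informed_percentage,
                    target = target, speed = speed, n_agents = n_agents)
    agents <- initialise_agents(arena, tr)
    res <- run_simulation(agents, arena, params, max_time, engine,
                          log_every = log_every)
    row <- run_result_row(res, seed)
    row$percentage <- informed_percentage
    row$n_informed <- sum(agents$informed)
    row$speed <- speed
    row$replicate <- rep
    rows[[rep]] <- row
    if (log_every > 0) runs[[rep]] <- res
  }
  batch <- do.call(rbind, rows)
  batch <- batch[c("percentage", "n_informed", "speed", "replicate", "seed",
                   "target", "number_reached", "time", "crossing_time",
                   "accurate", "plus1", "timeout", "arrived_fraction")]
  if (log_every > 0) attr(batch, "runs") <- runs
  batch
}

#' Informed-percentage x walking-speed grid for the large group
#'
#' @inheritParams run_large_group_batch
#' @param percentages Informed fractions (default `c(0.05, 0.10, 0.15)`).
#' @param speeds Speeds in m/s (default `c(0.4, 0.8, 1.2)`).
#' @return A named list of batch data frames, one per grid cell, named
#'   `p<percent>_s<speed>`.
#' @export
run_large_group_grid <- function(percentages = c(0.05, 0.10, 0.15),
                                 speeds = c(0.4, 0.8, 1.2),
                                 replicates = 100, n_agents = 200,
                                 outer_diameter_m = 30, base_seed = 1,
                                 params = default_params(), max_time = 300,
                                 engine = "cpp") {
  out <- list()
  for (p in percentages) {
    for (s in speeds) {
      key <- sprintf("p%g_s%g", 100 * p, s)
      out[[key]] <- run_large_group_batch(
        p, s, replicates = replicates, n_agents = n_agents,
        outer_diameter_m = outer_diameter_m, base_seed = base_seed,
        params = params, max_time = max_time, engine = engine)
    }
  }
  out
}

#' Informed agents' position along the direction of motion
#'
#' For each logged frame, projects the informed agents' offsets from the
#' group centroid onto the unit vector pointing from the centroid to the
#' target, and averages over the informed agents.  A rising series means
#' the informed individuals drift to the front edge of the group in the
#' target direction -- leadership emerging without any leadership rule.
#'
#' @param run A `run_result` produced with `log_every > 0`.
#' @param arena The `crowd_arena` the run used.
#' @return A data frame with columns `time` (s) and `projection` (px).
#' @export
leader_position_track <- function(run, arena) {
  if (is.null(run$trajectory)) {
    stop("run has no trajectory log; rerun with log_every > 0")
  }
  pos <- run$trajectory$positions   # [log, agent, coord]
  frames <- run$trajectory$frames
  informed <- run$informed
  tgt <- run$target_xy
  nlog <- dim(pos)[1]
  proj <- numeric(nlog)
  for (k in seq_len(nlog)) {
    P <- pos[k, , , drop = TRUE]
    ctr <- colMeans(P)
    u <- tgt - ctr
    nu <- sqrt(sum(u^2))
    if (nu < .eps) {
      proj[k] <- 0
      next
    }
    u <- u / nu
    off <- sweep(P[informed, , drop = FALSE], 2, ctr)
    proj[k] <- mean(off %*% u)
  }
  data.frame(time = frames * run$params$dt, projection = proj)
}

#' Linear trend of a leadership track
#'
#' @param track Output of [leader_position_track()].
#' @return Slope (px/s) of the least-squares line of projection on time.
#' @export
leadership_trend <- function(track) {
  if (nrow(track) < 2L) return(NA_real_)
  unname(coef(lm(projection ~ time, data = track))[2])
}
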