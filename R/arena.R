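# Arena geometry and initial agent placement.
#
# Both experimental arenas are circles carrying 16 equally spaced numbered
# targets on the outer circle.  The small arena (10 m outer diameter) has
# ten start letters: A-H equally spaced on a 2 m-diameter inner circle and
# I, J at the centre.  The large arena places 200 agents at random inside a
# 12 m-diameter inner circle.  1 pixel = 0.05 m throughout, so the small
# outer radius is 100 px.  Number 1 sits at the top (90 degrees) and numbers
# increase clockwise; results are rotation-invariant, so this choice only
# fixes labelling.

circle_points <- function(n, radius, start_deg = 90, clockwise = TRUE) {
  step <- 2 * pi / n
  ang <- (start_deg * pi / 180) + (if (clockwise) -1 else 1) * step * (seq_len(n) - 1)
  cbind(x = radius * cos(ang), y = radius * sin(ang))
}

new_arena <- function(kind, outer_radius, inner_radius, letter_positions = NULL,
                      unit_scale = 0.05) {
  numbers <- circle_points(16, outer_radius)
  rownames(numbers) <- as.character(1:16)
  structure(list(kind = kind,
                 outer_radius = outer_radius,
                 inner_radius = inner_radius,
                 number_positions = numbers,
                 letter_positions = letter_positions,
                 unit_scale = unit_scale),
            class = "crowd_arena")
}

#' @export
print.crowd_arena <- function(x, ...) {
  cat(sprintf("<crowd_arena: %s>\n", x$kind))
  cat(sprintf("  outer radius: %g px (%g m)\n", x$outer_radius,
              x$outer_radius * x$unit_scale))
  cat(sprintf("  inner radius: %g px (%g m)\n", x$inner_radius,
              x$inner_radius * x$unit_scale))
  cat(sprintf("  periphery numbers: %d\n", nrow(x$number_positions)))
  if (!is.null(x$letter_positions)) {
    cat(sprintf("  start letters: %s\n",
                paste(rownames(x$letter_positions), collapse = " ")))
  }
  invisible(x)
}

#' Build the small-group arena
#'
#' A 10 m-diameter circle (radius 100 px) with numbers 1-16 equally spaced
#' on its perimeter; start letters A-H equally spaced on the 2 m-diameter
#' inner circle (radius 20 px) and I, J at the centre.  I and J are offset
#' to (-7, 0) and (+7, 0) px so that two agents can occupy "the centre"
#' exactly an arm's length (0.7 m) apart.
#'
#' @return A `crowd_arena` object.
#' @examples
#' a <- build_small_arena()
#' a$number_positions["1", ]  # (0, 100): number 1 at the top
#' @export
build_small_arena <- function() {
  letters_ah <- circle_points(8, 20)
  core <- rbind(c(-7, 0), c(7, 0))
  colnames(core) <- c("x", "y")
  letter_positions <- rbind(letters_ah, core)
  rownames(letter_positions) <- LETTERS[1:10]
  new_arena("small", outer_radius = 100, inner_radius = 20,
            letter_positions = letter_positions)
}

#' Build the large-group arena
#'
#' The inner circle, inside which all 200 agents start, has the fixed 12 m
#' diameter (radius 120 px).  The outer circle bearing the 16 numbers is
#' configurable; it is not pinned down by the experiment description, and
#' 30 m is used as a realistic default.
#'
#' @param outer_diameter_m Outer-circle diameter in metres; must exceed the
#'   12 m inner diameter.  Default 30.
#' @return A `crowd_arena` object.
#' @export
build_large_arena <- function(outer_diameter_m = 30) {
  inner_radius <- 120
  outer_radius <- outer_diameter_m / 2 / 0.05
  if (outer_radius <= inner_radius) {
    stop("outer diameter must exceed the 12 m inner circle")
  }
  new_arena("large", outer_radius = outer_radius, inner_radius = inner_radius)
}

#' Describe one experimental treatment
#'
#' A treatment fixes everything about a run except the seed: the arena
#' class, which agents are informed (named start letters in the small
#' arena, a fraction of the group in the large arena), the target number,
#' the base walking speed, and placement parameters.
#'
#' @param arena `"small"` or `"large"`.
#' @param informed Character vector of start letters carrying informed
#'   agents (small arena), e.g. `c("J", "E")`.
#' @param informed_percentage Fraction of informed agents in (0, 1\]
#'   (large arena), e.g. 0.15.
#' @param target Periphery number index 1-16, or `NULL` to let the runner
#'   assign one.
#' @param speed Base walking speed in m/s (default 0.4); each agent's own
#'   speed is jittered once at initialisation by a factor drawn uniformly
#'   from `[1 - speed_jitter, 1 + speed_jitter]`.
#' @param n_agents Group size; defaults to 10 (small) or 200 (large).
#' @param speed_jitter Half-width of the relative speed jitter (default
#'   0.10, i.e. speed +/- 10\%).
#' @param min_separation Minimum centre-to-centre distance (px) enforced by
#'   rejection when placing large-arena agents (default 7 px = 0.35 m,
#'   about a body width).
#' @param max_attempts Rejection-sampling attempts per agent before a
#'   placement error (default 10000).
#' @return An object of class `crowd_treatment`.
#' @export
treatment <- function(arena = c("small", "large"), informed = NULL,
                      informed_percentage = NULL, target = NULL,
                      speed = 0.4, n_agents = NULL, speed_jitter = 0.10,
                      min_separation = 7, max_attempts = 10000) {
  arena <- match.arg(arena)
  if (arena == "small") {
    if (is.null(n_agents)) n_agents <- 10L
    if (is.null(informed) || !all(informed %in% LETTERS[1:10])) {
      stop("small-arena treatments need informed letters drawn from A..J")
    }
  } else {
    if (is.null(n_agents)) n_agents <- 200L
    if (is.null(informed_percentage) || informed_percentage <= 0 ||
        informed_percentage > 1) {
      stop("large-arena treatments need informed_percentage in (0, 1]")
    }
  }
  if (!is.null(target) && !(target %in% 1:16)) {
    stop("target must be a periphery number index 1..16")
  }
  if (speed <= 0) stop("speed must be positive")
  structure(list(arena = arena, informed = informed,
                 informed_percentage = informed_percentage, target = target,
                 speed = speed, n_agents = as.integer(n_agents),
                 speed_jitter = speed_jitter,
                 min_separation = min_separation,
                 max_attempts = as.integer(max_attempts)),
            class = "crowd_treatment")
}

# Rejection-sample n points uniformly in a disc of the given radius with a
# minimum pairwise separation.
place_in_disc <- function(n, radius, min_separation, max_attempts) {
  xs <- numeric(n)
  ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      r <- radius * sqrt(runif(1))
      ang <- runif(1, 0, 2 * pi)
      px <- r * cos(ang)
      py <- r * sin(ang)
      if (i == 1L) {
        ok <- TRUE
      } else {
        prev <- seq_len(i - 1L)
        ok <- all((xs[prev] - px)^2 + (ys[prev] - py)^2 >= min_separation^2)
      }
      if (ok) {
        xs[i] <- px
        ys[i] <- py
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "could not place agent %d after %d attempts (separation %g px too large for %d agents)",
        i, max_attempts, min_separation, n))
    }
  }
  cbind(x = xs, y = ys)
}

#' Initialise the agents of one run
#'
#' Small arena: the ten agents stand exactly on letters A-J, informed flags
#' on the treatment's letters.  Large arena: `n_agents` are placed uniformly
#' at random in the inner circle (rejection sampling keeps them at least
#' `min_separation` apart) and the informed subset is sampled uniformly at
#' the treatment's percentage.  Every agent faces a uniformly chosen
#' periphery number and draws its personal walking speed once, as the base
#' speed times a factor uniform in `[1 - jitter, 1 + jitter]`.  All draws
#' come from the session RNG, so placement is reproducible under
#' `set.seed()`.
#'
#' @param arena A `crowd_arena` from [build_small_arena()] or
#'   [build_large_arena()].
#' @param tr A [treatment()] consistent with the arena.
#' @return A data frame with one row per agent: `id`, `letter` (small arena
#'   only, else `NA`), `x`, `y` (px), `hx`, `hy` (unit heading),
#'   `speed` (m/s), `informed` (logical) and `target` (number index for
#'   informed agents, `NA` otherwise).
#' @export
initialise_agents <- function(arena, tr) {
  if (!inherits(arena, "crowd_arena")) stop("arena must be a crowd_arena")
  if (!inherits(tr, "crowd_treatment")) stop("tr must be a crowd_treatment")
  if (arena$kind != tr$arena) stop("treatment and arena kinds disagree")

  if (arena$kind == "small") {
    pos <- arena$letter_positions
    n <- nrow(pos)
    letter <- rownames(pos)
    informed <- letter %in% tr$informed
  } else {
    n <- tr$n_agents
    pos <- place_in_disc(n, arena$inner_radius, tr$min_separation,
                         tr$max_attempts)
    letter <- rep(NA_character_, n)
    n_informed <- round(tr$informed_percentage * n)
    informed <- rep(FALSE, n)
    informed[sample.int(n, n_informed)] <- TRUE
  }

  facing <- sample.int(16, n, replace = TRUE)
  jitter <- runif(n, 1 - tr$speed_jitter, 1 + tr$speed_jitter)

  hx <- numeric(n)
  hy <- numeric(n)
  for (i in seq_len(n)) {
    v <- arena$number_positions[facing[i], ] - pos[i, ]
    u <- v / sqrt(sum(v^2))
    hx[i] <- u[1]
    hy[i] <- u[2]
  }

  if (is.null(tr$target) && any(informed)) {
    stop("treatment has informed agents but no target; set treatment(target=)")
  }

  data.frame(id = seq_len(n), letter = letter,
             x = unname(pos[, 1]), y = unname(pos[, 2]),
             hx = hx, hy = hy,
             speed = tr$speed * jitter,
             informed = informed,
             target = ifelse(informed, tr$target %||% NA_integer_,
                             NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
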