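# Shared fixtures: hand-built agents and random configurations, all
# generated in code at test time.

# A single agent standing at the arena centre with an exact base speed
# (no jitter), informed and aimed at `target`.
lone_agent <- function(target = 1L, speed = 0.4, heading = c(0, 1)) {
  data.frame(id = 1L, letter = NA_character_, x = 0, y = 0,
             hx = heading[1], hy = heading[2], speed = speed,
             informed = TRUE, target = as.integer(target))
}

# n agents scattered uniformly in a disc, k of them informed on `target`.
random_agents <- function(n, k = 1L, target = 1L, radius = 50, speed = 0.4) {
  r <- radius * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  h_ang <- runif(n, 0, 2 * pi)
  informed <- rep(FALSE, n)
  informed[seq_len(k)] <- TRUE
  data.frame(id = seq_len(n), letter = NA_character_,
             x = r * cos(ang), y = r * sin(ang),
             hx = cos(h_ang), hy = sin(h_ang),
             speed = speed * runif(n, 0.9, 1.1),
             informed = informed,
             target = ifelse(informed, as.integer(target), NA_integer_))
}

# independent rotation oracle used by the isotropy property tests
rot2 <- function(v, a) {
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}
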