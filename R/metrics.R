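# Summary statistics over batches of runs.
#
# Accuracy is the fraction of runs whose first-reached periphery number
# equals the assigned target; the "+1 deviation" variant also accepts
# either adjacent number (indices +/-1 mod 16).  Timeout runs count as
# inaccurate and are excluded from arrival-time statistics; their count is
# reported.

#' Summarise a batch of runs
#'
#' @param batch Batch data frame from one of the `run_*` functions (needs at
#'   least `target`, `number_reached`, `time`, `accurate`, `plus1`,
#'   `timeout`; uses `arrived_fraction` when present).
#' @return An object of class `batch_summary`: a list with `n_runs`,
#'   `n_timeout`, `accuracy_exact`, `accuracy_plus1`, `mean_time`,
#'   `median_time`, `sd_time` (periphery arrival, non-timeout runs, s),
#'   `mean_time_target` (accurate runs only), `fraction_within_60s`,
#'   `group_arrival_fraction` and `per_target` (a data frame of per-target
#'   accuracy and mean time).
#' @export
summarise_batch <- function(batch) {
  if (nrow(batch) == 0L) stop("batch is empty")
  ok <- !batch$timeout
  times <- batch$time[ok]
  per_target <- do.call(rbind, lapply(split(batch, batch$target), function(b) {
    data.frame(target = b$target[1],
               n = nrow(b),
               accuracy_exact = mean(b$accurate),
               accuracy_plus1 = mean(b$plus1),
               mean_time = if (any(!b$timeout)) mean(b$time[!b$timeout]) else NA_real_)
  }))
  rownames(per_target) <- NULL
  structure(list(
    n_runs = nrow(batch),
    n_timeout = sum(batch$timeout),
    accuracy_exact = mean(batch$accurate),
    accuracy_plus1 = mean(batch$plus1),
    mean_time = if (length(times)) mean(times) else NA_real_,
    median_time = if (length(times)) median(times) else NA_real_,
    sd_time = if (length(times) > 1L) sd(times) else NA_real_,
    mean_time_target = if (any(batch$accurate & ok))
      mean(batch$time[batch$accurate & ok]) else NA_real_,
    fraction_within_60s = mean(ok & batch$time < 60),
    group_arrival_fraction = if ("arrived_fraction" %in% names(batch))
      mean(batch$arrived_fraction) else NA_real_,
    per_target = per_target), class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat("<batch_summary>\n")
  cat(sprintf("  runs: %d (timeouts: %d)\n", x$n_runs, x$n_timeout))
  cat(sprintf("  accuracy: %.1f%% exact, %.1f%% within +/-1 number\n",
              100 * x$accuracy_exact, 100 * x$accuracy_plus1))
  if (!is.na(x$mean_time)) {
    cat(sprintf("  periphery arrival time: mean %.1f s, median %.1f s, sd %.1f s\n",
                x$mean_time, x$median_time, x$sd_time))
  }
  if (!is.na(x$mean_time_target)) {
    cat(sprintf("  arrival time of accurate runs: mean %.1f s\n",
                x$mean_time_target))
  }
  cat(sprintf("  runs under 60 s: %.2f%%\n", 100 * x$fraction_within_60s))
  if (!is.na(x$group_arrival_fraction)) {
    cat(sprintf("  mean fraction of agents arrived: %.1f%%\n",
                100 * x$group_arrival_fraction))
  }
  invisible(x)
}

#' Histogram of periphery arrival times
#'
#' Bins the arrival times of the non-timeout runs at a fixed width
#' (default 0.1 s); the counts sum to the number of non-timeout runs.
#'
#' @param batch Batch data frame.
#' @param bin_width Bin width in seconds (default 0.1).
#' @return A data frame with `bin_start` and `count` (empty bins omitted).
#' @export
arrival_histogram <- function(batch, bin_width = 0.1) {
  times <- batch$time[!batch$timeout]
  if (length(times) == 0L) {
    return(data.frame(bin_start = numeric(0), count = integer(0)))
  }
  bins <- floor(times / bin_width) * bin_width
  tab <- table(bins)
  data.frame(bin_start = as.numeric(names(tab)),
             count = as.integer(tab))
}

#' Speed-accuracy trade-off table
#'
#' @param sweep Named list of batches from [run_speed_sweep()] (names are
#'   speeds); at least two speeds.
#' @return A data frame with one row per speed: `speed`, `mean_time`,
#'   `accuracy_exact`, `accuracy_plus1`, `fraction_within_60s`.
#' @export
tradeoff_curve <- function(sweep) {
  if (length(sweep) < 2L) stop("need at least two speeds")
  rows <- lapply(names(sweep), function(s) {
    sm <- summarise_batch(sweep[[s]])
    data.frame(speed = as.numeric(s),
               mean_time = sm$mean_time,
               accuracy_exact = sm$accuracy_exact,
               accuracy_plus1 = sm$accuracy_plus1,
               fraction_within_60s = sm$fraction_within_60s)
  })
  out <- do.call(rbind, rows)
  out[order(out$speed), , drop = FALSE]
}

#' Summary table for a large-group grid
#'
#' @param grid Named list of batches from [run_large_group_grid()].
#' @return A data frame with one row per cell: `percentage`, `n_informed`,
#'   `speed`, `n_runs`, `accuracy_exact`, `accuracy_plus1`, `mean_time`,
#'   `group_arrival_fraction`.
#' @export
grid_summary <- function(grid) {
  rows <- lapply(grid, function(b) {
    sm <- summarise_batch(b)
    data.frame(percentage = b$percentage[1],
               n_informed = b$n_informed[1],
               speed = b$speed[1],
               n_runs = sm$n_runs,
               accuracy_exact = sm$accuracy_exact,
               accuracy_plus1 = sm$accuracy_plus1,
               mean_time = sm$mean_time,
               group_arrival_fraction = sm$group_arrival_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
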