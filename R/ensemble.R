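# Ensemble runs over independent seeds, with per-seed gdat persistence,
# mean/SD/SEM summaries and peak statistics for oscillatory fixtures.

#' Run an ensemble of independent seeded simulations
#'
#' @param fixture fixture name (see [fixture_model()]) or a function
#'   `function(seed) -> mc_model_bundle`.
#' @param seeds integer vector of RNG seeds.
#' @param iterations iterations per run.
#' @param out_dir directory for per-seed gdat files (`NULL` to skip
#'   persistence).
#' @param peaks optional list `list(column =, window =, min_prominence =)`
#'   enabling low-pass peak statistics per run.
#' @param ... passed to [fixture_model()].
#' @return an `mc_ensemble_summary`: list with `time`, per-observable
#'   `mean`, `sd`, `sem` matrices, `trajectories` (list of count matrices)
#'   and optionally `peak_times` (list per seed) with `peak_mean`/`peak_sd`
#'   of the first-peak time.
#' @export
run_ensemble <- function(fixture, seeds, iterations, out_dir = NULL,
                         peaks = NULL, ...) {
  build <- if (is.function(fixture)) fixture
           else function(s) fixture_model(fixture, seed = s, ...)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  trajs <- vector("list", length(seeds))
  peak_times <- if (is.null(peaks)) NULL else vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    w <- tryCatch({
      w <- build_world(build(s))
      run_iterations(w, iterations)
      w
    }, error = function(e)
      stop("ensemble run failed for seed ", s, ": ", conditionMessage(e)))
    trajs[[i]] <- w$counts
    if (!is.null(out_dir))
      write_gdat(w$counts, file.path(out_dir, sprintf("seed_%05d.gdat", s)))
    if (!is.null(peaks)) {
      tr <- w$counts[, peaks$column]
      peak_times[[i]] <- lowpass_peak_times(
        tr, w$counts[, "time"], window = peaks$window,
        min_prominence = peaks$min_prominence %||% 0.1)
    }
  }
  tm <- trajs[[1]][, "time"]
  obs <- setdiff(colnames(trajs[[1]]), "time")
  arr <- vapply(trajs, function(m) m[, obs, drop = FALSE],
                matrix(0, length(tm), length(obs)))
  mean_m <- apply(arr, c(1, 2), mean)
  sd_m <- apply(arr, c(1, 2), stats::sd)
  colnames(mean_m) <- colnames(sd_m) <- obs
  out <- list(time = tm, mean = mean_m, sd = sd_m,
              sem = sd_m / sqrt(length(seeds)),
              seeds = seeds, trajectories = trajs)
  if (!is.null(peaks)) {
    first <- vapply(peak_times, function(p)
      if (length(p)) p[1] else NA_real_, 0)
    out$peak_times <- peak_times
    out$peak_mean <- mean(first, na.rm = TRUE)
    out$peak_sd <- stats::sd(first, na.rm = TRUE)
  }
  class(out) <- "mc_ensemble_summary"
  out
}

#' @export
print.mc_ensemble_summary <- function(x, ...) {
  cat("<mc_ensemble_summary>", length(x$seeds), "seeds,",
      length(x$time), "time points")
  if (!is.null(x$peak_mean))
    cat(", first-peak time", signif(x$peak_mean, 4), "+/-",
        signif(x$peak_sd, 3), "s")
  cat("\n")
  invisible(x)
}

#' Advance a hybrid world by one coupled iteration
#'
#' Runs one particle iteration, applies the explicit Euler update of the
#' continuous copy number from the current particle state, and refreshes
#' the pseudo-first-order rate of the coupled rule — the per-iteration
#' coupling cycle of a hybrid simulation.
#'
#' @param world an `mc_world` whose bundle carries a [hybrid_species()].
#' @return list with the updated `world` and the continuous copy number
#'   `value`.
#' @export
clock_hybrid_step <- function(world) {
  if (is.null(world$hybrid)) stop("world has no hybrid species")
  run_iterations(world, 1L)
  list(world = world, value = world$hybrid$value)
}
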