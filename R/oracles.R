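# Independent oracles for validation: deterministic mass-action ODE
# integration over a fully expanded network (deSolve), an exact Gillespie
# direct-method SSA, and low-pass peak extraction for oscillatory traces.

# per-event propensity constants from an expanded network
network_propensities <- function(net, volume, units = "mcell",
                                 area = volume) {
  r <- net$reactions
  c_const <- numeric(nrow(r))
  for (i in seq_len(nrow(r))) {
    k <- internal_rate(r$rate[i], r$context[i], units)
    c_const[i] <- switch(r$context[i],
      unimol = k,
      vol_bimol = k / volume,
      surf_bimol = k / area)
  }
  c_const
}

parse_products <- function(net) {
  lapply(strsplit(net$reactions$products, ",", fixed = TRUE), function(x) {
    x <- x[nzchar(x)]
    as.integer(x)
  })
}

#' Deterministic mass-action ODE oracle over an expanded network
#'
#' Integrates dn/dt for molecule copy numbers with per-event rates
#' c = k/V for bimolecular reactions (c n_A n_B, or c n_A^2 / 2 for identical
#' reactants) and c = k for unimolecular ones, using a stiff-safe integrator.
#'
#' @param net an `mc_network` from [expand_network()].
#' @param y0 named numeric of initial copy numbers (names are canonical
#'   species labels; unnamed species start at 0).
#' @param times output time grid (s).
#' @param volume compartment volume in um^3.
#' @param units unit system of the rates in the model (`"mcell"`/`"bng"`).
#' @param area membrane area in um^2 for surface-surface reactions
#'   (defaults to `volume`).
#' @return matrix: one column `time` plus one column per species label.
#' @export
ode_oracle <- function(net, y0, times, volume, units = "mcell",
                       area = volume) {
  ns <- nrow(net$species)
  r <- net$reactions
  cc <- network_propensities(net, volume, units, area)
  prods <- parse_products(net)
  idx <- stats::setNames(seq_len(ns), net$species$label)
  y <- numeric(ns)
  if (!is.null(names(y0))) {
    miss <- setdiff(names(y0), net$species$label)
    if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
    y[idx[names(y0)]] <- unname(y0)
  } else y[seq_along(y0)] <- y0
  # stoichiometry per reaction
  nr <- nrow(r)
  deriv <- function(t, y, parms) {
    dy <- numeric(ns)
    for (i in seq_len(nr)) {
      a <- r$r1[i]; b <- r$r2[i]
      flux <- if (is.na(b)) cc[i] * y[a]
              else if (a == b) cc[i] * y[a]^2 / 2
              else cc[i] * y[a] * y[b]
      dy[a] <- dy[a] - flux
      if (!is.na(b)) dy[b] <- dy[b] - flux
      for (p in prods[[i]]) dy[p] <- dy[p] + flux
    }
    list(dy)
  }
  out <- deSolve::lsoda(y, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  colnames(out) <- c("time", net$species$label)
  unclass(out)
}

#' Gillespie direct-method SSA oracle over an expanded network
#'
#' Exact stochastic simulation with the same propensity convention as
#' [ode_oracle()] (c n_A n_B for distinct reactants, c n(n-1)/2 for an
#' identical pair). The trajectory is sampled onto `times`.
#'
#' @inheritParams ode_oracle
#' @param seed RNG seed of the SSA stream.
#' @return matrix: `time` column plus one column per species label.
#' @export
ssa_oracle <- function(net, y0, seed, times, volume, units = "mcell",
                       area = volume) {
  ns <- nrow(net$species)
  r <- net$reactions
  cc <- network_propensities(net, volume, units, area)
  prods <- parse_products(net)
  idx <- stats::setNames(seq_len(ns), net$species$label)
  y <- integer(ns)
  if (!is.null(names(y0))) y[idx[names(y0)]] <- as.integer(unname(y0))
  else y[seq_along(y0)] <- as.integer(y0)
  m <- cpp_ssa(ns, as.integer(r$r1),
               as.integer(ifelse(is.na(r$r2), 0L, r$r2)),
               cc, prods, y, as.numeric(times), as.double(seed))
  out <- cbind(time = as.numeric(times), m)
  colnames(out) <- c("time", net$species$label)
  out
}

#' Peak times of an oscillatory trace after zero-phase low-pass smoothing
#'
#' The trace is smoothed with a centered moving-average FIR filter (zero
#' phase) and local maxima with a minimum prominence are extracted; the
#' smoothed peak time is a proxy for the oscillation peak time.
#'
#' @param trace numeric values, uniformly sampled.
#' @param time sample times (same length).
#' @param window filter window in samples (odd; e.g. one fifth of the
#'   expected period).
#' @param min_prominence minimum peak prominence as a fraction of the
#'   smoothed trace range (default 0.1).
#' @return numeric vector of peak times (possibly empty).
#' @export
lowpass_peak_times <- function(trace, time, window,
                               min_prominence = 0.1) {
  n <- length(trace)
  stopifnot(length(time) == n)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= n) stop("trace shorter than filter width")
  # zero-phase moving average with edge padding
  half <- window %/% 2L
  padded <- c(rep(trace[1], half), trace, rep(trace[n], half))
  sm <- as.numeric(stats::filter(padded, rep(1 / window, window),
                                 sides = 2L))
  sm <- sm[(half + 1L):(half + n)]
  rng <- diff(range(sm))
  if (rng <= 0) return(numeric())
  prom_min <- min_prominence * rng
  # local maxima (plateaus resolve to their first sample)
  is_peak <- logical(n)
  for (i in 2:(n - 1)) {
    if (sm[i] > sm[i - 1] && sm[i] >= sm[i + 1]) is_peak[i] <- TRUE
  }
  cand <- which(is_peak)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left and right to the lowest valley before a higher point
    lmin <- sm[i]; j <- i
    while (j > 1 && sm[j] <= sm[i]) { j <- j - 1L; lmin <- min(lmin, sm[j]) }
    rmin <- sm[i]; j <- i
    while (j < n && sm[j] <= sm[i]) { j <- j + 1L; rmin <- min(rmin, sm[j]) }
    prom <- sm[i] - max(lmin, rmin)
    # boundary peaks: prominence vs the single available side
    if (i - half <= 1 || i + half >= n) prom <- 0
    keep[k] <- prom >= prom_min
  }
  time[cand[keep]]
}
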