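#' Indication number
#'
#' Fraction of agents whose local value `W` exceeds the reference
#' threshold `What` (by default the passive-twin ensemble mean). Ties
#' count as not exceeding.
#'
#' @param W per-agent values.
#' @param What threshold.
#' @return fraction in `[0, 1]`.
#' @export
indication_number <- function(W, What) {
  if (length(W) < 1) stop("indication number needs at least one agent")
  mean(W > What)
}

#' Turbulence-avoidance fraction
#'
#' `P(|C|) = N(|C|) / N(|C|_passive)`: the indication number of the
#' active ensemble for absolute vorticity, with the threshold set to the
#' passive-twin ensemble mean, normalized by the passive ensemble's own
#' indication number. Equal ensembles give 1; full avoidance gives 0.
#'
#' @param absC_active,absC_passive per-agent `|C|` values of the two
#'   ensembles at one time.
#' @return the fraction, or `NA` (undefined) when no passive agent
#'   exceeds the threshold.
#' @export
turbulence_fraction <- function(absC_active, absC_passive) {
  What <- mean(absC_passive)
  den <- indication_number(absC_passive, What)
  if (den == 0) return(NA_real_)
  indication_number(absC_active, What) / den
}

#' Baseline of a turbulence-fraction series
#'
#' Robust plateau average that excludes the intermittent spikes of
#' `P(|C|)`: drop the first `burn_in` seconds, compute the maximum `Phat`
#' and minimum `Ptil` of the remainder, and average only samples below
#' `0.9 Ptil + 0.1 Phat`.
#'
#' @param P fraction series.
#' @param time time stamps (s).
#' @param burn_in initial transient to discard (s); default 50.
#' @return the baseline average `P_min`.
#' @export
baseline_fraction <- function(P, time, burn_in = 50) {
  keep <- time > burn_in & is.finite(P)
  if (!any(keep)) stop("series shorter than the burn-in")
  P <- P[keep]
  Phat <- max(P); Ptil <- min(P)
  thr <- 0.9 * Ptil + 0.1 * Phat
  low <- P < thr
  if (!any(low)) {
    warning("no samples below the spike threshold; returning the series minimum")
    return(Ptil)
  }
  mean(P[low])
}

#' Barrier-crossing fraction
#'
#' `P(x) = N_0(x) / N_0(x_passive)`, where `N_0` counts agents still at
#' `x > boundary`. Both ensembles fully right of the barrier give 1; an
#' active ensemble that has fully crossed gives 0.
#'
#' @param x_active,x_passive agent x positions of the paired ensembles.
#' @param boundary barrier position; default 0.
#' @return the fraction, or `NA` when no passive agent is right of the
#'   barrier.
#' @export
crossing_fraction <- function(x_active, x_passive, boundary = 0) {
  den <- mean(x_passive > boundary)
  if (den == 0) return(NA_real_)
  mean(x_active > boundary) / den
}

#' Velocity-flow correlation
#'
#' Mean of the componentwise Pearson correlations between agent
#' velocities and the flow sampled at the agents:
#' `Corr = (cor(vx, Ux) + cor(vy, Uy)) / 2`.
#'
#' @param vx,vy agent velocity components.
#' @param Ux,Uy sampled flow components.
#' @return correlation in `[-1, 1]`, or `NA` if any component has zero
#'   variance.
#' @export
velocity_correlation <- function(vx, vy, Ux, Uy) {
  if (length(vx) < 3) stop("correlation needs at least 3 agents")
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0 ||
      stats::sd(Ux) == 0 || stats::sd(Uy) == 0) return(NA_real_)
  (stats::cor(vx, Ux) + stats::cor(vy, Uy)) / 2
}

#' Hexatic (bond-orientational) order parameter
#'
#' For each agent, the modulus of the average of `exp(i 6 delta)` over
#' its `n` nearest neighbours, where `delta` is the full-quadrant angle
#' of the separation vector; then the ensemble mean. A perfect hexagonal
#' lattice gives 1 for interior agents; `n = 6` probes crystalline order
#' and `n = 12` resolves filamentation. Exactly coincident agents are
#' excluded from each other's neighbour sets; ties in distance break by
#' agent index.
#'
#' @param x,y agent positions.
#' @param n number of nearest neighbours.
#' @param per_agent return the per-agent moduli instead of their mean
#'   (boundary agents of a finite cluster dilute the ensemble value;
#'   interior agents of a perfect lattice score exactly 1).
#' @return ensemble-mean order in `[0, 1]`, or the per-agent vector.
#' @export
hex_order <- function(x, y, n = 6, per_agent = FALSE) {
  N <- length(x)
  if (N <= n) stop("hex order needs more agents than neighbours")
  per <- vapply(seq_len(N), function(j) {
    dx <- x - x[j]; dy <- y - y[j]
    d <- sqrt(dx^2 + dy^2)
    ok <- which(seq_len(N) != j & d > 0)
    if (length(ok) < n) return(NA_real_)
    nb <- ok[order(d[ok], ok)][seq_len(n)]
    ang <- atan2(dy[nb], dx[nb])
    Mod(mean(exp(1i * 6 * ang)))
  }, numeric(1))
  if (per_agent) per else mean(per, na.rm = TRUE)
}

#' Swarm spread
#'
#' `Sigma = sx^2(t) / (2 sx^2(0)) + sy^2(t) / (2 sy^2(0))`, the position
#' variance in each direction normalized by its initial value; 1 at
#' `t = 0`. The `Sigma_0` variant restricts to agents with `x < 0` at
#' time `t` (the left gyre after a crossing).
#'
#' @param x,y positions at time `t`.
#' @param x0,y0 positions at time 0 (of the full ensemble).
#' @param region optional `"left"` to restrict the time-`t` ensemble to
#'   `x < 0`.
#' @return the spread, or `NA` when fewer than 2 agents qualify.
#' @export
spread <- function(x, y, x0, y0, region = c("all", "left")) {
  region <- match.arg(region)
  if (stats::var(x0) == 0 || stats::var(y0) == 0)
    stop("zero initial position variance")
  if (region == "left") { keep <- x < 0; x <- x[keep]; y <- y[keep] }
  if (length(x) < 2) return(NA_real_)
  stats::var(x) / (2 * stats::var(x0)) + stats::var(y) / (2 * stats::var(y0))
}

#' Gaussian-kernel temporal smoothing
#'
#' Convolution with a normalized Gaussian kernel of total width `window`
#' (interpreted as 4 standard deviations, truncated at +/- 2 sd and
#' renormalized, also at the series edges). A constant series is
#' returned unchanged.
#'
#' @param x series on a uniform time grid.
#' @param time time stamps (s).
#' @param window kernel window (s); default 15.
#' @return the smoothed series.
#' @export
gaussian_smooth <- function(x, time, window = 15) {
  if (length(x) != length(time)) stop("series and time grid lengths differ")
  if (length(x) < 2) return(x)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * max(dt)) stop("time grid must be uniform")
  sigma <- window / 4
  half <- max(1L, ceiling(2 * sigma / dt[1]))
  k <- stats::dnorm(seq(-half, half) * dt[1], sd = sigma)
  n <- length(x)
  ok <- is.finite(x)
  # zero-pad and divide by the kernel mass actually inside the series, which
  # renormalizes the truncated kernel at the edges (and across NA gaps)
  pad <- rep(0, half)
  num <- stats::filter(c(pad, ifelse(ok, x, 0), pad), k, sides = 2)
  den <- stats::filter(c(pad, as.numeric(ok), pad), k, sides = 2)
  sel <- (half + 1L):(half + n)
  out <- as.numeric(num[sel] / den[sel])
  out[!is.finite(out)] <- NA_real_
  out
}

#' Double ensemble average
#'
#' The K-run statistic: each run's metric series is smoothed in time with
#' the Gaussian kernel, then the mean across runs is taken. Also returns
#' the per-run smoothed series, from which difference statistics
#' (active minus passive) are formed.
#'
#' @param series numeric matrix, time in rows, runs in columns (a single
#'   series may be passed as a vector).
#' @param time common time grid.
#' @param window smoothing window (s); default 15.
#' @return list with `time`, `mean` (the double average) and `runs` (the
#'   smoothed per-run matrix).
#' @export
double_average <- function(series, time, window = 15) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  if (nrow(series) != length(time))
    stop("series rows and time grid lengths differ")
  sm <- apply(series, 2, gaussian_smooth, time = time, window = window)
  sm <- matrix(sm, nrow = length(time))
  list(time = time, mean = rowMeans(sm, na.rm = TRUE), runs = sm)
}
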