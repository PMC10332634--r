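# Independent brute-force oracles for the swarm metrics, written from the
# definitions and kept free of the package implementations.

oracle_indication <- function(W, What) sum(W > What) / length(W)

oracle_turbulence_fraction <- function(a, p) {
  What <- sum(p) / length(p)
  na <- sum(a > What); np <- sum(p > What)
  if (np == 0) NA_real_ else (na / length(a)) / (np / length(p))
}

oracle_crossing_fraction <- function(xa, xp, b = 0) {
  np <- sum(xp > b)
  if (np == 0) NA_real_ else (sum(xa > b) / length(xa)) / (np / length(xp))
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

oracle_hex <- function(x, y, n) {
  N <- length(x)
  vals <- c()
  for (j in seq_len(N)) {
    d <- sqrt((x - x[j])^2 + (y - y[j])^2)
    ord <- order(d, seq_len(N))
    ord <- ord[ord != j & d[ord] > 0]
    if (length(ord) < n) next
    nb <- ord[1:n]
    z <- complex(modulus = 1, argument = 6 * atan2(y[nb] - y[j], x[nb] - x[j]))
    vals <- c(vals, Mod(mean(z)))
  }
  mean(vals)
}

# dense-grid root scan for stable fixed points of the orientation dynamics
oracle_stable_orientations <- function(eps_U, eps_C, eps_F, dU, dC, dF,
                                       n_grid = 20000) {
  th <- seq(-pi, pi, length.out = n_grid + 1)[-1]
  f <- eps_U * sin(th - dU) + eps_C * sin(th - dC) - eps_F * sin(th - dF)
  roots <- c()
  # sign changes from + to - mark stable roots of dtheta/dt = f(theta)
  s <- sign(f)
  for (i in seq_along(th)) {
    ip <- if (i == length(th)) 1L else i + 1L
    if (s[i] > 0 && s[ip] < 0) {
      # linear interpolation inside the bracket
      t1 <- th[i]; t2 <- if (ip == 1L) th[i] + diff(th[1:2]) else th[ip]
      w <- f[i] / (f[i] - f[ip])
      roots <- c(roots, t1 + w * (t2 - t1))
    }
  }
  roots
}

angle_diff <- function(a, b) atan2(sin(a - b), cos(a - b))
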