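# Naive scalar-loop oracles, kept deliberately independent of the
# vectorized implementations in the package.

oracle_pim_riemann <- function(x, ts) { s <- 0; for (v in x) s <- s + v; ts * s }

oracle_pim_simpson38 <- function(x, ts) {
  m <- length(x) - 1L
  n3 <- (m %/% 3L) * 3L
  total <- 0
  i <- 1L
  while (i + 3L <= n3 + 1L) {
    total <- total + 3 * ts / 8 * (x[i] + 3 * x[i + 1L] + 3 * x[i + 2L] + x[i + 3L])
    i <- i + 3L
  }
  while (i <= m) {
    total <- total + ts / 2 * (x[i] + x[i + 1L])
    i <- i + 1L
  }
  total
}

oracle_zcm <- function(x, thr) {
  side <- 0L; count <- 0L
  for (v in x) {
    s <- if (v > thr) 1L else if (v < thr) -1L else 0L
    if (s != 0L) {
      if (side != 0L && s != side) count <- count + 1L
      side <- s
    }
  }
  count
}

oracle_tat <- function(x, thr, ts) { n <- 0L; for (v in x) if (v > thr) n <- n + 1L; ts * n }

oracle_mad <- function(x) { m <- mean(x); s <- 0; for (v in x) s <- s + abs(v - m); s / length(x) }

oracle_enmo <- function(x) { s <- 0; for (v in x) if (v > 1) s <- s + v - 1; s / length(x) }

oracle_hfen <- function(x) { s <- 0; for (v in x) s <- s + v; s / length(x) }

oracle_ai <- function(ex, ey, ez, nv) {
  v2 <- function(w) { m <- mean(w); sum((w - m)^2) / (length(w) - 1) }
  max(((v2(ex) - nv) + (v2(ey) - nv) + (v2(ez) - nv)) / 3, 0)
}

# zero-mean band-limited series with a slowly drifting lognormal envelope,
# the shape of a band-pass-filtered magnitude signal; used for the
# full-rectification comparison
bandlimited_fixture <- function(seed, n_hours = 6, env_sd = 0.8, tau_s = 300,
                                high_cut = 1.0, scale = 0.05, fs = 10) {
  set.seed(seed)
  n <- n_hours * 3600 * fs
  carrier <- butterworth_filter(rnorm(n), filter_spec(high_cut_hz = high_cut),
                                fs = fs)
  carrier <- carrier / sd(carrier)
  z <- as.numeric(stats::filter(rnorm(n), exp(-1 / (fs * tau_s)),
                                method = "recursive"))
  z <- z / sd(z)
  x <- scale * exp(env_sd * z - env_sd^2 / 2) * carrier
  dataset_series(x, "FMpost", fs, "synthetic band-limited fixture")
}
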