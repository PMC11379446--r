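# Independent brute-force oracles used to validate the vectorised
# implementations. Deliberately written as plain loops over cells/samples.

oracle_roa <- function(map, layout, thr) {
  L <- -Inf
  for (r in seq_len(nrow(map))) for (c in seq_len(ncol(map)))
    if (!is.na(map[r, c]) && map[r, c] > L) L <- map[r, c]
  sw <- sft <- sfp <- 0
  n_act <- 0
  for (r in seq_len(nrow(map))) for (c in seq_len(ncol(map))) {
    a <- map[r, c]
    if (!is.na(a) && a >= thr * L) {
      sw <- sw + a
      sft <- sft + a * (c - 1) * layout$ied_ft
      sfp <- sfp + a * (r - 1) * layout$ied_fp
      n_act <- n_act + 1
    }
  }
  if (sw > 0) return(c(ft = sft / sw, fp = sfp / sw))
  # zero-amplitude active set: unweighted centroid
  sft <- sfp <- 0
  for (r in seq_len(nrow(map))) for (c in seq_len(ncol(map))) {
    a <- map[r, c]
    if (!is.na(a) && a >= thr * L) {
      sft <- sft + (c - 1) * layout$ied_ft
      sfp <- sfp + (r - 1) * layout$ied_fp
    }
  }
  c(ft = sft / n_act, fp = sfp / n_act)
}

oracle_path <- function(u, v) {
  tot <- tu <- tv <- 0
  for (i in 2:length(u)) {
    tot <- tot + sqrt((u[i] - u[i - 1])^2 + (v[i] - v[i - 1])^2)
    tu <- tu + abs(u[i] - u[i - 1])
    tv <- tv + abs(v[i] - v[i - 1])
  }
  c(tot, tu, tv)
}

oracle_dist <- function(u, v, ru, rv) {
  s <- su <- sv <- 0
  for (i in seq_along(u)) {
    s <- s + sqrt((u[i] - ru)^2 + (v[i] - rv)^2)
    su <- su + abs(u[i] - ru)
    sv <- sv + abs(v[i] - rv)
  }
  c(s, su, sv) / length(u)
}

oracle_spread <- function(u, v) {
  mu <- sum(u) / length(u); mv <- sum(v) / length(v)
  su <- sqrt(sum((u - mu)^2) / length(u))
  sv <- sqrt(sum((v - mv)^2) / length(v))
  c(sqrt(su^2 + sv^2), su, sv, mu, mv)
}

oracle_amz <- function(u, v, T) {
  x <- u - mean(u); y <- v - mean(v)
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] * y[i - 1] - x[i - 1] * y[i])
  s / (2 * T)
}

# raw (untapered) periodogram spectral centroid over a band
oracle_centroid <- function(x, fs, band = c(20, 450)) {
  n <- length(x)
  P <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= band[1] & f <= band[2]
  sum(P[keep] * f[keep]) / sum(P[keep])
}

rand_map <- function(layout, p_na = 0.1) {
  m <- matrix(runif(layout$n_rows * layout$n_cols, 0.1, 2),
              layout$n_rows, layout$n_cols)
  holes <- runif(length(m)) < p_na
  if (all(holes)) holes[1] <- FALSE
  m[holes] <- NA
  m
}

rand_traj <- function(n, dt = 0.1, sd = 3) {
  data.frame(t = (seq_len(n) - 0.5) * dt,
             ft = rnorm(n, 10, sd), fp = rnorm(n, 50, sd))
}

rotate_traj <- function(traj, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy <- as.matrix(traj[, c("ft", "fp")]) %*% t(R)
  data.frame(t = traj$t, ft = xy[, 1], fp = xy[, 2])
}

one_ch_rec <- function(x, fs = 2048)
  emg_recording(matrix(x, 1), fs, grid_layout(1, 1))

mid_rms <- function(x, frac = 0.6) {
  n <- length(x)
  i <- seq(floor(n * (1 - frac) / 2) + 1, length.out = floor(n * frac))
  sqrt(mean(x[i]^2))
}

# small, fast simulator setup used across tests: 13x5 grid, 45 s record
quick_cfg <- function(seed, ...) {
  args <- list(...)
  defaults <- list(
    layout = grid_layout(13, 5, 8, 8, missing = rbind(c(1L, 5L))),
    fs = 1024, duration_s = 45, failure_time_s = 42,
    center_path = rbind(c(0, 16, 40), c(45, 16, 60)), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}
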