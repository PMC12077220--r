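# Shared fixtures: small synthetic tracks and brute-force oracles.

# straight track along +x: speed um/s over duration_s at fps
straight_track <- function(speed = 10, duration_s = 10, fps = 30,
                           x0 = 0, y0 = 0, angle = 0) {
  nf <- fps * duration_s
  t <- (0:nf) / fps
  data.frame(frame = 0:nf, t_s = t,
             x_um = x0 + speed * t * cos(angle),
             y_um = y0 + speed * t * sin(angle))
}

# closed circle traversed once: circumference C, n vertices
circle_track <- function(circumference = 100, n = 2000, fps = 30) {
  r <- circumference / (2 * pi)
  th <- seq(0, 2 * pi, length.out = n + 1)
  data.frame(frame = 0:n, t_s = (0:n) / fps,
             x_um = r * cos(th), y_um = r * sin(th))
}

# random-walk track with n steps
rw_track <- function(n = 50, step_sd = 3, fps = 30) {
  data.frame(frame = 0:n, t_s = (0:n) / fps,
             x_um = cumsum(c(runif(1, 0, 100), rnorm(n, 0, step_sd))),
             y_um = cumsum(c(runif(1, 0, 100), rnorm(n, 0, step_sd))))
}

# independent brute-force recomputation of track metrics (O(n) loops,
# no vectorised shortcuts shared with the implementation)
brute_metrics <- function(track) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  total <- 0
  for (i in 2:n) {
    total <- total + sqrt((track$x_um[i] - track$x_um[i - 1])^2 +
                          (track$y_um[i] - track$y_um[i - 1])^2)
  }
  maxd <- 0
  for (i in 2:n) {
    d <- sqrt((track$x_um[i] - track$x_um[1])^2 +
              (track$y_um[i] - track$y_um[1])^2)
    if (d > maxd) maxd <- d
  }
  el <- track$t_s[n] - track$t_s[1]
  speed <- total / el
  conf <- if (total > 0) maxd / total else 0
  list(total = total, maxd = maxd, speed = speed, conf = conf,
       disp = speed * conf)
}

# brute-force assignment by permutation enumeration (n <= 7)
brute_lap <- function(M) {
  nr <- nrow(M)
  nc <- ncol(M)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  best_a <- NULL
  for (p in perms(seq_len(nc))) {
    a <- p[seq_len(nr)]
    cst <- sum(M[cbind(seq_len(nr), a)])
    if (cst < best) {
      best <- cst
      best_a <- a
    }
  }
  list(cost = best, assignment = best_a)
}

# per-temperature rate table drawn from a TPC model with replicate noise
gen_tpc_data <- function(model, params, temps, n_rep = 3, cv = 0.1,
                         seed = 1) {
  mu <- tpc_rate(model, temps, params)
  set.seed(seed)
  reps <- replicate(n_rep, mu + abs(mu) * cv * rnorm(length(temps)))
  data.frame(temperature_C = temps, rate = rowMeans(reps),
             sd = pmax(apply(reps, 1, sd), 0.05 * max(abs(mu)) * cv),
             n = n_rep)
}
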