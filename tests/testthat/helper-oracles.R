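# Independent brute-force oracles and trace constructions used across the
# suite. Each oracle is a direct-formula implementation kept deliberately
# separate from the package's code paths.

# ---- statistics oracles -----------------------------------------------------

# One-way ANOVA from raw sums of squares.
oracle_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, df_between = dfb, df_within = dfw,
       p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# Pooled-variance two-sided t test from the textbook formula.
oracle_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Pearson r and its t-transform p value from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Split-plot (two-way repeated measures) decomposition from cell means.
# df: subjects x (subject, group, w, y), complete design.
oracle_rm_anova <- function(df) {
  subj <- factor(df$subject); grp <- factor(df$group); w <- factor(df$w)
  a <- nlevels(grp); b <- nlevels(w); ns <- nlevels(subj)
  gm <- mean(df$y)
  subj_mean <- tapply(df$y, subj, mean)
  grp_of_subj <- tapply(as.character(df$group), subj, `[`, 1)
  grp_mean <- tapply(df$y, grp, mean)
  w_mean <- tapply(df$y, w, mean)
  cell_mean <- tapply(df$y, list(grp, w), mean)
  n_per_grp <- table(grp_of_subj)[levels(grp)]

  ss_group <- b * sum(n_per_grp * (grp_mean - gm)^2)
  ss_subj <- b * sum((subj_mean - gm)^2)
  ss_subj_w <- ss_subj - ss_group
  ss_w <- ns * sum((w_mean - gm)^2)
  ss_cells <- sum(rep(n_per_grp, b) * (as.vector(cell_mean) - gm)^2)
  ss_int <- ss_cells - ss_group - ss_w
  ss_tot <- sum((df$y - gm)^2)
  ss_res <- ss_tot - ss_subj - ss_w - ss_int

  df_sw <- ns - a; df_res <- (ns - a) * (b - 1)
  fg <- (ss_group / (a - 1)) / (ss_subj_w / df_sw)
  fw <- (ss_w / (b - 1)) / (ss_res / df_res)
  fi <- (ss_int / ((a - 1) * (b - 1))) / (ss_res / df_res)
  list(group = list(f = fg, p = pf(fg, a - 1, df_sw, lower.tail = FALSE)),
       within = list(f = fw, p = pf(fw, b - 1, df_res, lower.tail = FALSE)),
       interaction = list(f = fi,
                          p = pf(fi, (a - 1) * (b - 1), df_res,
                                 lower.tail = FALSE)))
}

# F/I slope by explicit normal equations.
oracle_fi_slope <- function(amps, freqs) {
  x <- cbind(1, amps)
  solve(t(x) %*% x, t(x) %*% freqs)[2]
}

# ---- waveform oracles -------------------------------------------------------

# Spike-threshold time by raw repeated central differences (no smoothing) in
# the window [peak - window_ms, peak].
oracle_threshold_index <- function(v, dt, peak_idx, window_ms = 2) {
  i0 <- max(1L, peak_idx - round(window_ms / dt))
  d <- v[i0:peak_idx]
  for (k in 1:3) {
    n <- length(d)
    d <- c(NA, (d[3:n] - d[1:(n - 2)]) / (2 * dt), NA)
  }
  i0 + which.max(d) - 1L
}

# Half-width by exhaustive crossing scan on a 20x dense linear resample.
oracle_half_width <- function(v, dt, peak_idx, level) {
  up <- 20L
  n <- length(v)
  td <- seq(0, (n - 1) * dt, by = dt / up)
  vd <- approx(seq(0, (n - 1) * dt, by = dt), v, td)$y
  pk <- (peak_idx - 1) * dt
  iu <- which(td < pk & vd >= level)
  idn <- which(td > pk & vd < level)
  if (!length(iu) || !length(idn)) return(NA_real_)
  td[idn[1]] - td[iu[1]]
}

# ---- constructions ----------------------------------------------------------

# A current-clamp sweep whose post-step epoch carries an imposed exponential
# decay (amp_mv, tau_ms) below a flat baseline, with n_spikes clean upward
# 0 mV crossings inside the step so the sweep qualifies for AHP measurement.
make_decay_sweep <- function(amp_mv = -4, tau_ms = 150, n_spikes = 13,
                             v0 = -67, dt = 0.05, onset = 100, dur = 250,
                             post = 720) {
  n <- round((onset + dur + post) / dt) + 1L
  tt <- (seq_len(n) - 1L) * dt
  v <- rep(v0, n)
  if (n_spikes > 0) {
    at <- onset + seq(10, dur - 10, length.out = n_spikes)
    for (t0 in at) {
      i <- round(t0 / dt) + 1L
      v[i:(i + 1L)] <- c(10, 10)  # two samples above 0 mV: one crossing
    }
  }
  post_idx <- tt >= onset + dur  # deflection starts at step end (t = 0)
  v[post_idx] <- v[post_idx] + amp_mv * exp(-(tt[post_idx] - onset - dur) / tau_ms)
  sweep_trace(v, dt = dt,
              stimulus = stimulus_step(300, onset = onset, duration = dur),
              mode = "current_clamp")
}

recording_of <- function(..., group = "test") {
  recording(list(...), cell_id = "c1", animal_id = "a1", group = group)
}

# Hand-built spike train (times in ms).
make_train <- function(times_ms) {
  structure(list(times = times_ms,
                 inst_freq = if (length(times_ms) >= 2)
                   1000 / diff(times_ms) else numeric(0)),
            class = "spike_train")
}

# Flat current-clamp recording with one sweep per requested step amplitude,
# long enough for the AHP windows (used with hand-built spike trains).
dummy_step_rec <- function(amps) {
  sw <- lapply(amps, function(a)
    sweep_trace(rep(-67, 1061), dt = 1,
                stimulus = stimulus_step(a, onset = 100, duration = 250),
                mode = "current_clamp"))
  recording(sw, group = "g")
}

# Random small cohort table for statistics oracle loops.
random_table <- function(k = 3, n = c(8, 7, 9), mean = 0, sd = 1) {
  do.call(rbind, lapply(seq_len(k), function(g)
    data.frame(subject = sprintf("g%d_%02d", g, seq_len(n[g])),
               group = paste0("g", g),
               value = rnorm(n[g], mean, sd),
               stringsAsFactors = FALSE)))
}

# Random complete split-plot table.
random_rm_table <- function(a = 2, b = 4, n = 5) {
  subj <- 0
  do.call(rbind, lapply(seq_len(a), function(g) {
    do.call(rbind, lapply(seq_len(n), function(s) {
      subj <<- subj + 1
      data.frame(subject = sprintf("s%02d", subj), group = paste0("g", g),
                 day = seq_len(b), value = rnorm(b, mean = g / 2),
                 stringsAsFactors = FALSE)
    }))
  }))
}
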