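# Independent oracle implementations, written straight from the metric
# definitions with plain loops. They deliberately share no code with the
# package internals they check.

oracle_interval_pace <- function(count, dur_sec) {
  if (dur_sec < 0.5) return(NULL)
  count / dur_sec * 60
}

oracle_day_pace <- function(counts, durs_sec) {
  paces <- c()
  for (i in seq_along(counts)) {
    p <- oracle_interval_pace(counts[i], durs_sec[i])
    if (!is.null(p)) paces <- c(paces, p)
  }
  if (length(paces) == 0) return(NULL)
  list(mean = sum(paces) / length(paces), max = max(paces))
}

oracle_hrr <- function(avg, rest) avg - rest

oracle_cardiac_effort <- function(whr, dist_m, dur_sec) {
  if (is.na(dist_m) || is.na(dur_sec) || dist_m <= 0 || dur_sec <= 0) return(NA_real_)
  whr / (dist_m / dur_sec)
}

oracle_bed_bound <- function(in_bed) in_bed >= 18

oracle_pace70 <- function(t_i, P_i, P_max) {
  num <- 0
  den <- 0
  for (i in seq_along(t_i)) {
    if (P_i[i] > 0) den <- den + t_i[i]
    if (P_i[i] > 0.7 * P_max) num <- num + t_i[i]
  }
  if (den == 0) return(NA_real_)
  num / den
}

# ---- brute-force featurization oracles -----------------------------------

oracle_time_features <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  out <- list(N = n)
  if (n == 0) return(out)
  mu <- sum(x) / n
  out$MAX <- max(x); out$MIN <- min(x); out$P2P <- max(x) - min(x)
  out$MEAN <- mu
  ss <- 0; s3 <- 0; s4 <- 0; sq <- 0
  for (v in x) {
    ss <- ss + (v - mu)^2
    s3 <- s3 + (v - mu)^3
    s4 <- s4 + (v - mu)^4
    sq <- sq + v^2
  }
  out$RMS <- sqrt(sq / n)
  out$PEAK <- max(abs(x))
  out$CREST_FACTOR <- if (out$RMS > 0) out$PEAK / out$RMS else NA_real_
  if (n >= 2) { out$VAR <- ss / (n - 1); out$STD <- sqrt(ss / (n - 1)) }
  m2 <- ss / n
  if (n >= 3) out$SKEW <- if (m2 > 0) (s3 / n) / m2^1.5 else NA_real_
  if (n >= 4) out$KURTOSIS <- if (m2 > 0) (s4 / n) / m2^2 - 3 else NA_real_
  for (lag in 0:2) {
    if (n >= lag + 1) {
      num <- 0
      for (t in seq_len(n - lag)) num <- num + (x[t] - mu) * (x[t + lag] - mu)
      out[[paste0("cc_lag", lag)]] <- if (ss > 0) num / ss else if (lag == 0) 1 else NA_real_
    }
  }
  out
}

# direct O(N^2) DFT of the centred series, DC bin excluded
oracle_spectrum <- function(x) {
  n <- length(x)
  z <- x - sum(x) / n
  mags <- numeric(n - 1)
  for (k in 1:(n - 1)) {
    re <- 0; im <- 0
    for (t in 0:(n - 1)) {
      ang <- -2 * pi * k * t / n
      re <- re + z[t + 1] * cos(ang)
      im <- im + z[t + 1] * sin(ang)
    }
    mags[k] <- sqrt(re^2 + im^2)
  }
  mags
}

oracle_freq_features <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NULL)
  m <- oracle_spectrum(x)
  k <- length(m)
  mu <- sum(m) / k
  ss2 <- 0; ss3 <- 0; ss4 <- 0
  for (v in m) {
    ss2 <- ss2 + (v - mu)^2; ss3 <- ss3 + (v - mu)^3; ss4 <- ss4 + (v - mu)^4
  }
  m2 <- ss2 / k
  list(MAX_f = max(m), MEAN_f = mu, VAR_f = ss2 / (k - 1), SUM_f = sum(m),
       PEAK_f = max(abs(m)),
       SKEW_f = if (m2 > 0) (ss3 / k) / m2^1.5 else NA_real_,
       KURTOSIS_f = if (m2 > 0) (ss4 / k) / m2^2 - 3 else NA_real_,
       POWER = sum(m^2) / (n * (n - 1)))
}

# random fixture day: intervals plus daily cardio values
random_fixture_day <- function() {
  k <- sample(1:8, 1)
  counts <- rpois(k, 400)
  durs <- runif(k, 0.1, 1800)          # includes sub-0.5 s exclusions
  list(
    counts = counts, durs = durs,
    avg_hr = runif(1, 60, 110), rest_hr = runif(1, 45, 90),
    walk_hr = runif(1, 70, 130), dist = runif(1, 0, 4000),
    walk_dur = runif(1, 60, 7200), in_bed = runif(1, 0, 24)
  )
}
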