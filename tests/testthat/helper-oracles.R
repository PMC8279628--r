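# Independent brute-force oracles used to cross-check the package's
# survival and classification machinery. These deliberately avoid the code
# paths (and libraries) they verify.

# Breslow log partial likelihood for a single covariate: every event term
# uses the full risk set {j : t_j >= t_i}.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_max_breslow <- function(time, event, x, lo = -3, hi = 3, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, breslow_loglik, numeric(1), time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Pairwise Mann-Whitney AUC: ties get half credit.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Harrell's C by enumeration: comparable pairs are event-event with
# distinct times and event-censored where censoring is at or after the
# event; score ties get half credit.
cindex_pairs <- function(scores, times, events) {
  n <- length(times)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || events[i] != 1) next
    comparable <- times[i] < times[j] ||
      (times[i] == times[j] && events[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

# Exhaustive Youden scan over midpoint thresholds, lowest threshold wins.
youden_brute <- function(values, labels) {
  uv <- sort(unique(values))
  cand <- (uv[-length(uv)] + uv[-1]) / 2
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(values[labels == 1] > t)
    spec <- mean(values[labels == 0] <= t)
    j <- sens + spec - 1
    if (j > best_j + 1e-15) { best_j <- j; best_t <- t }
  }
  structure(best_t, youden_j = best_j)
}

# Minimal outcome-frame constructor for toy examples.
toy_outcomes <- function(time_days, event, episode_count = event) {
  data.frame(patient_id = sprintf("T%03d", seq_along(time_days)),
             time_days = time_days, event = event,
             episode_count = episode_count, stringsAsFactors = FALSE)
}
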