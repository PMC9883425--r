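# Independent brute-force oracles used to validate the fast implementations.

# O(n^2) pair-enumeration concordance: a pair is usable iff the earlier
# observed time is an event (a censored time equal to an event time counts
# as later); tied risk scores contribute 1/2.
bruteC <- function(times, events, scores) {
  n <- length(times)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    earlier <- if (times[i] < times[j] && events[i] == 1) i
    else if (times[j] < times[i] && events[j] == 1) j
    else if (times[i] == times[j] && events[i] != events[j]) {
      if (events[i] == 1) i else j
    } else NA_integer_
    if (is.na(earlier)) next
    later <- if (earlier == i) j else i
    den <- den + 1
    if (scores[earlier] > scores[later]) num <- num + 1
    else if (scores[earlier] == scores[later]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables with the observed margins that are no more
# probable than the observed table.
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Plain rank-sum AUC of a binary label against scores (ties count 1/2).
rankAUC <- function(label, scores) {
  pos <- scores[label == 1]; neg <- scores[label == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Synthetic two-stain patch built from known unit stain vectors; the
# ground truth for Macenko recovery tests.
makeTwoStainPatch <- function(n = 64, seed = 1, cmax = c(1.2, 0.9)) {
  set.seed(seed)
  H <- c(0.65, 0.70, 0.29); H <- H / sqrt(sum(H^2))
  E <- c(0.07, 0.99, 0.11); E <- E / sqrt(sum(E^2))
  c1 <- runif(n * n, 0.05, cmax[1])
  c2 <- runif(n * n, 0.05, cmax[2])
  od <- cbind(c1, c2) %*% rbind(H, E)
  list(patch = array(10^(-od), c(n, n, 3)), H = H, E = E)
}

angleDeg <- function(a, b) acos(min(1, abs(sum(a * b)))) * 180 / pi

# Random censored-survival fixture for oracle comparisons.
randomSurvFixture <- function(n, seed, censorFrac = 0.3, tieProb = 0.2) {
  set.seed(seed)
  times <- round(rexp(n, 0.05), ifelse(runif(n) < tieProb, 0, 2))
  times <- pmax(times, 0.5)
  events <- rbinom(n, 1, 1 - censorFrac)
  scores <- rnorm(n)
  if (sum(events) == 0) events[1] <- 1
  list(times = times, events = events, scores = scores)
}
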