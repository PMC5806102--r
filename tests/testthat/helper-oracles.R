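# Independent brute-force oracles.  These deliberately share no code with
# the package: the log-rank oracle sums 2x2 hypergeometric tables time by
# time, the KM oracle multiplies pooled factors, and the concordance oracle
# enumerates every pair.

oracle_logrank <- function(time, event, groups) {
  g <- as.factor(groups)
  z <- as.numeric(g == levels(g)[2L])
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & z == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & z == 1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) 0 else oe^2 / v
}

oracle_km <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n <- sum(time >= t)
    d <- sum(event == 1 & time == t)
    s <- s * (1 - d / n)
  }
  s
}

oracle_cindex <- function(time, event, score) {
  conc <- 0; usable <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      first <- if (time[i] < time[j]) i else j
      second <- if (time[i] < time[j]) j else i
      if (event[first] != 1) next
      usable <- usable + 1
      if (score[first] > score[second]) conc <- conc + 1
      else if (score[first] == score[second]) conc <- conc + 0.5
    }
  }
  conc / usable
}

# small untied survival fixture with continuous times
random_surv <- function(n, seed, censor = 0.3) {
  withr::with_seed(seed, {
    time <- rexp(n, 1 / 50)
    event <- as.integer(runif(n) > censor)
    data.frame(time = time, event = event)
  })
}
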