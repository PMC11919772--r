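# Small shared fixtures, built in code at load time.

small_config <- function(seed = 42L, n_probes = 400L, n = 60L) {
  sim_config(n_cohorts = 2L, n_cases = n, n_controls = n, n_probes = n_probes,
             seed = seed)
}

small_cohort <- function(seed = 42L, ...) {
  generate_cohort(small_config(seed = seed, ...), 1L)
}

# brute-force Levene: one-way ANOVA on absolute deviations, from first
# principles (independent of the package's matrix formulas)
oracle_levene <- function(x, g, center = stats::median) {
  z <- unlist(lapply(split(x, g), function(v) abs(v - center(v))))
  gg <- factor(rep(names(split(x, g)), times = lengths(split(x, g))))
  fit <- stats::anova(stats::lm(z ~ gg))
  list(statistic = fit$`F value`[1], p.value = fit$`Pr(>F)`[1])
}

# brute-force Bartlett from the textbook formula, step by step
oracle_bartlett <- function(groups) {
  k <- length(groups); n <- lengths(groups); N <- sum(n)
  v <- vapply(groups, stats::var, 0)
  sp2 <- sum((n - 1) * v) / (N - k)
  C <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  T <- ((N - k) * log(sp2) - sum((n - 1) * log(v))) / C
  list(statistic = T, p.value = stats::pchisq(T, k - 1, lower.tail = FALSE))
}

# brute-force Fligner-Killeen via explicit rank/normal-score construction
oracle_fligner <- function(groups) {
  a_dev <- lapply(groups, function(v) abs(v - stats::median(v)))
  all_dev <- unlist(a_dev)
  N <- length(all_dev)
  r <- rank(all_dev)
  a <- stats::qnorm(0.5 + r / (2 * (N + 1)))
  gg <- rep(seq_along(groups), times = lengths(groups))
  abar <- mean(a)
  stat <- sum(tapply(a, gg, function(x) length(x) * (mean(x) - abar)^2)) / stats::var(a)
  list(statistic = stat, p.value = stats::pchisq(stat, length(groups) - 1,
                                                 lower.tail = FALSE))
}

# brute-force BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m); out[o] <- q
  out
}

# brute-force two-sided Fisher exact P by hypergeometric enumeration
oracle_fisher_p <- function(a, b, cc, d) {
  m <- a + cc; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# step-by-step DerSimonian-Laird random-effects meta-analysis
oracle_dl <- function(b, se) {
  w <- 1 / se^2
  bfe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - bfe)^2)
  k <- length(b)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  list(beta_fe = bfe, se_fe = 1 / sqrt(sum(w)), Q = Q, tau2 = tau2,
       beta_re = sum(wr * b) / sum(wr), se_re = 1 / sqrt(sum(wr)))
}
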