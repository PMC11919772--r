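toy_groups <- function(seed = 1, n1 = 8, n2 = 8, sd2 = 2) {
  set.seed(seed)
  list(x = c(rnorm(n1), rnorm(n2, 0, sd2)),
       g = rep(c("control", "case"), c(n1, n2)))
}

test_that("residualize leaves residuals orthogonal to the design", {
  co <- small_cohort(n_probes = 100L, n = 40L)
  rz <- residualize(co$beta, co$samplesheet)
  R <- rz$residuals; X <- rz$design
  ip <- R %*% X
  expect_lt(max(abs(ip)), 1e-8)
  expect_lt(max(abs(rowMeans(R))), 1e-10)  # intercept in design
  # age is a design column, so residuals are uncorrelated with it
  age <- co$samplesheet$horvath_age
  cors <- apply(R[1:20, ], 1, function(r) cor(r, age))
  expect_lt(max(abs(cors)), 1e-8)
  # intercept-only design: residuals equal centred values
  ss0 <- co$samplesheet[, c("sample_id", "diagnosis")]
  rz0 <- residualize(co$beta, ss0, covariates = character(0))
  expect_equal(rz0$residuals, co$beta - rowMeans(co$beta), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rank-deficient designs are rejected with the offending column", {
  co <- small_cohort(n_probes = 20L, n = 30L)
  ss <- co$samplesheet
  ss$dup_age <- ss$horvath_age
  expect_error(residualize(co$beta, ss, covariates = c("horvath_age", "dup_age")),
               "rank-deficient.*dup_age")
})

test_that("levene_test matches its brute-force oracle and is antisymmetric", {
  for (seed in 1:5) {
    toy <- toy_groups(seed)
    got <- levene_test(toy$x, toy$g)
    want <- oracle_levene(toy$x, toy$g)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
    # mean-centred form against its own oracle
    got_m <- levene_test(toy$x, toy$g, center = "mean")
    want_m <- oracle_levene(toy$x, toy$g, center = mean)
    expect_equal(got_m$statistic, want_m$statistic, tolerance = 1e-10)
    # swapping labels flips Z, preserves P
    flipped <- ifelse(toy$g == "case", "control", "case")
    got2 <- levene_test(toy$x, flipped)
    expect_equal(got2$z, -got$z, tolerance = 1e-10)
    expect_equal(got2$p.value, got$p.value, tolerance = 1e-10)
  }
  # identical groups: W = 0, P = 1, Z = 0
  same <- levene_test(c(1:5, 1:5), rep(c("control", "case"), each = 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$z, 0)
  # constant values: flagged NA
  degen <- levene_test(rep(1, 10), rep(c("control", "case"), each = 5))
  expect_true(is.na(degen$statistic))
})

test_that("bartlett_test matches stats::bartlett.test and the closed form", {
  for (seed in 1:5) {
    toy <- toy_groups(seed, n1 = 10, n2 = 12)
    got <- bartlett_test(toy$x, toy$g)
    ref <- bartlett.test(split(toy$x, toy$g))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
    want <- oracle_bartlett(split(toy$x, toy$g))
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    # scale invariance
    got_sc <- bartlett_test(toy$x * 3.7, toy$g)
    expect_equal(got_sc$statistic, got$statistic, tolerance = 1e-10)
  }
  # sign convention: larger case variance means positive Z
  x <- c(rnorm(20), rnorm(20, 0, 3)); g <- rep(c("control", "case"), each = 20)
  set.seed(4); expect_gt(bartlett_test(x, g)$z, 0)
})

test_that("fligner_killeen_test matches stats::fligner.test and the oracle", {
  for (seed in 1:5) {
    toy <- toy_groups(seed, n1 = 9, n2 = 11)
    got <- fligner_killeen_test(toy$x, toy$g)
    ref <- fligner.test(split(toy$x, toy$g))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
    want <- oracle_fligner(split(toy$x, toy$g))
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
  }
  same <- fligner_killeen_test(c(1:6, 1:6), rep(c("control", "case"), each = 6))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
})

test_that("signed Z and two-sided P are mutually consistent", {
  co <- small_cohort(n_probes = 300L, n = 50L)
  st <- run_cohort_association(co$beta, co$samplesheet)
  for (test in c("levene", "bartlett", "fligner")) {
    z <- st[[paste0(test, "_z")]]; p <- st[[paste0(test, "_p")]]
    ok <- !is.na(z)
    expect_equal(abs(z[ok]), qnorm(1 - p[ok] / 2), tolerance = 1e-9)
  }
})

test_that("mean_ewas matches a normal-equations oracle on a toy problem", {
  set.seed(9)
  n <- 10
  ss <- data.frame(sample_id = sprintf("s%d", 1:n),
                   diagnosis = rep(c("control", "case"), each = n / 2),
                   horvath_age = rnorm(n, 50, 5))
  beta <- matrix(runif(3 * n, 0.2, 0.8), 3, n,
                 dimnames = list(sprintf("cg%d", 1:3), ss$sample_id))
  got <- mean_ewas(beta, ss, covariates = "horvath_age")
  for (j in 1:3) {
    fit <- summary(lm(beta[j, ] ~ ss$horvath_age + I(ss$diagnosis == "case")))
    expect_equal(got$beta[j], fit$coefficients[3, 1], tolerance = 1e-10)
    expect_equal(got$se[j], fit$coefficients[3, 2], tolerance = 1e-10)
    expect_equal(got$p.value[j], fit$coefficients[3, 4], tolerance = 1e-10)
  }
})

test_that("mean_ewas recovers a planted latent mean shift", {
  cfg <- sim_config(n_cohorts = 1, n_cases = 200, n_controls = 200,
                    n_probes = 1000, mean_shift = 0.3, seed = 13)
  co <- generate_cohort(cfg, 1)
  me <- mean_ewas(co$beta, co$samplesheet)
  dmp <- co$truth$effect_class == "mean_shift"
  # planted shifts are detected far above the null probes
  expect_gt(mean(abs(me$z[dmp])), 3 * mean(abs(me$z[co$truth$effect_class == "null"])))
  # recovered beta agrees in sign with the planted latent delta
  expect_true(all(sign(me$beta[dmp]) == sign(co$truth$delta[dmp])))
})

test_that("run_cohort_association handles the minimal 2/2 cohort", {
  set.seed(2)
  ss <- data.frame(sample_id = sprintf("s%d", 1:4),
                   diagnosis = rep(c("control", "case"), each = 2))
  beta <- matrix(runif(8, 0.3, 0.7), 2, 4,
                 dimnames = list(c("cg1", "cg2"), ss$sample_id))
  st <- run_cohort_association(beta, ss, covariates = character(0))
  expect_equal(nrow(st), 2)
  expect_equal(st$n_case[1], 2)
})

test_that("null P-values are uniform where each test's assumptions hold", {
  cfg <- sim_config(n_cohorts = 1, n_cases = 200, n_controls = 200,
                    n_probes = 2000, fraction_vmp_up = 0, fraction_vmp_down = 0,
                    fraction_dmp = 0, seed = 21)
  co <- generate_cohort(cfg, 1, keep_latent = TRUE)
  st <- run_cohort_association(co$beta, co$samplesheet)
  ks_crit_1pct <- 1.63 / sqrt(2000)
  # robust tests are uniform on the (non-normal) beta scale
  for (test in c("levene", "fligner")) {
    p <- st[[paste0(test, "_p")]]
    expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), ks_crit_1pct)
  }
  # Bartlett is uniform on the exactly Gaussian latent noise; on the beta
  # scale the logistic map breaks its normality assumption (anticonservative)
  case <- which(co$samplesheet$diagnosis == "case")
  ctrl <- which(co$samplesheet$diagnosis == "control")
  bt_latent <- methvar:::row_bartlett(co$epsilon, case, ctrl)
  expect_lt(suppressWarnings(ks.test(bt_latent$p.value, "punif")$statistic),
            ks_crit_1pct)
  expect_gt(mean(st$bartlett_p < 0.05), mean(st$fligner_p < 0.05))
})

test_that("Bartlett rejects more than Fligner-Killeen under heavy-tailed null noise", {
  set.seed(9)
  M <- matrix(rt(1000 * 300, df = 5), 1000, 300)
  bt <- methvar:::row_bartlett(M, 1:150, 151:300)
  fk <- methvar:::row_fligner(M, 1:150, 151:300)
  expect_gt(mean(bt$p.value < 0.05), mean(fk$p.value < 0.05))
  # and the robust test stays near its level
  expect_lt(abs(mean(fk$p.value < 0.05) - 0.05), 0.02)
})
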