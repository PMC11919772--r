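test_that("sim_config validates its invariants", {
  expect_s3_class(small_config(), "sim_config")
  expect_error(sim_config(n_cases = 1), "at least 2")
  expect_error(sim_config(variance_ratio = 0), "positive")
  expect_error(sim_config(fraction_vmp_up = 0.8, fraction_dmp = 0.4), "sum")
  expect_error(sim_config(n_probes = 0), "n_probes")
})

test_that("all-zero effect fractions give an all-null ground truth", {
  cfg <- sim_config(n_cohorts = 1, n_cases = 5, n_controls = 5, n_probes = 200,
                    fraction_vmp_up = 0, fraction_vmp_down = 0, fraction_dmp = 0)
  co <- generate_cohort(cfg, 1)
  expect_true(all(co$truth$effect_class == "null"))
  expect_true(all(co$truth$rho == 1))
  expect_true(all(co$truth$delta == 0))
})

test_that("ground-truth class counts match the configured fractions", {
  cfg <- small_config(n_probes = 2000L)
  tr <- generate_cohort(cfg, 1)$truth
  expect_equal(sum(tr$effect_class == "variance_up"),
               round(cfg$fraction_vmp_up * cfg$n_probes))
  expect_equal(sum(tr$effect_class == "variance_down"),
               round(cfg$fraction_vmp_down * cfg$n_probes))
  expect_equal(sum(tr$effect_class == "mean_shift"),
               round(cfg$fraction_dmp * cfg$n_probes))
  expect_true(all(tr$rho[tr$effect_class == "null"] == 1))
})

test_that("generation is deterministic and beta values live in (0,1)", {
  a <- generate_cohort(small_config(), 1)
  b <- generate_cohort(small_config(), 1)
  expect_identical(a$beta, b$beta)
  expect_identical(a$samplesheet, b$samplesheet)
  expect_true(all(a$beta > 0 & a$beta < 1))
  # different cohorts of the same study share ground truth but not samples
  c2 <- generate_cohort(small_config(), 2)
  expect_identical(a$truth, c2$truth)
  expect_false(identical(a$beta[1, 1], c2$beta[1, 1]))
})

test_that("planted variance ratio is recoverable from the emitted latent noise", {
  cfg <- sim_config(n_cohorts = 1, n_cases = 500, n_controls = 500,
                    n_probes = 300, variance_ratio = 2, seed = 7)
  co <- generate_cohort(cfg, 1, keep_latent = TRUE)
  up <- which(co$truth$effect_class == "variance_up")
  case <- co$samplesheet$diagnosis == "case"
  ratios <- vapply(up, function(j)
    var(co$epsilon[j, case]) / var(co$epsilon[j, !case]), 0)
  # each ratio should sit in the F-based 95% sampling interval around rho = 2
  qs <- 2 * qf(c(0.025, 0.975), 499, 499)
  expect_true(all(ratios > qs[1] & ratios < qs[2]))
  # and null probes near 1 on average
  nulls <- sample(which(co$truth$effect_class == "null"), 50)
  rn <- vapply(nulls, function(j)
    var(co$epsilon[j, case]) / var(co$epsilon[j, !case]), 0)
  expect_lt(abs(mean(rn) - 1), 0.05)
})

test_that("samplesheet invariants hold", {
  co <- small_cohort()
  ss <- co$samplesheet
  expect_false(any(duplicated(ss$sample_id)))
  cells <- as.matrix(ss[, grep("^cell_prop_", names(ss))])
  expect_true(all(abs(rowSums(cells) - 1) < 1e-6))
  expect_true(all(ss$diagnosis %in% c("control", "case")))
})

test_that("annotation clustering behaves as configured", {
  # clustering off: no two probes within the 500 bp region window
  ann0 <- generate_annotation(300, cluster_fraction = 0, seed = 5)
  for (cc in unique(ann0$chr)) {
    p <- sort(ann0$pos[ann0$chr == cc])
    if (length(p) > 1) expect_gt(min(diff(p)), 500)
  }
  # clusters requested: at least one run of 5 probes within the cluster width
  ann1 <- generate_annotation(500, cluster_fraction = 0.5, cluster_size = 5,
                              cluster_width = 200, seed = 5)
  found <- FALSE
  for (cc in unique(ann1$chr)) {
    p <- sort(ann1$pos[ann1$chr == cc])
    if (length(p) >= 5)
      for (i in seq_len(length(p) - 4))
        if (p[i + 4] - p[i] <= 200) { found <- TRUE; break }
  }
  expect_true(found)
  # seeded blacklist counts are reproducible
  a1 <- generate_annotation(5000, frac_cross_hyb = 0.1, seed = 9)
  a2 <- generate_annotation(5000, frac_cross_hyb = 0.1, seed = 9)
  expect_identical(sum(a1$flag_cross_hybridising), sum(a2$flag_cross_hybridising))
  expect_lt(abs(sum(a1$flag_cross_hybridising) / 5000 - 0.1), 0.02)
})

test_that("external catalog hits its target correlation and flags tiny traits", {
  set.seed(31)
  z <- setNames(rnorm(2000), sprintf("cg%07d", 1:2000))
  specs <- data.frame(trait = c("null_trait", "cor_trait", "tiny"),
                      n_probes = c(150, 200, 9),
                      target_r = c(0, 0.4, 0.5))
  cat_tab <- generate_external_catalog(z, specs, seed = 8)
  r0 <- cor(z[cat_tab$probe_id[cat_tab$trait == "null_trait"]],
            cat_tab$effect[cat_tab$trait == "null_trait"])
  expect_lt(abs(r0), 2 / sqrt(150))  # ~95% null band
  sub <- cat_tab[cat_tab$trait == "cor_trait", ]
  r1 <- cor(z[sub$probe_id], sub$effect)
  ci <- tanh(atanh(0.4) + c(-1.96, 1.96) / sqrt(200 - 3))
  expect_gt(r1, ci[1]); expect_lt(r1, ci[2])
  expect_true(all(cat_tab$below_threshold[cat_tab$trait == "tiny"]))
  expect_error(generate_external_catalog(z[1:10],
    data.frame(trait = "x", n_probes = 11, target_r = 0)), "available")
})

test_that("null probes reject at the nominal Levene rate", {
  # property: at alpha = 0.05, rejection rate over >= 2000 null probes stays
  # inside the binomial 99% band
  cfg <- sim_config(n_cohorts = 1, n_cases = 200, n_controls = 200,
                    n_probes = 2000, fraction_vmp_up = 0, fraction_vmp_down = 0,
                    fraction_dmp = 0, seed = 11)
  co <- generate_cohort(cfg, 1, keep_latent = TRUE)
  case <- co$samplesheet$diagnosis == "case"
  lv <- methvar:::row_levene(co$epsilon, which(case), which(!case))
  rate <- mean(lv$p.value < 0.05)
  band <- 0.05 + c(-1, 1) * 2.58 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(rate, band[1]); expect_lt(rate, band[2])
})
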