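test_that("paired comparison handles symmetric, identical and zero cases", {
  ## diffs (1, -1, 2, -2, 0): mean 0, t = 0, p = 1, d = 0
  base <- c(10, 10, 10, 10, 10)
  res <- pairedCompare(base, base + c(1, -1, 2, -2, 0))
  expect_equal(res$diff, 0)
  expect_equal(res$p, 1)
  expect_equal(res$cohens_d, 0)
  ## identical vectors
  res2 <- pairedCompare(base, base)
  expect_equal(res2$cohens_d, 0)
  expect_equal(res2$pct_change, 0)
  expect_equal(res2$p, 1)
  ## zero baseline excluded from percent change with warning
  expect_warning(res3 <- pairedCompare(c(0, 10, 10, 10), c(1, 11, 11, 11)),
                 "baseline 0")
  expect_equal(res3$pct_change, 10)
  expect_error(pairedCompare(1:2, 2:3), "3 complete pairs")
})

test_that("CI brackets the mean difference and the normality gate switches tests", {
  set.seed(77)
  base <- rnorm(22, 100, 10)
  res <- pairedCompare(base, base + rnorm(22, 1, 2))
  expect_equal(res$test, "paired-t")
  expect_lte(res$ci_lo, res$diff); expect_gte(res$ci_hi, res$diff)
  ## strongly skewed differences trigger Wilcoxon
  d <- rexp(30)^3
  res2 <- pairedCompare(rep(1, 30), 1 + d)
  expect_equal(res2$test, "wilcoxon")
})

test_that("paired t rejection rate matches noncentral-t power (MC vs closed form)", {
  set.seed(123)
  B <- 2000; n <- 22; alpha <- 0.025
  rejNull <- rejAlt <- 0L
  for (b in seq_len(B)) {
    base <- rnorm(n, 100, 1)
    rejNull <- rejNull + (pairedCompare(base, base + rnorm(n))$p < alpha)
    rejAlt <- rejAlt + (pairedCompare(base, base + rnorm(n, 0.7))$p < alpha)
  }
  seN <- sqrt(alpha * (1 - alpha) / B)
  expect_lt(abs(rejNull / B - alpha), 3 * seN)
  pw <- pairedTPower(n, 0.7, alpha)
  seP <- sqrt(pw * (1 - pw) / B)
  expect_lt(abs(rejAlt / B - pw), 3 * seP)
})

test_that("mixed model recovers an exactly injected change in the degenerate fit", {
  base <- phantomSpec(n_frames = 6, noise_sd = 0, psf_sigma = 0)
  cs <- cohortSpec(n_subjects = 5, condition_effects = c(1, 0.9, 0.9, 0.9),
                   between_subject_sd = 0, seed = 2)
  tab <- makeCohort(cs, base, images = FALSE)$truth
  res <- suppressWarnings(fitLmm(tab, "ap_mean", plane = "NP"))
  injected <- -0.1 * 2 * base$ap_semiaxis *
    mean(aircine:::phantomModulation(base))
  expect_equal(res$lsm$estimate, rep(injected, 3), tolerance = 1e-8)
})

test_that("mixed model LSM CIs achieve nominal coverage on null cohorts", {
  base <- phantomSpec(n_frames = 4, noise_sd = 0, psf_sigma = 0)
  covered <- 0L; total <- 0L
  for (b in 1:200) {
    cs <- cohortSpec(n_subjects = 22, seed = 3000 + b)
    tab <- makeCohort(cs, base, images = FALSE, measurement_cv = 0.05)$truth
    res <- suppressWarnings(
      suppressMessages(fitLmm(tab, "area_mean", plane = "NP")))
    covered <- covered + sum(res$lsm$ci_lo <= 0 & res$lsm$ci_hi >= 0)
    total <- total + nrow(res$lsm)
  }
  ## binomial tolerance around nominal 95% (CIs within a model are correlated,
  ## so use the conservative >= 90% bound)
  expect_gte(covered / total, 0.90)
})

test_that("mixed model recovers the sign of a -10% condition effect", {
  base <- phantomSpec(n_frames = 4, noise_sd = 0, psf_sigma = 0)
  hits <- 0L
  for (b in 1:200) {
    cs <- cohortSpec(n_subjects = 22,
                     condition_effects = c(1, 0.9, 0.9, 0.9),
                     seed = 6000 + b)
    tab <- makeCohort(cs, base, images = FALSE, measurement_cv = 0.05)$truth
    res <- suppressWarnings(
      suppressMessages(fitLmm(tab, "ap_mean", plane = "NP")))
    if (all(res$lsm$estimate < 0)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("mixed model estimates a -10% effect on a 10 mm baseline near -1 mm", {
  ## direct construction: diameter 10 mm at baseline, 9 mm at follow-ups,
  ## subject offsets and mild noise
  set.seed(55)
  est <- replicate(20, {
    n <- 22
    subj <- sprintf("S%02d", 1:n)
    off <- rnorm(n, 0, 0.5); age <- runif(n, 1, 13)
    rows <- do.call(rbind, lapply(1:n, function(i) {
      base10 <- 10 + off[i]
      data.frame(subject = subj[i], plane = "NP",
                 condition = c("00", "5", "10", "15"),
                 measure = "ap_mean",
                 value = c(base10, rep(base10 * 0.9, 3)) + rnorm(4, 0, 0.2),
                 age = age[i])
    }))
    r <- suppressWarnings(suppressMessages(fitLmm(rows, "ap_mean", "NP")))
    mean(r$lsm$estimate)
  })
  expect_lt(abs(mean(est) - (-1)), 0.1)   # bias < 10% of the effect
})

test_that("multiplicity adjustment is monotone, dominated and edge-safe", {
  expect_identical(multiplicityAdjust(numeric()), numeric())
  expect_equal(multiplicityAdjust(0.01), 0.01)
  expect_equal(multiplicityAdjust(rep(0.0184, 24))[1], 0.4416)
  set.seed(9)
  for (i in 1:100) {
    p <- runif(sample(2:30, 1))
    bf <- multiplicityAdjust(p, "bonferroni")
    hm <- multiplicityAdjust(p, "holm")
    expect_true(all(bf >= p) && all(hm >= p))
    expect_true(all(hm <= bf + 1e-12))
    ## monotone: order of adjusted follows order of raw
    expect_true(all(diff(bf[order(p)]) >= -1e-12))
    expect_true(all(diff(hm[order(p)]) >= -1e-12))
  }
})

test_that("Dunnett comparison: identical groups, single-comparison limit", {
  base <- c(5, 7, 9, 11, 6, 8)
  res <- dunnettCompare(base, cbind(a = base, b = base, c = base))
  expect_equal(res$p_adj, rep(1, 3))
  ## k = 1 reduces to the unadjusted paired t-test
  set.seed(14)
  fu <- base + rnorm(6)
  r1 <- dunnettCompare(base, fu)
  tt <- t.test(fu - base)
  expect_equal(r1$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(r1$p_raw, tt$p.value, tolerance = 1e-10)
  expect_error(dunnettCompare(base, matrix(nrow = 6, ncol = 0)), "no time levels")
})

test_that("Dunnett adjusted p-values agree with multcomp's implementation", {
  skip_if_not_installed("multcomp")
  set.seed(21)
  n <- 16
  base <- rnorm(n, 50, 6)
  fu <- cbind(t5 = base + rnorm(n, 1, 4), t10 = base + rnorm(n, -1, 4),
              t15 = base + rnorm(n, 0, 4))
  mine <- dunnettCompare(base, fu)
  ## independent route: within-subject differences as a parameter block,
  ## single-step max-|t| adjustment via multcomp
  D <- fu - base
  gl <- multcomp::glht(multcomp::parm(colMeans(D), cov(D) / n, df = n - 1),
                       linfct = diag(3))
  ref <- summary(gl, test = multcomp::adjusted("single-step"))
  expect_equal(mine$p_adj, as.numeric(ref$test$pvalues), tolerance = 5e-3)
})

test_that("Dunnett family-wise error is controlled at ~0.05 under the null", {
  set.seed(31)
  B <- 1000; fwe <- 0L
  for (b in seq_len(B)) {
    base <- rnorm(22); fu <- matrix(rnorm(22 * 3), 22, 3)
    fwe <- fwe + any(dunnettCompare(base, fu)$p_adj < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / B)
  expect_lt(abs(fwe / B - 0.05), 3 * se)
})

test_that("cohort-level tables assemble with adjusted p >= raw", {
  base <- phantomSpec(n_frames = 4, noise_sd = 0, psf_sigma = 0)
  tab <- makeCohort(cohortSpec(n_subjects = 8, seed = 17), base,
                    images = FALSE, measurement_cv = 0.05)$truth
  paired <- cohortCompare(tab)
  expect_equal(nrow(paired), 18)   # 2 planes x 9 measures
  expect_true(all(paired$p_adj >= paired$p_raw - 1e-12))
  expect_true(all(c("diff", "ci_lo", "ci_hi", "pct_change", "cohens_d",
                    "test", "p_raw", "p_adj") %in% names(paired)))
  lmm <- suppressWarnings(suppressMessages(cohortLmm(tab)))
  expect_equal(nrow(lmm), 18 * 3)  # 3 time levels each
  expect_true(all(lmm$p_adj >= lmm$p_raw - 1e-12))
})
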