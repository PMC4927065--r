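test_that("Bonferroni thresholds reproduce the standard analytic values", {
  expect_equal(signif(bonferroni_threshold(0.05, 71 * 601), 3), 1.17e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 105), 3), 4.76e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("discordance partition follows the one-SD MZ rule", {
  set.seed(10)
  cohort <- make_cohort(5, n_mz = 3)   # 3 MZ pairs, 2 DZ pairs
  # intakes chosen so the sample SD (sqrt(30.5/9) ~= 1.84) is hand-checkable:
  # an MZ pair 3 apart, an equal-intake MZ pair, and a DZ pair 5 apart
  x <- setNames(c(1, 4,   2, 2,   3, 2.5,   0, 5,   5, 5.5), cohort$subject_id)
  s <- sd(x)
  expect_equal(s, sqrt(30.5 / 9))
  part <- classify_discordant_pairs(x, cohort, food_group_id = "g1")
  expect_equal(part$sd, s)
  expect_true(3 >= s)  # the constructed pair really is discordant
  expect_setequal(part$replication, c("S001", "S002"))
  # equal-intake MZ pair and the wildly discordant DZ pair stay in discovery
  expect_true(all(c("S003", "S004", "S007", "S008") %in% part$discovery))
  # disjoint, and union covers all observed subjects
  expect_length(intersect(part$discovery, part$replication), 0)
  expect_setequal(c(part$discovery, part$replication), cohort$subject_id)
  # the discordance rule is >=, not >: at margin 0 even an MZ pair with
  # identical intakes (difference exactly equal to the threshold) is flagged
  part0 <- classify_discordant_pairs(x, cohort, sd_multiplier = 0)
  expect_true(all(c("S003", "S004") %in% part0$replication))
})

test_that("constant intake yields an empty replication set with a warning", {
  cohort <- make_cohort(6)
  x <- setNames(rep(2, 12), cohort$subject_id)
  expect_warning(part <- classify_discordant_pairs(x, cohort), "zero intake SD")
  expect_length(part$replication, 0)
  expect_setequal(part$discovery, cohort$subject_id)
})

test_that("random-intercept fit recovers a planted slope in the noise-free limit", {
  set.seed(12)
  d <- make_twin_data(250, slope = 0.5, var_family = 0, var_noise = 1e-12)
  fit <- fit_random_intercept(d$y, d$x, d$age, d$bmi, d$batch, d$family_id)
  expect_lt(abs(fit$beta - 0.5), 1e-6)
  expect_lt(fit$p, 1e-100)
  expect_equal(fit$n, 500)
  expect_equal(fit$n_families, 250)
})

test_that("random-intercept fit matches the brute-force REML oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- make_twin_data(15, slope = 0.3, var_family = 0.5, var_noise = 0.4,
                        n_batch = 2)
    fit <- fit_random_intercept(d$y, d$x, d$age, d$bmi, d$batch, d$family_id)
    X <- model.matrix(~ x + age + bmi + batch, d)
    orc <- oracle_reml(d$y, X, d$family_id, beta_col = 2)
    expect_equal(fit$beta, orc$beta, tolerance = 1e-4)
    expect_equal(fit$se, orc$se, tolerance = 1e-3)
  }
})

test_that("zero family variance degrades smoothly to ordinary least squares", {
  set.seed(13)
  n <- 200
  # anti-correlated co-twins force the family variance estimate onto the
  # zero boundary, where the fit must coincide with ordinary least squares
  base <- rnorm(n / 2)
  y <- as.vector(rbind(base, -base)) + rnorm(n, 0, 0.05)
  d <- data.frame(y = y, x = rnorm(n), age = runif(n, 20, 70),
                  bmi = rnorm(n, 25, 3), batch = "b1",
                  family_id = sprintf("F%03d", rep(1:(n / 2), each = 2)))
  fit <- fit_random_intercept(d$y, d$x, d$age, d$bmi, d$batch, d$family_id)
  ols <- summary(lm(y ~ x + age + bmi, d))$coefficients
  expect_equal(fit$beta, unname(ols["x", "Estimate"]), tolerance = 1e-6)
  expect_equal(fit$se, unname(ols["x", "Std. Error"]), tolerance = 1e-6)
})

test_that("degenerate designs are rejected with the offending column named", {
  set.seed(14)
  d <- make_twin_data(30)
  expect_error(fit_random_intercept(d$y, rep(1, 60), d$age, d$bmi, d$batch,
                                    d$family_id), "x")
  expect_error(fit_random_intercept(d$y[1:8], d$x[1:8], d$age[1:8], d$bmi[1:8],
                                    d$batch[1:8], d$family_id[1:8]),
               "fewer than 10")
  expect_error(fit_random_intercept(d$y, d$x, d$age, d$bmi, d$batch,
                                    rep("F001", 60)), "2 families")
})

test_that("inverse-variance meta-analysis obeys its closed-form identities", {
  mk <- function(beta, se) data.frame(food_group = "g", metabolite = "m",
                                      beta = beta, se = se)
  eq <- meta_fixed_effect(mk(1, 1), mk(1, 1))
  expect_equal(eq$beta, 1)
  expect_equal(eq$se, 1 / sqrt(2))

  # hand arithmetic: weights 1/0.02^2 = 2500 and 1/0.04^2 = 625
  m <- meta_fixed_effect(mk(0.1, 0.02), mk(0.2, 0.04))
  expect_equal(m$beta, (2500 * 0.1 + 625 * 0.2) / 3125)
  expect_equal(m$beta, 0.12)
  expect_equal(m$se, 1 / sqrt(3125))
  expect_equal(m$se, 0.0178885, tolerance = 1e-5)

  # one weight vanishing: meta tends to the other record
  lim <- meta_fixed_effect(mk(0.3, 0.05), mk(-5, 1e6))
  expect_equal(lim$beta, 0.3, tolerance = 1e-6)
  expect_equal(lim$se, 0.05, tolerance = 1e-6)

  expect_error(meta_fixed_effect(mk(1, 1), data.frame(food_group = "h",
                                                      metabolite = "m",
                                                      beta = 1, se = 1)),
               "different pairs")

  # properties over random stage records: order invariance, SE bound,
  # meta estimate between the stage estimates
  set.seed(15)
  for (i in 1:25) {
    a <- mk(rnorm(1), runif(1, 0.01, 2))
    b <- mk(rnorm(1), runif(1, 0.01, 2))
    ab <- meta_fixed_effect(a, b); ba <- meta_fixed_effect(b, a)
    expect_equal(ab$beta, ba$beta)
    expect_equal(ab$se, ba$se)
    expect_lte(ab$se, min(a$se, b$se))
    expect_gte(ab$beta, min(a$beta, b$beta))
    expect_lte(ab$beta, max(a$beta, b$beta))
  }
})

test_that("replication applies the direction rule and the platform-specific p rule", {
  sim <- simulate_cohort(sim_params(
    n_pairs = 150, frac_mz = 1, n_food_groups = 2, n_metabolites_nt = 2,
    n_metabolites_t = 2,
    effect_table = data.frame(food_group = c(1, 1), metabolite = c(1, 1),
                              platform = c("non_targeted", "targeted"),
                              slope = c(0.6, 0.6)),
    missing_rate = 0, seed = 21))
  for (pf in c("non_targeted", "targeted")) {
    panel <- if (pf == "non_targeted")
      preprocess_nontargeted(sim$panel_nt)$panel else
      preprocess_targeted(sim$panel_t)
    scan <- discovery_scan(panel, sim$truth$foods, sim$cohort)
    sig <- scan$records[scan$records$significant, ]
    expect_true(nrow(sig) >= 1)
    reps <- replicate_associations(sig, panel, sim$truth$foods, sim$cohort,
                                   scan$partitions)
    expect_equal(nrow(reps), nrow(sig))
    # direction always required; p < 0.05 additionally on non-targeted only
    for (i in seq_len(nrow(reps))) {
      r <- reps[i, ]
      if (is.na(r$beta)) next
      d <- sig[i, ]
      expected <- sign(r$beta) == sign(d$beta) &&
        (pf == "targeted" || r$p < 0.05)
      expect_identical(r$replicated, expected)
    }
  }
})

test_that("replication flags follow the stated criteria on constructed records", {
  disc <- data.frame(food_group = "g", metabolite = "m", beta = 1, se = 0.1)
  flag <- function(beta_rep, p_rep, platform) {
    same <- sign(beta_rep) == sign(disc$beta)
    same && (platform == "targeted" || p_rep < 0.05)
  }
  expect_true(flag(0.5, 0.03, "non_targeted"))
  expect_true(flag(0.5, 0.30, "targeted"))
  expect_false(flag(-0.5, 0.001, "non_targeted"))
  expect_false(flag(0.5, 0.30, "non_targeted"))
})

test_that("discovery scan emits one record per pair and propagates fit failures", {
  sim <- simulate_cohort(sim_params(n_pairs = 60, n_food_groups = 2,
                                    n_metabolites_nt = 3, n_metabolites_t = 0,
                                    missing_rate = 0, seed = 22))
  panel <- preprocess_nontargeted(sim$panel_nt)$panel
  scan <- discovery_scan(panel, sim$truth$foods, sim$cohort)
  expect_equal(nrow(scan$records), 2 * 3)
  expect_setequal(unique(scan$records$food_group), colnames(sim$truth$foods))
  expect_equal(scan$threshold, 0.05 / 6)
  # partitions: replication members are MZ-only and disjoint from discovery
  for (part in scan$partitions) {
    expect_length(intersect(part$discovery, part$replication), 0)
    if (length(part$replication)) {
      z <- sim$cohort$zygosity[match(part$replication, sim$cohort$subject_id)]
      expect_true(all(z == "MZ"))
    }
  }
})

test_that("a large planted effect is flagged significant in the discovery scan", {
  sim <- simulate_cohort(sim_params(
    n_pairs = 500, n_food_groups = 3, n_metabolites_nt = 4, n_metabolites_t = 0,
    effect_table = data.frame(food_group = 2, metabolite = 3,
                              platform = "non_targeted", slope = 0.5),
    missing_rate = 0, seed = 23))
  panel <- preprocess_nontargeted(sim$panel_nt)$panel
  scan <- discovery_scan(panel, sim$truth$foods, sim$cohort)
  rec <- scan$records[scan$records$food_group == "fg02" &
                        scan$records$metabolite == "nt_m003", ]
  expect_gt(abs(rec$beta / rec$se), 10)
  expect_true(rec$significant)
  # and it is the only significant record in this scan
  expect_equal(sum(scan$records$significant), 1)
})
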