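test_that("run-day median normalization divides by the per-day metabolite median", {
  p1 <- make_panel(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(unname(run_day_median_normalize(p1)$values[, 1]),
               c(0.5, 1.0, 1.5))

  p2 <- make_panel(matrix(c(1, 3, 10, 30), ncol = 1),
                   run_day = c("d1", "d1", "d2", "d2"))
  expect_equal(unname(run_day_median_normalize(p2)$values[, 1]),
               c(1 / 2, 3 / 2, 10 / 20, 30 / 20))

  p3 <- make_panel(matrix(7, 5, 2))
  expect_true(all(run_day_median_normalize(p3)$values == 1))

  # per-(metabolite, run day) median of the output is 1 wherever observed
  set.seed(4)
  v <- matrix(exp(rnorm(60)), 20, 3)
  v[sample(60, 8)] <- NA
  p4 <- run_day_median_normalize(make_panel(v, run_day = rep_len(c("a", "b"), 20)))
  for (d in c("a", "b"))
    expect_equal(unname(apply(p4$values[p4$run_day == d, ], 2, median, na.rm = TRUE)),
                 rep(1, 3))

  expect_error(run_day_median_normalize(make_panel(matrix(1:4, 2), platform = "targeted")),
               "non_targeted")
  # a fully missing (metabolite, day) cell group stays missing with a warning
  v5 <- matrix(c(NA, NA, 5, 6), 2, 2)
  expect_warning(out <- run_day_median_normalize(make_panel(v5)), "all values missing")
  expect_true(all(is.na(out$values[, 1])))
})

test_that("missingness filter removes strictly above the threshold only", {
  v <- matrix(rnorm(300), 100, 3)
  v[1:21, 1] <- NA   # 21% -> excluded
  v[1:20, 2] <- NA   # exactly 20% -> retained
  flt <- filter_missingness(make_panel(v))
  expect_identical(flt$excluded, "m001")
  expect_identical(colnames(flt$panel$values), c("m002", "m003"))

  full <- filter_missingness(make_panel(matrix(rnorm(50), 10, 5)))
  expect_length(full$excluded, 0)
  expect_equal(ncol(full$panel$values), 5)
})

test_that("imputation fills missing cells with the run-day minimum", {
  p <- make_panel(matrix(c(NA, 5, 2), ncol = 1), steps = "filter_missingness")
  expect_equal(unname(impute_run_day_minimum(p)$values[, 1]), c(2, 5, 2))

  # whole run day missing: global per-metabolite minimum is the fallback
  p2 <- make_panel(matrix(c(NA, 4, 8), ncol = 1),
                   run_day = c("d1", "d2", "d2"), steps = "filter_missingness")
  expect_equal(unname(impute_run_day_minimum(p2)$values[, 1]), c(4, 4, 8))

  p3 <- make_panel(matrix(1:6, 3, 2), steps = "filter_missingness")
  expect_equal(impute_run_day_minimum(p3)$values, p3$values)

  p4 <- make_panel(matrix(NA_real_, 3, 1), steps = "filter_missingness")
  expect_error(impute_run_day_minimum(p4), "filtered")
})

test_that("filter then impute leaves no missing cells and preserves counts", {
  set.seed(8)
  v <- matrix(exp(rnorm(400)), 40, 10)
  v[sample(400, 60)] <- NA
  flt <- filter_missingness(make_panel(v, run_day = rep_len(c("a", "b"), 40)))
  imp <- impute_run_day_minimum(flt$panel)
  expect_false(anyNA(imp$values))
  expect_equal(ncol(imp$values) + length(flt$excluded), 10)
})

test_that("inverse normal transform matches Blom scores from an independent quantile", {
  skip_if_not_installed("pracma")
  x <- c(5, 1, 9)
  got <- inverse_normal_transform(x)
  expect_equal(got, oracle_blom(x), tolerance = 1e-10)
  expect_equal(round(got, 4), c(0, -0.8694, 0.8694))

  set.seed(2)
  z <- rnorm(25)
  expect_equal(inverse_normal_transform(z), oracle_blom(z), tolerance = 1e-10)
})

test_that("inverse normal transform is a rank statistic", {
  set.seed(3)
  x <- rnorm(51)
  out <- inverse_normal_transform(x)
  # median element of an odd-length tie-free vector maps to 0
  expect_equal(out[which(x == median(x))], 0)
  expect_lt(abs(mean(out)), 1e-6)
  # invariant under strictly monotone transforms of the input
  expect_equal(out, inverse_normal_transform(exp(2 * x)))
  expect_equal(inverse_normal_transform(rank(x)), out)
  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
})

test_that("targeted log transform is elementwise natural log and rejects non-positives", {
  p <- make_panel(matrix(c(1, exp(1), exp(2)), ncol = 1), platform = "targeted")
  expect_equal(unname(log_transform_targeted(p)$values[, 1]), c(0, 1, 2))
  p0 <- make_panel(matrix(c(1, 0, 2), ncol = 1), platform = "targeted")
  expect_error(log_transform_targeted(p0), "non-positive concentration")
})

test_that("platform-overlap removal matches the expected retained count and is idempotent", {
  v <- matrix(exp(rnorm(5 * 163)), 5, 163,
              dimnames = list(sprintf("S%d", 1:5), sprintf("t_m%03d", 1:163)))
  panel <- metabolite_panel(v, rep("d1", 5), "targeted")
  overlap <- sprintf("t_m%03d", 1:18)
  out <- drop_overlapping(panel, overlap)
  expect_equal(ncol(out$values), 145)
  out2 <- suppressWarnings(drop_overlapping(out, overlap))
  expect_identical(out2$values, out$values)
  expect_identical(drop_overlapping(panel, character())$values, panel$values)
  expect_warning(drop_overlapping(panel, "not_a_metabolite"), "not_a_metabolite")
})

test_that("out-of-order preprocessing chains are rejected via the recorded state", {
  raw <- make_panel(matrix(rnorm(20, 10), 10, 2))
  expect_error(impute_run_day_minimum(raw), "filter_missingness")
  expect_error(inverse_normalize_panel(raw), "filter_missingness")
  norm <- run_day_median_normalize(raw)
  expect_error(run_day_median_normalize(norm), "median_normalize")
  flt <- filter_missingness(norm)$panel
  expect_error(run_day_median_normalize(flt), "cannot be applied after")
  imp <- impute_run_day_minimum(flt)
  int <- inverse_normalize_panel(imp)
  expect_identical(int$steps, c("median_normalize", "filter_missingness",
                                "impute_run_day_minimum", "inverse_normal"))
  expect_error(inverse_normalize_panel(int), "inverse_normal")
  tgt <- log_transform_targeted(make_panel(matrix(1:4 + 0.5, 2), platform = "targeted"))
  expect_error(log_transform_targeted(tgt), "log_transform")
})
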