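# Small constructors shared across test files.

make_panel <- function(values, run_day = rep("day01", nrow(values)),
                       platform = "non_targeted", steps = character()) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("m%03d", seq_len(ncol(values)))
  metabolite_panel(values, run_day, platform, steps = steps)
}

# Minimal cohort of twin pairs: 2*n_pairs subjects, first frac_mz MZ.
make_cohort <- function(n_pairs, n_mz = n_pairs) {
  n <- 2 * n_pairs
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    family_id = sprintf("F%03d", rep(seq_len(n_pairs), each = 2)),
    zygosity = rep(c(rep("MZ", n_mz), rep("DZ", n_pairs - n_mz)), each = 2),
    age = rep(runif(n_pairs, 20, 70), each = 2),
    bmi = rnorm(n, 25, 3),
    stringsAsFactors = FALSE)
}

# Twin-structured regression data with known variance components, used by
# the mixed-model tests. Returns the frame plus the generating values.
make_twin_data <- function(n_pairs, slope = 0.1, var_family = 0.3,
                           var_noise = 0.5, n_batch = 3) {
  n <- 2 * n_pairs
  fam <- rep(seq_len(n_pairs), each = 2)
  x <- rnorm(n, 0, 2)
  age <- rep(runif(n_pairs, 20, 70), each = 2)
  bmi <- rnorm(n, 25, 3)
  batch <- rep_len(sprintf("b%d", seq_len(n_batch)), n)
  y <- 0.2 + slope * x + 0.005 * age + 0.01 * bmi +
    rep(rnorm(n_pairs, 0, sqrt(var_family)), each = 2) +
    rnorm(n, 0, sqrt(var_noise))
  data.frame(y, x, age, bmi, batch, family_id = sprintf("F%03d", fam),
             stringsAsFactors = FALSE)
}
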