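#' Simulation parameters for a synthetic twin cohort
#'
#' Bundles and validates the parameters of [simulate_cohort()]. Defaults
#' describe a desk-scale female twin cohort with the statistical structure
#' the association pipeline assumes: family clustering with extra sharing in
#' MZ pairs, age/BMI confounding, multiplicative run-day batch shifts on the
#' non-targeted platform, intensity-dependent (left-censored-like)
#' missingness, and right-skewed targeted concentrations.
#'
#' @param n_pairs number of twin pairs.
#' @param frac_mz fraction of pairs that are monozygotic, in [0,1].
#' @param n_food_groups number of food groups (each built from 2 FFQ items).
#' @param n_metabolites_nt,n_metabolites_t metabolite counts on the
#'   non-targeted and targeted platforms.
#' @param n_run_days number of acquisition days (round-robin assignment).
#' @param effect_table data frame of planted diet effects with columns
#'   `food_group` (index), `metabolite` (index within its platform),
#'   `platform` ("non_targeted"/"targeted"), `slope` (metabolite units per
#'   serving/week on the generator's latent linear scale).
#' @param var_family family random-intercept variance (shared by co-twins).
#' @param var_pair_mz_extra additional variance shared only within MZ pairs.
#' @param var_noise residual variance, > 0.
#' @param age_range min/max age in years (uniform pair-level draw).
#' @param bmi_mean_sd mean and SD of BMI (kg/m^2); co-twins vary around a
#'   shared pair mean.
#' @param gamma_age,delta_bmi confounder slopes of age and BMI on every
#'   metabolite.
#' @param missing_rate expected missing fraction per non-targeted
#'   metabolite, in [0,1).
#' @param batch_shift_sd SD of the log multiplicative run-day factor.
#' @param n_snps number of simulated SNPs (additive dosages).
#' @param snp_effect_table data frame of planted genotype effects on diet
#'   with columns `snp` (index), `food_group` (index), `shift` (added to the
#'   latent consumption propensity per allele).
#' @param seed integer seed; identical parameters give bit-identical cohorts.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 500, frac_mz = 0.5, n_food_groups = 10,
                       n_metabolites_nt = 20, n_metabolites_t = 10,
                       n_run_days = 5, effect_table = NULL,
                       var_family = 0.3, var_pair_mz_extra = 0.2,
                       var_noise = 0.5, age_range = c(18, 79),
                       bmi_mean_sd = c(25, 4), gamma_age = 0.005,
                       delta_bmi = 0.01, missing_rate = 0.05,
                       batch_shift_sd = 0.1, n_snps = 0,
                       snp_effect_table = NULL, seed = 1L) {
  if (is.null(effect_table))
    effect_table <- data.frame(food_group = integer(), metabolite = integer(),
                               platform = character(), slope = numeric())
  if (is.null(snp_effect_table))
    snp_effect_table <- data.frame(snp = integer(), food_group = integer(),
                                   shift = numeric())
  p <- structure(as.list(environment()), class = "sim_params")
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(p$n_pairs >= 1, p$frac_mz >= 0, p$frac_mz <= 1,
            p$n_food_groups >= 1, p$n_metabolites_nt >= 0,
            p$n_metabolites_t >= 0, p$n_run_days >= 1,
            p$var_family >= 0, p$var_pair_mz_extra >= 0, p$var_noise > 0,
            p$missing_rate >= 0, p$missing_rate < 1, p$batch_shift_sd >= 0,
            p$n_snps >= 0)
  et <- p$effect_table
  for (i in seq_len(nrow(et))) {
    n_m <- if (et$platform[i] == "non_targeted") p$n_metabolites_nt else p$n_metabolites_t
    if (et$food_group[i] < 1 || et$food_group[i] > p$n_food_groups ||
        et$metabolite[i] < 1 || et$metabolite[i] > n_m)
      stop(sprintf(
        "effect_table row %d out of range: food_group %d, metabolite %d (%s)",
        i, et$food_group[i], et$metabolite[i], et$platform[i]))
  }
  st <- p$snp_effect_table
  for (i in seq_len(nrow(st))) {
    if (st$snp[i] < 1 || st$snp[i] > p$n_snps ||
        st$food_group[i] < 1 || st$food_group[i] > p$n_food_groups)
      stop(sprintf("snp_effect_table row %d out of range: snp %d, food_group %d",
                   i, st$snp[i], st$food_group[i]))
  }
  invisible(p)
}

# Latent-consumption category probabilities for the 9-point frequency scale:
# right-skewed, most items consumed rarely, as in semi-quantitative FFQs.
ffq_category_probs <- c(0.30, 0.20, 0.15, 0.12, 0.08, 0.06, 0.04, 0.03, 0.02)

#' Simulate a twin cohort with planted diet-metabolite effects
#'
#' Generates a cohort table, an FFQ table, non-targeted and targeted
#' metabolite panels, a genotype table and the ground truth used to build
#' them. Metabolites follow the model the pipeline fits: a linear
#' combination of the energy-adjusted food-group intakes (planted slopes),
#' age and BMI confounding, a family random intercept with extra MZ-shared
#' variance, and Gaussian noise; the non-targeted panel is then scaled by a
#' per-(run day, metabolite) multiplicative batch factor and thinned with
#' intensity-dependent missingness, and the targeted panel is exponentiated
#' so concentrations are right-skewed.
#'
#' @param params a [sim_params()] object.
#' @return List with elements `cohort`, `ffq`, `food_map`, `panel_nt`,
#'   `panel_t`, `genotypes` (subjects x SNPs dosage matrix, or NULL),
#'   `snp_food_map`, and `truth` (a `sim_truth` list holding the planted
#'   effect table, the realized family effects, the variance components, and
#'   the energy-adjusted food-group matrix the effects act on).
#' @export
simulate_cohort <- function(params) {
  validate_sim_params(params)
  p <- params
  set.seed(p$seed)

  n_mz <- round(p$frac_mz * p$n_pairs)
  n <- 2L * p$n_pairs
  pair_id <- rep(seq_len(p$n_pairs), each = 2)
  zygosity <- rep(c(rep("MZ", n_mz), rep("DZ", p$n_pairs - n_mz)), each = 2)
  subject_id <- sprintf("S%04d", seq_len(n))
  family_id <- sprintf("F%04d", pair_id)

  age_pair <- runif(p$n_pairs, p$age_range[1], p$age_range[2])
  age <- rep(age_pair, each = 2)              # twins share age exactly
  bmi_pair <- rnorm(p$n_pairs, p$bmi_mean_sd[1], p$bmi_mean_sd[2] / sqrt(2))
  bmi <- rep(bmi_pair, each = 2) + rnorm(n, 0, p$bmi_mean_sd[2] / sqrt(2))

  cohort <- data.frame(subject_id, family_id, zygosity, age, bmi,
                       stringsAsFactors = FALSE)

  # Genotypes: HWE with MAF ~ U(0.1, 0.5); MZ co-twins identical, DZ
  # co-twins share one transmitted allele (correlation 1/2).
  genotypes <- NULL
  snp_food_map <- NULL
  if (p$n_snps > 0) {
    maf <- runif(p$n_snps, 0.1, 0.5)
    genotypes <- matrix(0L, n, p$n_snps,
                        dimnames = list(subject_id, sprintf("snp%03d", seq_len(p$n_snps))))
    for (s in seq_len(p$n_snps)) {
      a_shared <- rbinom(p$n_pairs, 1, maf[s])
      a1 <- rbinom(p$n_pairs, 1, maf[s])
      a2 <- rbinom(p$n_pairs, 1, maf[s])
      mz <- zygosity[seq(1, n, 2)] == "MZ"
      d1 <- a_shared + a1
      d2 <- ifelse(mz, a_shared + a1, a_shared + a2)
      genotypes[seq(1, n, 2), s] <- d1
      genotypes[seq(2, n, 2), s] <- d2
    }
    snp_food_map <- data.frame(
      snp = colnames(genotypes),
      food_group = sprintf("fg%02d", ((seq_len(p$n_snps) - 1) %% p$n_food_groups) + 1),
      stringsAsFactors = FALSE)
  }

  # FFQ: two items per food group; each item's frequency code comes from a
  # latent consumption propensity (pair-correlated, plus any planted
  # genotype shift) cut at fixed right-skewed category breaks.
  n_items <- 2L * p$n_food_groups
  item_ids <- sprintf("item%03d", seq_len(n_items))
  food_map <- data.frame(item = item_ids,
                         food_group = sprintf("fg%02d", rep(seq_len(p$n_food_groups), each = 2)),
                         stringsAsFactors = FALSE)
  breaks <- qnorm(cumsum(ffq_category_probs))[1:8]
  ffq <- data.frame(subject_id, stringsAsFactors = FALSE)
  for (it in seq_len(n_items)) {
    g <- ((it - 1) %/% 2) + 1
    z_pair <- rnorm(p$n_pairs)                       # shared taste within pair
    z <- sqrt(0.5) * rep(z_pair, each = 2) + sqrt(0.5) * rnorm(n)
    st <- p$snp_effect_table
    for (k in seq_len(nrow(st))) {
      if (st$food_group[k] == g && !is.null(genotypes))
        z <- z + st$shift[k] * genotypes[, st$snp[k]]
    }
    ffq[[item_ids[it]]] <- as.integer(findInterval(z, breaks) + 1L)
  }
  servings <- frequency_to_servings(ffq, default_frequency_scale())
  # energy tracks overall consumption only moderately (FFQ-derived energy
  # is noisy), so residual adjustment does not tie food groups together
  total_servings <- rowSums(as.matrix(servings[, -1]))
  energy <- pmax(800, 1500 + 5 * total_servings + rnorm(n, 0, 300))
  ffq$energy_kcal <- energy

  # The planted effects act on the same energy-adjusted food-group matrix
  # the pipeline will reconstruct, so slopes are recoverable exactly.
  foods <- build_food_group_matrix(ffq, food_map)

  run_day <- sprintf("day%02d", ((seq_len(n) - 1) %% p$n_run_days) + 1)

  gen_panel <- function(platform, n_metab, baseline) {
    if (n_metab == 0) return(NULL)
    met_ids <- sprintf("%s_m%03d", if (platform == "non_targeted") "nt" else "t",
                       seq_len(n_metab))
    fam_eff <- matrix(rnorm(p$n_pairs * n_metab, 0, sqrt(p$var_family)),
                      p$n_pairs, n_metab)
    mz_eff <- matrix(rnorm(p$n_pairs * n_metab, 0, sqrt(p$var_pair_mz_extra)),
                     p$n_pairs, n_metab)
    mz_eff[zygosity[seq(1, n, 2)] != "MZ", ] <- 0
    latent <- matrix(baseline, n, n_metab) +
      p$gamma_age * age + p$delta_bmi * bmi +
      fam_eff[pair_id, ] + mz_eff[pair_id, ] +
      matrix(rnorm(n * n_metab, 0, sqrt(p$var_noise)), n, n_metab)
    et <- p$effect_table[p$effect_table$platform == platform, , drop = FALSE]
    for (k in seq_len(nrow(et)))
      latent[, et$metabolite[k]] <- latent[, et$metabolite[k]] +
        et$slope[k] * foods[, et$food_group[k]]
    dimnames(latent) <- list(subject_id, met_ids)
    list(latent = latent, fam_eff = fam_eff, mz_eff = mz_eff, ids = met_ids)
  }

  nt <- gen_panel("non_targeted", p$n_metabolites_nt, baseline = 10)
  tg <- gen_panel("targeted", p$n_metabolites_t, baseline = 0.5)

  panel_nt <- NULL
  if (!is.null(nt)) {
    v <- nt$latent
    if (p$batch_shift_sd > 0) {
      days <- unique(run_day)
      shift <- matrix(exp(rnorm(length(days) * ncol(v), 0, p$batch_shift_sd)),
                      length(days), ncol(v), dimnames = list(days, NULL))
      v <- v * shift[run_day, ]
    }
    annotation <- data.frame(metabolite = nt$ids,
                             named = seq_along(nt$ids) <= ceiling(0.7 * length(nt$ids)))
    panel_nt <- metabolite_panel(v, run_day, "non_targeted", annotation = annotation)
    if (p$missing_rate > 0)
      panel_nt <- inject_missingness(panel_nt, p$missing_rate,
                                     seed = p$seed + 104729L)
  }

  panel_t <- NULL
  if (!is.null(tg)) {
    annotation <- data.frame(metabolite = tg$ids, named = TRUE)
    panel_t <- metabolite_panel(exp(tg$latent), run_day, "targeted",
                                annotation = annotation)
  }

  truth <- structure(list(
    effect_table = p$effect_table,
    snp_effect_table = p$snp_effect_table,
    family_effects = list(non_targeted = if (!is.null(nt)) nt$fam_eff + nt$mz_eff,
                          targeted = if (!is.null(tg)) tg$fam_eff + tg$mz_eff),
    variance_components = c(var_family = p$var_family,
                            var_pair_mz_extra = p$var_pair_mz_extra,
                            var_noise = p$var_noise),
    foods = foods,
    latent_nt = if (!is.null(nt)) nt$latent,
    latent_t = if (!is.null(tg)) tg$latent
  ), class = "sim_truth")

  list(cohort = cohort, ffq = ffq, food_map = food_map,
       panel_nt = panel_nt, panel_t = panel_t,
       genotypes = genotypes, snp_food_map = snp_food_map, truth = truth)
}

#' Mask values of a panel at random, preferentially at low intensities
#'
#' Marks cells missing with per-metabolite expected missing fraction `rate`,
#' weighting the probability toward the lowest-intensity tertile so the
#' missingness mimics left censoring near the detection limit. The complete
#' pre-masking values are kept in the `complete_values` attribute for
#' ground-truth checks.
#'
#' @param panel a [metabolite_panel()].
#' @param rate expected missing fraction per metabolite, in [0,1).
#' @param seed integer seed for the masking draw.
#' @return Panel with `NA`s inserted.
#' @export
inject_missingness <- function(panel, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("missing rate must be in [0, 1)")
  if (rate == 0) return(panel)
  set.seed(seed)
  v <- panel$values
  complete <- v
  tert_w <- c(1.8, 0.9, 0.3)  # low/mid/high intensity tertile weights, mean 1
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    q <- quantile(x, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    tert <- findInterval(x, q) + 1L
    pr <- pmin(1, rate * tert_w[tert])
    v[runif(length(x)) < pr, j] <- NA
  }
  panel$values <- v
  attr(panel, "complete_values") <- complete
  panel
}
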