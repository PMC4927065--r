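#' Validate a genotype dosage table against the cohort
#'
#' Dosages must be 0/1/2 (or missing) and MZ co-twins must carry identical
#' dosages at every SNP; a violation is a data error, not a warning.
#'
#' @param genotypes subjects x SNPs matrix of additive dosages (row names
#'   subject ids).
#' @param cohort cohort data frame.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_genotypes <- function(genotypes, cohort) {
  ok <- is.na(genotypes) | genotypes %in% c(0, 1, 2)
  if (!all(ok))
    stop("dosages must be 0, 1, 2 or missing")
  fams <- split(cohort$subject_id, cohort$family_id)
  for (f in fams) {
    if (length(f) != 2) next
    if (cohort$zygosity[match(f[1], cohort$subject_id)] != "MZ") next
    g1 <- genotypes[f[1], ]
    g2 <- genotypes[f[2], ]
    both <- !is.na(g1) & !is.na(g2)
    if (any(g1[both] != g2[both]))
      stop(sprintf("MZ co-twins %s/%s differ in dosage: data error", f[1], f[2]))
  }
  invisible(TRUE)
}

#' Random-intercept regression of food-group intake on genotype
#'
#' Fits `intake = b0 + b dosage + g age + zeta_family + e` by REML, with the
#' additive dosage as predictor, returning the per-allele slope, its Wald SE
#' and the two-sided p-value.
#'
#' @param dosage additive genotype vector (0/1/2).
#' @param food_group energy-adjusted intake vector (servings/week).
#' @param age numeric covariate.
#' @param family_id family identifiers for the random intercept.
#' @return One-row data frame: `beta`, `se`, `p`, `n`, `n_families`.
#' @export
fit_snp_food <- function(dosage, food_group, age, family_id) {
  d <- data.frame(y = food_group, x = dosage, age = age,
                  family_id = factor(family_id))
  d <- d[complete.cases(d), , drop = FALSE]
  d$family_id <- droplevels(d$family_id)
  if (nrow(d) < 10) stop("fewer than 10 subjects after listwise deletion")
  if (sd(d$x) == 0) stop("monomorphic SNP: dosage is constant")
  if (nlevels(d$family_id) < 2) stop("need at least 2 families")
  fit <- lme4::lmer(y ~ x + age + (1 | family_id), data = d, REML = TRUE,
                    control = lmer_ctrl())
  out <- extract_assoc(fit)
  out$n <- nrow(d)
  out$n_families <- nlevels(d$family_id)
  out
}

#' SNP-to-food-intake follow-up scan
#'
#' Runs [fit_snp_food()] for every (SNP, food group) pair in a supplied
#' list — typically SNPs previously associated with blood levels of
#' diet-associated metabolites. Each record carries both a nominal flag
#' (p < `alpha`) and a Bonferroni flag (p < `alpha` / number of listed
#' tests). Unresolvable or failed pairs stay in the output with an explicit
#' error message, so the output always has one row per listed pair.
#'
#' @param snp_food_map data frame with columns `snp` and `food_group`.
#' @param genotypes subjects x SNPs dosage matrix (row names subject ids).
#' @param foods subjects x food groups matrix of energy-adjusted intakes.
#' @param cohort cohort data frame.
#' @param alpha significance level; default 0.05.
#' @return List with `records` (snp, food_group, beta, se, p, n,
#'   n_families, nominal, significant, error) and `threshold`
#'   (`alpha / nrow(snp_food_map)`).
#' @export
snp_scan <- function(snp_food_map, genotypes, foods, cohort, alpha = 0.05) {
  validate_genotypes(genotypes, cohort)
  if (nrow(snp_food_map) == 0)
    return(list(records = data.frame(
      snp = character(), food_group = character(), beta = numeric(),
      se = numeric(), p = numeric(), n = integer(), n_families = integer(),
      nominal = logical(), significant = logical(), error = character(),
      stringsAsFactors = FALSE), threshold = NA_real_))
  thr <- bonferroni_threshold(alpha, nrow(snp_food_map))
  subj <- cohort$subject_id
  out <- vector("list", nrow(snp_food_map))
  for (i in seq_len(nrow(snp_food_map))) {
    s <- snp_food_map$snp[i]
    g <- snp_food_map$food_group[i]
    rec <- data.frame(snp = s, food_group = g, beta = NA_real_, se = NA_real_,
                      p = NA_real_, n = NA_integer_, n_families = NA_integer_,
                      nominal = FALSE, significant = FALSE,
                      error = NA_character_, stringsAsFactors = FALSE)
    fit <- tryCatch({
      if (!s %in% colnames(genotypes)) stop(sprintf("SNP %s not in genotypes", s))
      if (!g %in% colnames(foods)) stop(sprintf("food group %s not in foods", g))
      fit_snp_food(genotypes[subj, s], foods[subj, g], cohort$age,
                   cohort$family_id)
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      rec$error <- fit
    } else {
      rec$beta <- fit$beta; rec$se <- fit$se; rec$p <- fit$p
      rec$n <- fit$n; rec$n_families <- fit$n_families
      rec$nominal <- fit$p < alpha
      rec$significant <- fit$p < thr
    }
    out[[i]] <- rec
  }
  list(records = do.call(rbind, out), threshold = thr)
}
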