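#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level, in (0,1).
#' @param n_tests number of tests, >= 1.
#' @return `alpha / n_tests` (unrounded; the reporting layer rounds to 3
#'   significant figures).
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Partition a cohort by MZ-pair discordance for a food group
#'
#' Computes the sample SD of the food-group intake over all subjects with an
#' observed value, flags each complete MZ pair discordant when the absolute
#' within-pair difference is at least `sd_multiplier` SDs, and splits the
#' sample: members of discordant MZ pairs form the replication set, everyone
#' else (concordant MZ pairs, all DZ pairs, singletons) the discovery set.
#'
#' @param food_group named numeric vector of energy-adjusted intakes
#'   (servings/week), names are subject ids.
#' @param cohort cohort data frame (`subject_id`, `family_id`, `zygosity`).
#' @param sd_multiplier discordance margin in intake SDs; default 1.
#' @param food_group_id label stored in the partition.
#' @return An object of class `discordance_partition`: list with
#'   `food_group`, `sd`, `discovery` / `replication` subject id vectors, and
#'   `pair_flags` (one row per complete MZ pair with its absolute difference
#'   and discordance flag).
#' @export
classify_discordant_pairs <- function(food_group, cohort, sd_multiplier = 1,
                                      food_group_id = "food_group") {
  stopifnot(!is.null(names(food_group)))
  x <- food_group[cohort$subject_id]
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    warning(sprintf("food group %s has zero intake SD; replication set empty",
                    food_group_id))
    s <- if (is.na(s)) 0 else s
  }

  fams <- split(seq_len(nrow(cohort)), cohort$family_id)
  rep_ids <- character()
  flags <- list()
  for (f in fams) {
    if (length(f) != 2) next
    if (cohort$zygosity[f[1]] != "MZ") next
    d <- abs(x[f[1]] - x[f[2]])
    if (is.na(d)) next  # a missing co-twin intake: treated as concordant
    disc <- s > 0 && d >= sd_multiplier * s
    flags[[length(flags) + 1]] <- data.frame(
      family_id = cohort$family_id[f[1]], abs_diff = unname(d),
      discordant = disc, stringsAsFactors = FALSE)
    if (disc) rep_ids <- c(rep_ids, cohort$subject_id[f])
  }
  observed <- cohort$subject_id[!is.na(x)]
  structure(list(
    food_group = food_group_id, sd = s,
    discovery = setdiff(observed, rep_ids),
    replication = rep_ids,
    pair_flags = if (length(flags)) do.call(rbind, flags) else
      data.frame(family_id = character(), abs_diff = numeric(),
                 discordant = logical())
  ), class = "discordance_partition")
}

# Shared model-frame builder: listwise deletion, batch/family as factors,
# a single-level batch is dropped from the fixed effects.
build_fit_frame <- function(y, x, age, bmi, batch, family_id) {
  d <- data.frame(y = y, x = x, age = age, bmi = bmi,
                  batch = factor(batch), family_id = factor(family_id))
  d <- d[complete.cases(d), , drop = FALSE]
  d$batch <- droplevels(d$batch)
  d$family_id <- droplevels(d$family_id)
  d
}

lmer_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore")
}

extract_assoc <- function(fit, term = "x") {
  beta <- lme4::fixef(fit)[[term]]
  se <- sqrt(as.matrix(vcov(fit))[term, term])
  z <- beta / se
  data.frame(beta = beta, se = se, p = 2 * pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Family random-intercept regression of a metabolite on a food group
#'
#' Fits, by REML,
#' `Y = b0 + b X + g age + d BMI + batch + zeta_family + e`
#' where `zeta_family` is a family-level random intercept capturing twin
#' relatedness and `batch` enters as categorical fixed effects (omitted when
#' only one batch is present). Inference on the food-group slope is by a
#' two-sided Wald z test. When the estimated family variance hits the zero
#' boundary the fit coincides with ordinary least squares.
#'
#' @param metabolite numeric response vector (preprocessed metabolite).
#' @param food_group numeric predictor (energy-adjusted servings/week).
#' @param age,bmi numeric covariates.
#' @param batch batch labels (categorical); a constant batch is dropped.
#' @param family_id family identifiers for the random intercept.
#' @return One-row data frame: `beta`, `se`, `p`, `n`, `n_families`.
#' @export
fit_random_intercept <- function(metabolite, food_group, age, bmi, batch,
                                 family_id) {
  d <- build_fit_frame(metabolite, food_group, age, bmi, batch, family_id)
  if (nrow(d) < 10) stop("fewer than 10 subjects after listwise deletion")
  if (nlevels(d$family_id) < 2) stop("need at least 2 families")
  check_fixed_design(d)
  form <- if (nlevels(d$batch) > 1)
    y ~ x + age + bmi + batch + (1 | family_id) else
    y ~ x + age + bmi + (1 | family_id)
  fit <- lme4::lmer(form, data = d, REML = TRUE, control = lmer_ctrl())
  out <- extract_assoc(fit)
  out$n <- nrow(d)
  out$n_families <- nlevels(d$family_id)
  out
}

check_fixed_design <- function(d) {
  X <- model.matrix(if (nlevels(d$batch) > 1) ~ x + age + bmi + batch else
    ~ x + age + bmi, d)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop(sprintf("singular fixed-effect design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  invisible(TRUE)
}

# Scan fast path: the design for one food group's subset is fixed across
# metabolites, so fit the first metabolite fully and refit() the rest
# (response-only update re-optimises the REML criterion).
scan_food_group <- function(Y, x, age, bmi, batch, family_id) {
  covar_ok <- complete.cases(data.frame(x, age, bmi, batch, family_id))
  res <- vector("list", ncol(Y))
  base_fit <- NULL
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    rec <- tryCatch({
      if (anyNA(y[covar_ok])) {
        r <- fit_random_intercept(y, x, age, bmi, batch, family_id)
      } else {
        dj <- build_fit_frame(y, x, age, bmi, batch, family_id)
        if (nrow(dj) < 10) stop("fewer than 10 subjects after listwise deletion")
        if (nlevels(dj$family_id) < 2) stop("need at least 2 families")
        if (is.null(base_fit)) {
          check_fixed_design(dj)
          form <- if (nlevels(dj$batch) > 1)
            y ~ x + age + bmi + batch + (1 | family_id) else
            y ~ x + age + bmi + (1 | family_id)
          base_fit <- lme4::lmer(form, data = dj, REML = TRUE,
                                 control = lmer_ctrl())
          fit <- base_fit
        } else {
          fit <- suppressMessages(lme4::refit(base_fit, newresp = dj$y))
        }
        r <- extract_assoc(fit)
        r$n <- nrow(dj)
        r$n_families <- nlevels(dj$family_id)
        r
      }
      r$error <- NA_character_
      r
    }, error = function(e) {
      data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                 n = NA_integer_, n_families = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rec$metabolite <- colnames(Y)[j]
    res[[j]] <- rec
  }
  do.call(rbind, res)
}

#' Discovery-stage metabolome-wide scan
#'
#' For each food group, partitions the sample by MZ discordance
#' ([classify_discordant_pairs()]) and fits the family random-intercept
#' model of every metabolite on that food group over the discovery subset.
#' Records are flagged significant at the Bonferroni threshold
#' `alpha / n_tests`, where `n_tests` defaults to the number of
#' (food group, metabolite) pairs in this scan; pass `n_tests` explicitly
#' when the multiplicity spans several platforms.
#'
#' @param panel preprocessed [metabolite_panel()].
#' @param foods subjects x food groups matrix of energy-adjusted intakes
#'   (row names subject ids).
#' @param cohort cohort data frame (`subject_id`, `family_id`, `zygosity`,
#'   `age`, `bmi`).
#' @param alpha family-wise error level; default 0.05.
#' @param sd_multiplier discordance margin; default 1.
#' @param n_tests multiplicity denominator override (e.g. a fixed product
#'   of food groups and metabolites spanning both platforms).
#' @return List with `records` (one row per pair: food_group, metabolite,
#'   platform, stage, beta, se, p, n, n_families, significant, error),
#'   `partitions` (named list of per-food-group partitions), and
#'   `threshold`.
#' @export
discovery_scan <- function(panel, foods, cohort, alpha = 0.05,
                           sd_multiplier = 1, n_tests = NULL) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (anyNA(panel$values))
    stop("panel still contains missing values; preprocess before scanning")
  subj <- cohort$subject_id
  if (!all(subj %in% rownames(foods)) || !all(subj %in% rownames(panel$values)))
    stop("cohort subjects missing from foods or panel")
  if (is.null(n_tests)) n_tests <- ncol(foods) * ncol(panel$values)
  thr <- bonferroni_threshold(alpha, n_tests)

  partitions <- list()
  records <- list()
  for (g in colnames(foods)) {
    fg <- setNames(foods[subj, g], subj)
    part <- classify_discordant_pairs(fg, cohort, sd_multiplier, g)
    partitions[[g]] <- part
    idx <- match(part$discovery, subj)
    recs <- scan_food_group(
      panel$values[part$discovery, , drop = FALSE],
      fg[part$discovery], cohort$age[idx], cohort$bmi[idx],
      panel$run_day[match(part$discovery, rownames(panel$values))],
      cohort$family_id[idx])
    recs$food_group <- g
    records[[g]] <- recs
  }
  records <- do.call(rbind, records)
  n_fail <- sum(!is.na(records$error))
  if (n_fail) message(sprintf("discovery scan: %d of %d fits failed",
                              n_fail, nrow(records)))
  records$platform <- panel$platform
  records$stage <- "discovery"
  records$significant <- !is.na(records$p) & records$p < thr
  rownames(records) <- NULL
  cols <- c("food_group", "metabolite", "platform", "stage", "beta", "se",
            "p", "n", "n_families", "significant", "error")
  list(records = records[, cols], partitions = partitions, threshold = thr)
}

#' Replication of discovery-significant associations in MZ-discordant pairs
#'
#' Refits the same random-intercept model for each discovery-significant
#' record, on the members of the MZ pairs discordant for that food group.
#' An association replicates when the replication slope has the same sign
#' as the discovery slope and, on the non-targeted platform only, its
#' two-sided p-value is below `replication_alpha`; the direction criterion
#' alone is applied to the targeted platform.
#'
#' @param significant data frame of discovery-significant records (subset of
#'   a [discovery_scan()] `records` table).
#' @param panel,foods,cohort as in [discovery_scan()].
#' @param partitions the partitions returned by the discovery scan.
#' @param replication_alpha replication significance level; default 0.05.
#' @return Data frame with one row per input record: the replication-stage
#'   fit plus a `replicated` flag and a `reason` for records that could not
#'   be tested (replication set below the minimum fit size).
#' @export
replicate_associations <- function(significant, panel, foods, cohort,
                                   partitions, replication_alpha = 0.05) {
  subj <- cohort$subject_id
  out <- vector("list", nrow(significant))
  for (i in seq_len(nrow(significant))) {
    g <- significant$food_group[i]
    m <- significant$metabolite[i]
    part <- partitions[[g]]
    rep_ids <- part$replication
    rec <- data.frame(food_group = g, metabolite = m,
                      platform = panel$platform, stage = "replication",
                      beta = NA_real_, se = NA_real_, p = NA_real_,
                      n = length(rep_ids), n_families = NA_integer_,
                      replicated = FALSE, reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (length(rep_ids) < 10) {
      rec$reason <- "replication set below minimum fit size"
    } else {
      idx <- match(rep_ids, subj)
      fit <- tryCatch(
        fit_random_intercept(
          panel$values[rep_ids, m], foods[rep_ids, g],
          cohort$age[idx], cohort$bmi[idx],
          panel$run_day[match(rep_ids, rownames(panel$values))],
          cohort$family_id[idx]),
        error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        rec$reason <- fit
      } else {
        rec$beta <- fit$beta; rec$se <- fit$se; rec$p <- fit$p
        rec$n <- fit$n; rec$n_families <- fit$n_families
        same_dir <- sign(fit$beta) == sign(significant$beta[i])
        rec$replicated <- same_dir &&
          (panel$platform == "targeted" || fit$p < replication_alpha)
      }
    }
    out[[i]] <- rec
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(food_group = character(), metabolite = character(),
               platform = character(), stage = character(), beta = numeric(),
               se = numeric(), p = numeric(), n = integer(),
               n_families = integer(), replicated = logical(),
               reason = character(), stringsAsFactors = FALSE)
}

#' Inverse-variance fixed-effect meta-analysis of two stage estimates
#'
#' Combines the discovery and replication estimates of one
#' (food group, metabolite) pair with weights `1/SE^2`: the meta estimate is
#' the weighted mean of the stage slopes, its SE is `1/sqrt(sum(weights))`,
#' and the p-value is the two-sided normal tail of the combined z.
#'
#' @param disc,rep one-row data frames with `food_group`, `metabolite`,
#'   `beta`, `se` (both SEs > 0) for the same pair.
#' @param threshold significance threshold applied to the meta p-value
#'   (normally the scan's Bonferroni threshold).
#' @param replicated logical replication flag carried into the record.
#' @return One-row data frame: `food_group`, `metabolite`, `beta`, `se`,
#'   `p`, `replicated`, `significant`.
#' @export
meta_fixed_effect <- function(disc, rep, threshold = NULL, replicated = NA) {
  if (disc$food_group != rep$food_group || disc$metabolite != rep$metabolite)
    stop("meta_fixed_effect: stage records refer to different pairs")
  if (!is.finite(disc$se) || !is.finite(rep$se) || disc$se <= 0 || rep$se <= 0)
    stop("meta_fixed_effect: both standard errors must be positive")
  w <- c(1 / disc$se^2, 1 / rep$se^2)
  beta <- sum(w * c(disc$beta, rep$beta)) / sum(w)
  se <- 1 / sqrt(sum(w))
  p <- 2 * pnorm(-abs(beta / se))
  data.frame(food_group = disc$food_group, metabolite = disc$metabolite,
             beta = beta, se = se, p = p, replicated = replicated,
             significant = if (is.null(threshold)) NA else p < threshold,
             stringsAsFactors = FALSE)
}
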