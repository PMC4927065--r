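#' Default 9-point FFQ frequency scale, in servings per week
#'
#' Midpoint convention for the usual semi-quantitative food-frequency
#' categories, from "never or less than once per month" up to "6+ per day".
#' Category 1 maps to 0 (never / under once a month), category 3 to exactly
#' 1 serving per week; daily categories use midpoints times 7.
#'
#' @return Named numeric vector of length 9 (names are the category codes
#'   "1".."9"), non-decreasing.
#' @export
default_frequency_scale <- function() {
  setNames(c(0, 0.5, 1, 3, 5.5, 7, 17.5, 31.5, 45), as.character(1:9))
}

#' Convert FFQ frequency codes to servings per week
#'
#' @param ffq data frame with `subject_id`, one column per food item holding
#'   integer frequency codes 1..9, and `energy_kcal` (total energy intake,
#'   kcal/day).
#' @param scale_map named numeric vector mapping the 9 category codes to
#'   servings/week; must cover all codes present and be non-decreasing.
#' @return data frame: `subject_id`, then one servings/week column per item.
#' @export
frequency_to_servings <- function(ffq, scale_map = default_frequency_scale()) {
  if (!"subject_id" %in% names(ffq)) stop("ffq needs a subject_id column")
  if (is.unsorted(scale_map)) stop("scale_map must be non-decreasing")
  item_cols <- setdiff(names(ffq), c("subject_id", "energy_kcal"))
  out <- ffq[, "subject_id", drop = FALSE]
  for (it in item_cols) {
    code <- as.character(ffq[[it]])
    unknown <- !is.na(code) & !code %in% names(scale_map)
    if (any(unknown)) {
      i <- which(unknown)[1]
      stop(sprintf("unknown frequency code %s for subject %s, item %s",
                   code[i], ffq$subject_id[i], it))
    }
    out[[it]] <- unname(scale_map[code])
  }
  out
}

#' Sum item-level servings into food groups
#'
#' @param items data frame from [frequency_to_servings()] (`subject_id` plus
#'   item columns).
#' @param map data frame with columns `item` and `food_group`; every item
#'   column must be mapped, each to exactly one group.
#' @return Numeric matrix, subjects x food groups (row names subject ids),
#'   unadjusted servings/week.
#' @export
aggregate_food_groups <- function(items, map) {
  item_cols <- setdiff(names(items), "subject_id")
  if (anyDuplicated(map$item))
    stop("each item must map to exactly one food group")
  unmapped <- setdiff(item_cols, map$item)
  if (length(unmapped))
    stop(sprintf("unmapped item(s): %s", paste(unmapped, collapse = ", ")))
  groups <- unique(map$food_group)
  m <- matrix(0, nrow(items), length(groups),
              dimnames = list(items$subject_id, groups))
  for (it in item_cols) {
    g <- map$food_group[match(it, map$item)]
    m[, g] <- m[, g] + items[[it]]
  }
  m
}

#' Energy adjustment by the residual method
#'
#' Regresses an intake variable on total energy intake and replaces it with
#' the residual plus the sample mean of the intake, removing confounding by
#' overall consumption while preserving the original units and location. The
#' output is uncorrelated with energy by construction.
#'
#' @param group_values numeric vector of intakes (servings/week).
#' @param energy numeric vector of total energy intakes (kcal/day), same
#'   length, non-constant.
#' @return Energy-adjusted vector, same length, same mean.
#' @export
energy_adjust_residual <- function(group_values, energy) {
  if (length(group_values) != length(energy) || length(energy) < 3)
    stop("group_values and energy must have equal length >= 3")
  if (sd(energy) == 0) stop("energy intake is constant; residual method undefined")
  fit <- lm(group_values ~ energy)
  unname(resid(fit)) + mean(group_values)
}

#' FFQ to energy-adjusted food-group matrix
#'
#' The full diet chain: frequency codes to servings/week, summation into
#' food groups, then energy adjustment by the residual method. Adjustment is
#' applied at the food-group level by default; `adjust_order = "item"`
#' adjusts each item before aggregation instead.
#'
#' @param ffq FFQ data frame (see [frequency_to_servings()]); must include
#'   `energy_kcal`.
#' @param map item-to-food-group map (see [aggregate_food_groups()]).
#' @param scale_map frequency-code scale; default [default_frequency_scale()].
#' @param adjust_order `"group"` (default) or `"item"`.
#' @return Numeric matrix, subjects x food groups, energy-adjusted
#'   servings/week.
#' @export
build_food_group_matrix <- function(ffq, map, scale_map = default_frequency_scale(),
                                    adjust_order = c("group", "item")) {
  adjust_order <- match.arg(adjust_order)
  if (!"energy_kcal" %in% names(ffq)) stop("ffq needs an energy_kcal column")
  if (any(ffq$energy_kcal <= 0)) stop("total energy intake must be positive")
  items <- frequency_to_servings(ffq, scale_map)
  if (adjust_order == "item") {
    for (it in setdiff(names(items), "subject_id"))
      items[[it]] <- energy_adjust_residual(items[[it]], ffq$energy_kcal)
    aggregate_food_groups(items, map)
  } else {
    m <- aggregate_food_groups(items, map)
    out <- apply(m, 2, energy_adjust_residual, energy = ffq$energy_kcal)
    dimnames(out) <- dimnames(m)
    out
  }
}
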