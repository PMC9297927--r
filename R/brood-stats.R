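#' Proportion with an exact binomial confidence interval
#'
#' Wraps a count proportion with its Clopper-Pearson (exact binomial) 95%
#' interval, the small-sample-safe default for brood counts.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `proportion_result`: list with `numerator`,
#'   `denominator`, `proportion`, `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' proportion_result(350, 781)
#' @export
proportion_result <- function(numerator, denominator, conf_level = 0.95) {
  stopifnot(length(numerator) == 1L, length(denominator) == 1L,
            numerator >= 0, denominator > 0, numerator <= denominator)
  bt <- stats::binom.test(round(numerator), round(denominator),
                          conf.level = conf_level)
  structure(
    list(numerator = numerator, denominator = denominator,
         proportion = numerator / denominator,
         ci_low = unname(bt$conf.int[1L]), ci_high = unname(bt$conf.int[2L]),
         conf_level = conf_level),
    class = "proportion_result"
  )
}

#' @export
print.proportion_result <- function(x, digits = 3, ...) {
  cat(x$numerator, "/", x$denominator, " = ", signif(x$proportion, digits),
      "  (", 100 * x$conf_level, "% CI ", signif(x$ci_low, digits), "-",
      signif(x$ci_high, digits), ")\n", sep = "")
  invisible(x)
}

#' Classify broods as all-male, with-females, or no-offspring
#'
#' Under arrhenotoky an unmated female produces only (haploid) sons, so a
#' brood with male but no female adults is classified all-male. Broods with
#' no adult offspring at all are a separate "no_offspring" category, not
#' all-male.
#'
#' @param records Brood table with columns `n_female_adults`,
#'   `n_male_adults` (one row per mother).
#' @return `classify_all_male()`: logical vector, `TRUE` for all-male
#'   broods. `brood_category()`: character vector in
#'   `c("all_male", "with_females", "no_offspring")`.
#' @export
classify_all_male <- function(records) {
  records$n_female_adults == 0L & records$n_male_adults > 0L
}

#' @rdname classify_all_male
#' @export
brood_category <- function(records) {
  ifelse(records$n_female_adults > 0L, "with_females",
         ifelse(records$n_male_adults > 0L, "all_male", "no_offspring"))
}

#' Proportion of all-male broods
#'
#' Fraction of broods classified all-male, with an exact binomial CI. The
#' default denominator counts only offspring-bearing broods; set
#' `denominator = "all"` to count every hosted mother including those that
#' produced no offspring.
#'
#' @param records Brood table (see [classify_all_male()]); may also carry a
#'   `group` column.
#' @param group Optional group label to filter on (e.g. `"inbred"`,
#'   `"control"`).
#' @param denominator `"offspring_bearing"` (default) or `"all"`.
#' @return A [proportion_result()].
#' @examples
#' rec <- data.frame(n_female_adults = c(0, 3, 0), n_male_adults = c(7, 2, 0))
#' all_male_proportion(rec)   # 1 all-male of 2 offspring-bearing broods
#' @export
all_male_proportion <- function(records, group = NULL,
                                denominator = c("offspring_bearing", "all")) {
  denominator <- match.arg(denominator)
  if (!is.null(group)) records <- records[records$group == group, , drop = FALSE]
  if (nrow(records) == 0L) stop("no broods in group", call. = FALSE)
  cat_ <- brood_category(records)
  denom <- if (denominator == "offspring_bearing") {
    sum(cat_ != "no_offspring")
  } else {
    nrow(records)
  }
  if (denom == 0L) stop("no offspring-bearing broods in group", call. = FALSE)
  proportion_result(sum(cat_ == "all_male"), denom)
}

#' Exclude all-male broods from analysis
#'
#' All-male broods are interpreted as the product of unmated mothers and
#' removed before sex-ratio analysis; only broods with at least one female
#' adult are retained (so re-application is idempotent). An exclusion log
#' is attached as attribute `"exclusion_log"`.
#'
#' @param records Brood table.
#' @return The daughter-producing subset of `records`, with attribute
#'   `"exclusion_log"`: tibble of the dropped rows' `mother_id` (when
#'   present) and category.
#' @export
exclude_all_male <- function(records) {
  cat_ <- brood_category(records)
  keep <- cat_ == "with_females"
  log <- tibble::tibble(
    mother_id = if ("mother_id" %in% names(records)) {
      as.character(records$mother_id[!keep])
    } else {
      as.character(which(!keep))
    },
    category = cat_[!keep]
  )
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Progeny sex ratio (proportion male)
#'
#' @param records Brood table with `n_female_adults`, `n_male_adults`.
#' @param mode `"pooled"`: total males over total adults, with exact CI;
#'   `"per_brood_mean"`: mean of per-brood proportions with its standard
#'   error (broods with no adults are dropped).
#' @return `"pooled"`: a [proportion_result()]. `"per_brood_mean"`: list
#'   with `mean`, `se`, `n_broods`.
#' @export
sex_ratio <- function(records, mode = c("pooled", "per_brood_mean")) {
  mode <- match.arg(mode)
  tot <- records$n_female_adults + records$n_male_adults
  if (sum(tot) == 0) stop("no adult wasps in records", call. = FALSE)
  if (mode == "pooled") {
    proportion_result(sum(records$n_male_adults), sum(tot))
  } else {
    r <- records$n_male_adults[tot > 0] / tot[tot > 0]
    list(mean = mean(r),
         se = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_,
         n_broods = length(r))
  }
}

#' Host-outcome proportions for one or more broods
#'
#' Each parasitized host yields exactly one adult wasp in these solitary
#' species, so host outcomes partition into emerged adult wasps, emerged
#' flies, and non-emerged fly pupae (which may hide wasps that died before
#' emergence). By default proportions are taken over the total of these
#' observed outcomes; `denominator = "hosts"` divides by the recorded host
#' count instead.
#'
#' @param records Brood table with `n_female_adults`, `n_male_adults`,
#'   `n_flies_emerged`, `n_fly_pupae_unemerged` (and `n_hosts` when
#'   `denominator = "hosts"`).
#' @param denominator `"outcomes"` (default) or `"hosts"`.
#' @return Tibble with `adult_wasp_proportion` and
#'   `non_emerged_pupa_proportion` per row (`NA` where the denominator is 0).
#' @export
emergence_proportions <- function(records,
                                  denominator = c("outcomes", "hosts")) {
  denominator <- match.arg(denominator)
  adults <- records$n_female_adults + records$n_male_adults
  denom <- if (denominator == "outcomes") {
    adults + records$n_flies_emerged + records$n_fly_pupae_unemerged
  } else {
    records$n_hosts
  }
  tibble::tibble(
    adult_wasp_proportion = ifelse(denom > 0, adults / denom, NA_real_),
    non_emerged_pupa_proportion =
      ifelse(denom > 0, records$n_fly_pupae_unemerged / denom, NA_real_)
  )
}

#' Exact two-sided comparison of two proportions
#'
#' Conditional exact test (Fisher) on the 2x2 table of the two counts by
#' default, with a pooled-proportion normal approximation as an option.
#' Symmetric in its arguments.
#'
#' @param a,b [proportion_result()] objects (or lists with `numerator` and
#'   `denominator`).
#' @param method `"exact"` (conditional exact, default) or `"normal"`
#'   (two-sample proportion test without continuity correction).
#' @return Two-sided p-value.
#' @examples
#' compare_proportions(proportion_result(350, 781),
#'                     proportion_result(343, 559))
#' @export
compare_proportions <- function(a, b, method = c("exact", "normal")) {
  method <- match.arg(method)
  stopifnot(a$denominator > 0, b$denominator > 0)
  m <- rbind(c(a$numerator, a$denominator - a$numerator),
             c(b$numerator, b$denominator - b$numerator))
  if (method == "exact") {
    stats::fisher.test(m)$p.value
  } else {
    stats::prop.test(m, correct = FALSE)$p.value
  }
}

#' Pooled female fraction among dissected dead wasps
#'
#' Non-emerged host pupae are sometimes opened and the dead wasps inside
#' sexed by antennal morphology; a female-biased dead-wasp pool indicates
#' inbreeding depression on diploid females rather than diploid male
#' mortality.
#'
#' @param records Brood table with dissection counts `n_dead_wasps_female`,
#'   `n_dead_wasps_male` (`NA`s allowed and treated as no dissection).
#' @return A [proportion_result()] for females among all dissected dead
#'   wasps.
#' @export
dead_wasp_female_proportion <- function(records) {
  f <- records$n_dead_wasps_female
  m <- records$n_dead_wasps_male
  have <- !(is.na(f) & is.na(m))
  if (!any(have)) stop("no dissection counts present", call. = FALSE)
  nf <- sum(f[have], na.rm = TRUE)
  nm <- sum(m[have], na.rm = TRUE)
  if (nf + nm == 0) stop("no dissected wasps", call. = FALSE)
  proportion_result(nf, nf + nm)
}

#' Probability of observing zero diploid males
#'
#' If a fraction `d` of tested males is expected to be diploid, the chance
#' that none of `n` independently tested males is diploid is `(1 - d)^n`.
#' Vector inputs are treated as independent batches (broods, generations)
#' and the probabilities multiplied.
#'
#' @param n_tested Count(s) of males tested for ploidy.
#' @param d Expected diploid fraction(s) among tested males, in `[0, 1]`
#'   (recycled against `n_tested`).
#' @return Single probability.
#' @examples
#' zero_diploid_probability(80, 0.5)   # ~8.3e-25
#' @export
zero_diploid_probability <- function(n_tested, d) {
  stopifnot(all(n_tested >= 0), all(d >= 0 & d <= 1))
  len <- max(length(n_tested), length(d))
  n <- rep_len(unname(as.numeric(n_tested)), len)
  dd <- rep_len(unname(as.numeric(d)), len)
  if (any(dd == 1 & n > 0)) return(0)
  prod((1 - dd)^n)
}

#' Detection power of a ploidy-testing plan against a CSD hypothesis
#'
#' Probability of finding *no* diploid males when `n_g` males are tested at
#' generation `g`, under the CSD scenario embodied by a pedigree
#' simulation. A small value means the observed absence of diploid males
#' would be very unlikely under that scenario.
#'
#' Two estimators are available:
#'
#' * `mode = "pooled"` (default): `prod_g (1 - d_g)^(n_g)` with `d_g` the
#'   diploid fraction among males pooled across all surviving replicates
#'   at generation `g`. This matches an experiment that samples its tested
#'   males across many independent families.
#' * `mode = "per_replicate"`: the mean over replicates of
#'   `prod_g (1 - d_rg)^(n_g)` with `d_rg` the replicate's own realized
#'   fraction. This is the evidence a *single* family lineage would give;
#'   with small broods it is dominated by families that by chance contain
#'   no diploid males at all, and so stays orders of magnitude larger than
#'   the pooled estimate.
#'
#' Generations where a replicate is extinct or has no males contribute no
#' testable males (factor 1 in the per-replicate mode; excluded from the
#' pooled fraction).
#'
#' @param sim A `csd_simulation` from [run_simulation()].
#' @param tested_per_generation Named numeric vector mapping generation
#'   labels (as in the simulation summary) to numbers of tested males.
#' @param mode `"pooled"` or `"per_replicate"` (see above).
#' @return List with `p_zero` (the power statistic), `mc_se` (Monte Carlo
#'   standard error; `NA` in pooled mode) and `n_replicates`.
#' @examples
#' sim <- run_simulation(cross_scheme_preset("heterotoma", n_bs = 1),
#'                       csd_params(1), brood_model(), 500, seed = 7)
#' power_from_simulation(sim, c("B-S 1" = 80))
#' @export
power_from_simulation <- function(sim, tested_per_generation,
                                  mode = c("pooled", "per_replicate")) {
  stopifnot(inherits(sim, "csd_simulation"))
  mode <- match.arg(mode)
  gens <- names(tested_per_generation)
  if (is.null(gens) || !all(gens %in% sim$summary$generation)) {
    stop("tested_per_generation must be named by simulation generation labels",
         call. = FALSE)
  }
  reps <- sim$replicates
  if (mode == "pooled") {
    pz <- 1
    for (g in gens) {
      x <- reps[reps$generation == g & !reps$extinct, ]
      males <- sum(x$n_haploid_male + x$n_diploid_male, na.rm = TRUE)
      d <- if (males > 0) sum(x$n_diploid_male, na.rm = TRUE) / males else 0
      pz <- pz * (1 - d)^tested_per_generation[[g]]
    }
    list(p_zero = pz, mc_se = NA_real_, n_replicates = sim$n_replicates)
  } else {
    pz <- rep(1, sim$n_replicates)
    for (g in gens) {
      x <- reps[reps$generation == g, ]
      males <- x$n_haploid_male + x$n_diploid_male
      d <- ifelse(!is.na(males) & males > 0, x$n_diploid_male / males, 0)
      pz <- pz * (1 - d)^tested_per_generation[[g]]
    }
    list(p_zero = mean(pz), mc_se = stats::sd(pz) / sqrt(length(pz)),
         n_replicates = sim$n_replicates)
  }
}
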