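#' Relative endosymbiont titer from qPCR quantities
#'
#' The relative *Wolbachia* titer of a diploid female is twice the ratio of
#' the endosymbiont-specific gene quantity (*gssb*) to the host
#' single-copy reference gene quantity (*ef1a*), the factor 2 correcting
#' for the two reference-gene copies per diploid cell. Quantities may be
#' given directly or as qPCR cycle thresholds (Ct), in which case quantity
#' ratios are `efficiency^(ct_ref - ct_target)`.
#'
#' Scale-invariant: multiplying both quantities by the same positive
#' constant leaves the titer unchanged.
#'
#' @param gssb_quantity,ef1a_quantity Relative DNA quantities (> 0);
#'   vectorized.
#' @param ct_gssb,ct_ef1a Alternatively, cycle thresholds (>= 0).
#' @param efficiency Amplification factor per cycle (default 2, perfect
#'   doubling).
#' @return Numeric vector of dimensionless titers.
#' @examples
#' relative_titer(gssb_quantity = 3, ef1a_quantity = 3)        # 2
#' relative_titer(ct_gssb = 20.0, ct_ef1a = 21.63)             # ~6.19
#' @export
relative_titer <- function(gssb_quantity = NULL, ef1a_quantity = NULL,
                           ct_gssb = NULL, ct_ef1a = NULL, efficiency = 2) {
  have_q <- !is.null(gssb_quantity) || !is.null(ef1a_quantity)
  have_ct <- !is.null(ct_gssb) || !is.null(ct_ef1a)
  if (have_q == have_ct) {
    stop("supply either quantities (gssb_quantity, ef1a_quantity) or cycle ",
         "thresholds (ct_gssb, ct_ef1a), not both", call. = FALSE)
  }
  if (have_q) {
    if (any(ef1a_quantity <= 0)) {
      stop("reference quantities must be > 0", call. = FALSE)
    }
    if (any(gssb_quantity < 0)) stop("quantities must be >= 0", call. = FALSE)
    2 * gssb_quantity / ef1a_quantity
  } else {
    if (any(ct_gssb < 0) || any(ct_ef1a < 0)) {
      stop("cycle thresholds must be >= 0", call. = FALSE)
    }
    if (efficiency <= 1) stop("efficiency must exceed 1", call. = FALSE)
    2 * efficiency^(ct_ef1a - ct_gssb)
  }
}

# logistic-in-log-titer dose response; slope = Inf gives a sharp threshold
# (>= threshold -> 1)
.titer_response <- function(titer, threshold, slope) {
  stopifnot(all(titer >= 0))
  if (is.infinite(slope)) {
    as.numeric(titer >= threshold)
  } else {
    out <- stats::plogis(slope * (log(titer) - log(threshold)))
    out[titer == 0] <- 0
    out
  }
}

#' Titer-threshold model of endosymbiont-induced thelytoky
#'
#' Generative model for the fate of an unfertilized egg as a function of
#' the mother's endosymbiont titer. Diploidization happens with probability
#' `p_dip(titer)`; a non-diploidized egg develops as a haploid male. Under
#' the `"one_step"` variant diploidy suffices for female development; under
#' the `"two_step"` variant the diploidized egg is feminized with
#' probability `p_fem(titer)` and otherwise develops as a diploid male.
#' Both responses are non-decreasing logistics in log titer
#' (`plogis(slope * (log(titer) - log(threshold)))`), with `slope = Inf`
#' giving a sharp threshold; `p(0) = 0` always. A two-step model with
#' `t_fem > t_dip` produces diploid males in the intermediate titer window.
#'
#' @param variant `"one_step"` or `"two_step"`.
#' @param t_dip,s_dip Diploidization threshold titer and slope.
#' @param t_fem,s_fem Feminization threshold and slope (two-step only).
#' @return Object of class `mechanism_model` with callable fields `p_dip`
#'   and `p_fem`.
#' @examples
#' m <- mechanism_model("two_step", t_dip = 0.5, s_dip = Inf,
#'                      t_fem = 2.5, s_fem = Inf)
#' expected_category_fractions(1, m)   # all diploid males in the window
#' @export
mechanism_model <- function(variant = c("one_step", "two_step"),
                            t_dip = 2, s_dip = 5,
                            t_fem = t_dip, s_fem = s_dip) {
  variant <- match.arg(variant)
  stopifnot(t_dip > 0, s_dip > 0, t_fem > 0, s_fem > 0)
  structure(
    list(variant = variant, t_dip = t_dip, s_dip = s_dip,
         t_fem = t_fem, s_fem = s_fem,
         p_dip = function(titer) .titer_response(titer, t_dip, s_dip),
         p_fem = function(titer) .titer_response(titer, t_fem, s_fem)),
    class = "mechanism_model"
  )
}

#' @export
print.mechanism_model <- function(x, ...) {
  cat("Thelytoky mechanism model (", x$variant, "): diploidization ",
      "threshold ", x$t_dip, " (slope ", x$s_dip, ")", sep = "")
  if (x$variant == "two_step") {
    cat("; feminization threshold ", x$t_fem, " (slope ", x$s_fem, ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Closed-form egg-fate probabilities at a given titer
#'
#' @param titer Titer(s) >= 0.
#' @param model A [mechanism_model()].
#' @return Tibble with columns `titer`, `p_haploid_male`, `p_diploid_male`,
#'   `p_diploid_female`; rows sum to 1.
#' @export
expected_category_fractions <- function(titer, model) {
  stopifnot(inherits(model, "mechanism_model"))
  pd <- model$p_dip(titer)
  pf <- if (model$variant == "two_step") model$p_fem(titer) else 1
  tibble::tibble(
    titer = titer,
    p_haploid_male = 1 - pd,
    p_diploid_male = pd * (1 - pf),
    p_diploid_female = pd * pf
  )
}

#' Stochastic egg fate
#'
#' Draws the developmental fate of `n` unfertilized eggs of a mother with
#' the given titer, per the mechanism model.
#'
#' @param titer Single titer >= 0.
#' @param model A [mechanism_model()].
#' @param n Number of eggs.
#' @return Character vector in
#'   `c("haploid_male", "diploid_male", "diploid_female")`.
#' @export
egg_fate <- function(titer, model, n = 1L) {
  stopifnot(length(titer) == 1L, titer >= 0)
  p <- expected_category_fractions(titer, model)
  sample(c("haploid_male", "diploid_male", "diploid_female"), n,
         replace = TRUE,
         prob = c(p$p_haploid_male, p$p_diploid_male, p$p_diploid_female))
}

#' Clutch and host model for dose-response simulations
#'
#' @param mean_offspring,dispersion Negative binomial parameters for the
#'   number of offspring (parasitized hosts) per mother.
#' @param extra_hosts_mean Mean number of additional, unparasitized hosts
#'   per mother (negative binomial with the same dispersion); these emerge
#'   as flies or die as non-emerged pupae.
#' @param fly_emerge_p Probability an unparasitized host emerges as a fly.
#' @param test_fraction Fraction of male offspring tested for ploidy.
#' @return Object of class `clutch_model`.
#' @export
clutch_model <- function(mean_offspring = 12, dispersion = 5,
                         extra_hosts_mean = 10, fly_emerge_p = 0.95,
                         test_fraction = 1) {
  stopifnot(mean_offspring > 0, dispersion > 0, extra_hosts_mean >= 0,
            fly_emerge_p >= 0, fly_emerge_p <= 1,
            test_fraction >= 0, test_fraction <= 1)
  structure(list(mean_offspring = mean_offspring, dispersion = dispersion,
                 extra_hosts_mean = extra_hosts_mean,
                 fly_emerge_p = fly_emerge_p, test_fraction = test_fraction),
            class = "clutch_model")
}

#' Default dose-to-titer map
#'
#' Mean titer as a decreasing logistic in log antibiotic dose with a
#' control plateau, plus a lognormal spread between mothers: dose 0 sits at
#' the plateau (untreated titers around 6), and the half-effect dose and
#' steepness control where titers collapse.
#'
#' @param doses Antibiotic doses (mg tetracycline per g yeast); the default
#'   covers both a coarse and a fine dilution series plus controls.
#' @param plateau Untreated mean titer.
#' @param d50 Dose at which the mean titer is half the plateau.
#' @param hill Steepness of the decrease in log dose.
#' @param log_sd Lognormal sd of mother-to-mother titer spread.
#' @return Tibble with columns `dose`, `mean_titer`, `log_sd`.
#' @export
dose_titer_map <- function(doses = c(0, 0.004, 0.008, 0.016, 0.031, 0.063,
                                     0.067, 0.089, 0.119, 0.125, 0.158,
                                     0.211, 0.25, 0.281, 0.375, 0.5, 1),
                           plateau = 6.3, d50 = 0.2, hill = 4,
                           log_sd = 0.4) {
  stopifnot(all(doses >= 0), plateau > 0, d50 > 0, hill > 0, log_sd >= 0)
  frac <- ifelse(doses == 0, 0,
                 stats::plogis(hill * (log(doses) - log(d50))))
  tibble::tibble(dose = doses, mean_titer = plateau * (1 - frac),
                 log_sd = log_sd)
}

#' Simulate a dose-response experiment
#'
#' For each mother at each dose, draws a titer (lognormal around the dose's
#' mean), a clutch of unfertilized eggs, applies [egg_fate()] per egg, and
#' aggregates per dose into the shape of a dose-response table: offspring
#' counts, sex, males tested for ploidy (a binomial subsample, hypergeometric
#' draw of diploids among them), and host fly outcomes.
#'
#' @param model A [mechanism_model()].
#' @param titer_map A [dose_titer_map()]-shaped tibble (`dose`,
#'   `mean_titer`, `log_sd`).
#' @param clutch A [clutch_model()].
#' @param n_mothers Mothers per dose (recycled over doses).
#' @param seed Optional integer seed.
#' @return Object of class `dose_response_table`: tibble with one row per
#'   dose and columns `dose`, `n_mothers`, `n_offspring`, `n_female`,
#'   `n_male`, `n_males_tested`, `n_diploid_males_found`,
#'   `n_flies_emerged`, `n_flies_unemerged`.
#' @examples
#' simulate_dose_response(mechanism_model("one_step"), dose_titer_map(),
#'                        clutch_model(), n_mothers = 5, seed = 1)
#' @export
simulate_dose_response <- function(model, titer_map = dose_titer_map(),
                                   clutch = clutch_model(), n_mothers = 5L,
                                   seed = NULL) {
  stopifnot(inherits(model, "mechanism_model"), nrow(titer_map) > 0)
  if (!is.null(seed)) set.seed(seed)
  n_mothers <- rep_len(as.integer(n_mothers), nrow(titer_map))
  rows <- lapply(seq_len(nrow(titer_map)), function(i) {
    nm <- n_mothers[i]
    n_off <- n_f <- n_m <- n_dm <- n_tested <- n_dm_found <- 0L
    flies_e <- flies_u <- 0L
    for (j in seq_len(nm)) {
      titer <- stats::rlnorm(1L, meanlog = log(max(titer_map$mean_titer[i],
                                                   1e-12)),
                             sdlog = titer_map$log_sd[i])
      if (titer_map$mean_titer[i] <= 0) titer <- 0
      n_eggs <- stats::rnbinom(1L, mu = clutch$mean_offspring,
                               size = clutch$dispersion)
      fate <- if (n_eggs > 0) egg_fate(titer, model, n_eggs) else character(0)
      nf <- sum(fate == "diploid_female")
      ndm <- sum(fate == "diploid_male")
      nhm <- sum(fate == "haploid_male")
      n_off <- n_off + n_eggs; n_f <- n_f + nf
      n_m <- n_m + ndm + nhm; n_dm <- n_dm + ndm
      nt <- stats::rbinom(1L, ndm + nhm, clutch$test_fraction)
      n_tested <- n_tested + nt
      if (nt > 0) {
        n_dm_found <- n_dm_found + stats::rhyper(1L, m = ndm, n = nhm, k = nt)
      }
      extra <- stats::rnbinom(1L, mu = clutch$extra_hosts_mean,
                              size = clutch$dispersion)
      fe <- stats::rbinom(1L, extra, clutch$fly_emerge_p)
      flies_e <- flies_e + fe; flies_u <- flies_u + (extra - fe)
    }
    tibble::tibble(dose = titer_map$dose[i], n_mothers = nm,
                   n_offspring = n_off, n_female = n_f, n_male = n_m,
                   n_males_tested = n_tested,
                   n_diploid_males_found = n_dm_found,
                   n_flies_emerged = flies_e, n_flies_unemerged = flies_u)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dose_response_table", class(out))
  out
}

#' Classify the thelytoky mechanism from a dose-response table
#'
#' Diploid males found at intermediate titers are the signature of a
#' two-step mechanism with separated diploidization and feminization
#' thresholds. If no diploid males are found, the data are compatible with
#' a one-step mechanism (diploidy suffices for female development) *or* a
#' two-step mechanism whose thresholds coincide — the two cannot be told
#' apart by titer manipulation, so a joint verdict is returned. The
#' rejection of the separated two-step alternative is quantified by the
#' probability of finding zero diploid males among the males tested from
#' mixed-sex broods if a fraction `alternative_d` of them were diploid;
#' when that probability exceeds `alpha`, too few males were tested and the
#' verdict is inconclusive.
#'
#' @param table A `dose_response_table` (or data frame with its columns).
#' @param alpha Significance level for the zero-diploid probability.
#' @param alternative_d Diploid fraction among mixed-brood males under the
#'   separated two-step alternative (default 0.5, a moderate alternative;
#'   a sharp separated two-step would make nearly all such males diploid).
#' @return Object of class `mechanism_verdict`: list with `verdict` (one of
#'   `"two_step_separated"`, `"one_step_or_coincident"`, `"inconclusive"`),
#'   `n_diploid_found`, `n_tested_intermediate` (tested males from
#'   mixed-sex broods), `p_zero_under_alternative`, `alpha`,
#'   `alternative_d`.
#' @export
classify_mechanism <- function(table, alpha = 0.05, alternative_d = 0.5) {
  need <- c("dose", "n_offspring", "n_male", "n_males_tested",
            "n_diploid_males_found")
  if (nrow(table) == 0L) stop("empty dose-response table", call. = FALSE)
  if (!all(need %in% names(table))) {
    stop("table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  }
  if (sum(table$n_males_tested) == 0L) {
    stop("no males tested for ploidy", call. = FALSE)
  }
  n_dip <- sum(table$n_diploid_males_found)
  mixed <- table$n_male > 0L & table$n_male < table$n_offspring
  n_int <- sum(table$n_males_tested[mixed])
  p_zero <- zero_diploid_probability(n_int, alternative_d)
  verdict <- if (n_dip > 0L) {
    "two_step_separated"
  } else if (p_zero <= alpha) {
    "one_step_or_coincident"
  } else {
    "inconclusive"
  }
  structure(
    list(verdict = verdict, n_diploid_found = n_dip,
         n_tested_intermediate = n_int,
         p_zero_under_alternative = p_zero, alpha = alpha,
         alternative_d = alternative_d),
    class = "mechanism_verdict"
  )
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("Mechanism verdict:", x$verdict, "\n")
  cat("  diploid males found:", x$n_diploid_found,
      "| males tested from mixed broods:", x$n_tested_intermediate, "\n")
  cat("  P(zero diploid males | separated two-step, d = ", x$alternative_d,
      ") = ", format(x$p_zero_under_alternative, digits = 3),
      " (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}
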