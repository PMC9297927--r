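#' Configuration of a synthetic inbreeding experiment
#'
#' Describes the generative conditions for a synthetic brood-record dataset
#' mirroring the structure of a multi-generation inbreeding experiment with
#' matched controls: families followed along a cross scheme, several
#' recorded mothers per family per generation, a fraction of set-up females
#' that remain unmated (producing all-male broods), brood sizes and
#' fertilization from the brood model, optional true CSD (to test
#' detection) and optional inbreeding-depression mortality on diploid
#' females.
#'
#' @param scheme A [cross_scheme()] (default the mother-son-first preset).
#' @param csd A [csd_params()]; the default disables CSD, the null the
#'   study species follow.
#' @param n_families Families (independent lineages) per group.
#' @param n_mothers_per_family Females set up per family per generation.
#' @param p_unmated_inbred,p_unmated_control Probability a set-up female
#'   remains unmated; defaults are the study-scale all-male brood rates
#'   (45% inbred, 61% control).
#' @param brood A [brood_model()] for brood size and fertilization.
#' @param female_survival_multiplier Per-inbred-generation geometric
#'   survival multiplier on diploid females (1 = no inbreeding
#'   depression); at inbred generation g, a daughter survives to adulthood
#'   with probability `multiplier^g`. Dead daughters are counted as
#'   non-emerged pupae and, in dissected broods, as dead female wasps.
#' @param extra_hosts_mean Mean unparasitized hosts per brood (negative
#'   binomial, dispersion 5); these emerge as flies or die as pupae.
#' @param fly_emerge_p Probability an unparasitized host emerges as a fly.
#' @param dissect_fraction Fraction of broods whose non-emerged pupae are
#'   dissected and the dead wasps sexed.
#' @param n_males_tested_per_generation Male adults flow-cytometry tested
#'   for ploidy per group and generation (capped by availability).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(scheme = cross_scheme_preset("heterotoma"),
                              csd = csd_params(1L, csd_enabled = FALSE),
                              n_families = 25L,
                              n_mothers_per_family = 3L,
                              p_unmated_inbred = 0.45,
                              p_unmated_control = 0.61,
                              brood = brood_model(),
                              female_survival_multiplier = 1,
                              extra_hosts_mean = 10,
                              fly_emerge_p = 0.95,
                              dissect_fraction = 0.4,
                              n_males_tested_per_generation = 40L) {
  stopifnot(inherits(scheme, "cross_scheme"), inherits(csd, "csd_params"),
            inherits(brood, "brood_model"),
            n_families >= 1, n_mothers_per_family >= 1,
            p_unmated_inbred >= 0, p_unmated_inbred <= 1,
            p_unmated_control >= 0, p_unmated_control <= 1,
            female_survival_multiplier > 0, female_survival_multiplier <= 1,
            extra_hosts_mean >= 0, fly_emerge_p >= 0, fly_emerge_p <= 1,
            dissect_fraction >= 0, dissect_fraction <= 1,
            n_males_tested_per_generation >= 0)
  structure(
    list(scheme = scheme, csd = csd,
         n_families = as.integer(n_families),
         n_mothers_per_family = as.integer(n_mothers_per_family),
         p_unmated_inbred = p_unmated_inbred,
         p_unmated_control = p_unmated_control,
         brood = brood,
         female_survival_multiplier = female_survival_multiplier,
         extra_hosts_mean = extra_hosts_mean, fly_emerge_p = fly_emerge_p,
         dissect_fraction = dissect_fraction,
         n_males_tested_per_generation =
           as.integer(n_males_tested_per_generation)),
    class = "experiment_config"
  )
}

# record bookkeeping for one set-up mother; returns the record row and the
# brood (NULL brood if unmated -> all haploid sons)
.synth_brood_row <- function(mother_mat, father_vec, mated, config, group,
                             gen_label, inbred_gen, mother_id) {
  bp <- draw_brood_params(config$brood)
  csd <- config$csd
  if (mated) {
    b <- .produce_brood_fast(mother_mat, father_vec, bp$n, bp$f, csd)
  } else {
    b <- .produce_brood_fast(mother_mat, father_vec, bp$n, 0, csd)
  }
  # inbreeding depression: each daughter survives with prob mult^g
  surv_p <- if (group == "inbred" && inbred_gen > 0) {
    config$female_survival_multiplier^inbred_gen
  } else 1
  is_f <- b$sex == "female" & b$viable
  died <- is_f & (stats::runif(b$n) >= surv_p)
  alive <- b$viable & !died
  nf <- sum(b$sex == "female" & alive)
  nm <- sum(b$sex != "female" & alive)
  n_dead_wasps <- sum(died) + sum(!b$viable)  # incl. inviable diploid males
  extra <- stats::rnbinom(1L, mu = config$extra_hosts_mean, size = 5)
  flies <- stats::rbinom(1L, extra, config$fly_emerge_p)
  dissected <- n_dead_wasps > 0 && stats::runif(1L) < config$dissect_fraction
  row <- tibble::tibble(
    mother_id = mother_id, group = group, generation = gen_label,
    n_female_adults = nf, n_male_adults = nm,
    n_flies_emerged = flies,
    n_fly_pupae_unemerged = (extra - flies) + n_dead_wasps,
    n_hosts = b$n + extra,
    n_dead_wasps_female = if (dissected) sum(died) else NA_integer_,
    n_dead_wasps_male = if (dissected) sum(!b$viable) else NA_integer_
  )
  b$alive <- alive
  b$mother_mat <- mother_mat
  list(row = row, brood = b)
}

#' Generate a synthetic inbreeding brood-record dataset
#'
#' Simulates, genotype-explicitly, the full inbreeding experiment: per
#' family, an outcross generation followed by the scheme's inbreeding
#' crosses for the inbred group, and fresh outcrosses to unrelated males
#' every generation for the control group. Each generation sets up several
#' females per family; each is unmated with the group's probability and
#' then produces an all-male brood. Offspring sexes follow the configured
#' CSD rule, so embedding `csd_params(1)` yields detectable diploid males
#' while the disabled-CSD default reproduces the null. A flow-cytometry
#' style ploidy subsample of male adults is drawn per group and generation.
#'
#' Lineages end when no mated brood with both a surviving daughter and a
#' haploid son is available, so sample sizes decline over generations as in
#' real experiments.
#'
#' @param config An [experiment_config()].
#' @param seed Optional integer seed.
#' @return List with:
#'   * `records`: brood table (one row per set-up mother) with the schema
#'     `mother_id, group, generation, n_female_adults, n_male_adults,
#'     n_flies_emerged, n_fly_pupae_unemerged, n_hosts,
#'     n_dead_wasps_female, n_dead_wasps_male`;
#'   * `ploidy_tests`: tibble `group, generation, n_males_available,
#'     n_males_tested, n_diploid_found`;
#'   * `config`: the configuration used.
#' @examples
#' d <- generate_inbreeding_dataset(
#'   experiment_config(n_families = 4, scheme = cross_scheme_preset(
#'     "heterotoma", n_bs = 1)), seed = 1)
#' head(d$records)
#' @export
generate_inbreeding_dataset <- function(config = experiment_config(),
                                        seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(seed)) set.seed(seed)
  scheme <- config$scheme
  csd <- config$csd
  k <- csd$n_loci
  n_gen <- length(scheme$steps)
  rows <- list()
  # ploidy bookkeeping: males available and diploid among them
  ploidy <- list()
  add_ploidy <- function(group, gen, nm, ndm) {
    key <- paste(group, gen, sep = "|")
    cur <- ploidy[[key]]
    if (is.null(cur)) cur <- c(males = 0L, dm = 0L)
    ploidy[[key]] <<- cur + c(males = nm, dm = ndm)
  }
  novel_allele <- 4L  # 1,2 founders; 3 = F0 sire; controls draw fresh labels

  for (group in c("inbred", "control")) {
    p_unmated <- if (group == "inbred") config$p_unmated_inbred else
      config$p_unmated_control
    for (fam in seq_len(config$n_families)) {
      # founding mothers: fully heterozygous A/B, sires C (outcross step)
      mothers <- replicate(config$n_mothers_per_family,
                           list(mat = cbind(rep(1L, k), rep(2L, k)),
                                sire = rep(3L, k)), simplify = FALSE)
      inbred_gen <- 0L
      for (j in seq_len(n_gen)) {
        step <- scheme$steps[j]
        gen_label <- scheme$generation[j]
        if (group == "inbred" && step != "outcross") {
          inbred_gen <- inbred_gen + 1L
        }
        broods <- list()
        for (mi in seq_along(mothers)) {
          mated <- stats::runif(1L) >= p_unmated
          res <- .synth_brood_row(
            mothers[[mi]]$mat, mothers[[mi]]$sire, mated, config, group,
            gen_label, inbred_gen,
            sprintf("%s-%s-f%02d-m%d", substr(group, 1, 3),
                    gsub(" ", "", gen_label), fam, mi))
          rows[[length(rows) + 1L]] <- res$row
          b <- res$brood
          if (mated) {
            # ploidy screening draws on daughter-producing broods' males
            add_ploidy(group, gen_label,
                       sum(b$sex != "female" & b$alive),
                       sum(b$sex == "diploid_male" & b$alive))
            broods[[length(broods) + 1L]] <- b
          }
        }
        if (j == n_gen) break
        # set up the next generation's mothers from this generation's broods;
        # control females are always mated to unrelated stock males carrying
        # novel alleles, whatever the inbred group's cross type is
        next_step <- scheme$steps[j + 1L]
        if (group == "control" && next_step == "mother_son") {
          # the same control mothers are remated to fresh stock males
          mothers <- lapply(mothers, function(mo) {
            a <- novel_allele; novel_allele <<- novel_allele + 1L
            list(mat = mo$mat, sire = rep(a, k))
          })
        } else if (next_step == "mother_son") {
          # each mother is remated to one of her own sons
          usable <- Filter(function(b) any(b$sex == "haploid_male" & b$alive),
                           broods)
          if (length(usable) == 0L) { mothers <- list(); break }
          mothers <- lapply(seq_len(config$n_mothers_per_family),
                            function(mi) {
            b <- usable[[((mi - 1L) %% length(usable)) + 1L]]
            sons <- which(b$sex == "haploid_male" & b$alive)
            s <- if (length(sons) == 1L) sons else sample(sons, 1L)
            list(mat = b$mother_mat, sire = b$maternal[, s])
          })
        } else {
          ok <- vapply(broods, function(b) {
            has_d <- any(b$sex == "female" & b$alive)
            has_s <- any(b$sex == "haploid_male" & b$alive)
            if (group == "control") has_d else has_d && has_s
          }, logical(1))
          if (!any(ok)) { mothers <- list(); break }
          b <- broods[[if (sum(ok) == 1L) which(ok) else
            sample(which(ok), 1L)]]
          sons <- which(b$sex == "haploid_male" & b$alive)
          daughters <- which(b$sex == "female" & b$alive)
          mothers <- lapply(seq_len(config$n_mothers_per_family),
                            function(mi) {
            d <- if (length(daughters) == 1L) daughters else
              sample(daughters, 1L)
            mat <- cbind(b$maternal[, d], b$paternal)
            swap <- mat[, 1L] > mat[, 2L]
            if (any(swap)) mat[swap, ] <- mat[swap, 2:1, drop = FALSE]
            sire <- if (group == "control") {
              a <- novel_allele; novel_allele <<- novel_allele + 1L
              rep(a, k)
            } else {
              s <- if (length(sons) == 1L) sons else sample(sons, 1L)
              b$maternal[, s]
            }
            list(mat = mat, sire = sire)
          })
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  ploidy_tests <- do.call(rbind, lapply(names(ploidy), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    avail <- ploidy[[key]][["males"]]
    dm <- ploidy[[key]][["dm"]]
    nt <- min(avail, config$n_males_tested_per_generation)
    found <- if (nt > 0) stats::rhyper(1L, m = dm, n = avail - dm, k = nt)
             else 0L
    tibble::tibble(group = parts[1L], generation = parts[2L],
                   n_males_available = avail, n_diploid_available = dm,
                   n_males_tested = nt, n_diploid_found = found)
  }))
  list(records = records, ploidy_tests = ploidy_tests, config = config)
}

#' Generate a synthetic qPCR titer dataset
#'
#' Individual titers are lognormal around a decreasing logistic mean curve
#' in log dose (control doses sit at the plateau); each individual is
#' reported as a pair of relative DNA quantities whose doubled ratio
#' recovers the titer, with an arbitrary per-sample scale (qPCR quantities
#' are only relatively quantified).
#'
#' @param titer_map A [dose_titer_map()]-shaped tibble; set its `log_sd`
#'   to 0 for noiseless titers exactly on the curve.
#' @param n_per_dose Individuals per dose.
#' @param seed Optional integer seed.
#' @return Tibble with `individual_id`, `dose`, `gssb_quantity`,
#'   `ef1a_quantity`.
#' @export
generate_qpcr_dataset <- function(titer_map = dose_titer_map(),
                                  n_per_dose = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(titer_map)), function(i) {
    titer <- stats::rlnorm(n_per_dose,
                           meanlog = log(max(titer_map$mean_titer[i], 1e-12)),
                           sdlog = titer_map$log_sd[i])
    scale_ <- stats::rlnorm(n_per_dose, 0, 0.25)  # arbitrary per-sample scale
    tibble::tibble(
      individual_id = sprintf("d%s-%02d", format(titer_map$dose[i]),
                              seq_len(n_per_dose)),
      dose = titer_map$dose[i],
      gssb_quantity = titer * scale_ / 2,
      ef1a_quantity = scale_
    )
  })
  do.call(rbind, rows)
}

#' Generate a synthetic dose-response dataset
#'
#' Thin wrapper over [simulate_dose_response()] returning the table shaped
#' like a published antibiotic dose-response experiment.
#'
#' @inheritParams simulate_dose_response
#' @return A `dose_response_table` tibble.
#' @export
generate_dose_response_dataset <- function(model = mechanism_model("one_step"),
                                           titer_map = dose_titer_map(),
                                           clutch = clutch_model(),
                                           n_mothers = 5L, seed = NULL) {
  simulate_dose_response(model, titer_map, clutch, n_mothers, seed)
}
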