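test_that("all-male classification distinguishes no-offspring broods", {
  rec <- tibble::tibble(n_female_adults = c(0L, 1L, 0L),
                        n_male_adults = c(7L, 30L, 0L))
  expect_identical(classify_all_male(rec), c(TRUE, FALSE, FALSE))
  expect_identical(brood_category(rec),
                   c("all_male", "with_females", "no_offspring"))
})

test_that("published all-male brood counts are reproduced", {
  lh_inbred <- broods_from_counts("inbred", 350, 781 - 350)
  pr <- all_male_proportion(lh_inbred)
  expect_equal(pr$numerator, 350)
  expect_equal(pr$denominator, 781)
  expect_equal(round(100 * pr$proportion), 45)
  lc_inbred <- broods_from_counts("inbred", 762, 1054 - 762)
  expect_equal(round(100 * all_male_proportion(lc_inbred)$proportion), 72)
  lh_control <- broods_from_counts("control", 343, 559 - 343)
  expect_equal(round(100 * all_male_proportion(lh_control)$proportion), 61)
  lc_control <- broods_from_counts("control", 704, 783 - 704)
  expect_equal(round(100 * all_male_proportion(lc_control)$proportion), 90)
  # inbred vs control proportions differ strongly in both species
  expect_lt(compare_proportions(all_male_proportion(lh_inbred),
                                all_male_proportion(lh_control)), 1e-4)
  expect_lt(compare_proportions(all_male_proportion(lc_inbred),
                                all_male_proportion(lc_control)), 1e-4)
})

test_that("exclusion keeps every daughter-producing brood and is idempotent", {
  rec <- broods_from_counts("inbred", 10, 20)
  rec$n_female_adults[25] <- 0L; rec$n_male_adults[25] <- 0L  # no offspring
  kept <- exclude_all_male(rec)
  expect_true(all(kept$n_female_adults >= 1))
  log <- attr(kept, "exclusion_log")
  expect_equal(nrow(kept) + nrow(log), nrow(rec))
  expect_equal(sum(log$category == "no_offspring"), 1)
  again <- exclude_all_male(kept)
  expect_equal(nrow(again), nrow(kept))
  expect_equal(nrow(exclude_all_male(rec[0, ])), 0)
})

test_that("sex ratios pool or average per brood", {
  rec <- tibble::tibble(n_female_adults = c(7L, 5L, 0L),
                        n_male_adults = c(3L, 5L, 4L))
  pooled <- sex_ratio(rec, "pooled")
  expect_equal(pooled$proportion, 12 / 24)
  per <- sex_ratio(rec, "per_brood_mean")
  expect_equal(per$mean, mean(c(0.3, 0.5, 1)))
  expect_equal(per$n_broods, 3)
  # pooled ratio lies between per-brood extremes
  expect_gte(pooled$proportion, 0.3)
  expect_lte(pooled$proportion, 1)
  all_f <- tibble::tibble(n_female_adults = 5L, n_male_adults = 0L)
  expect_equal(sex_ratio(all_f, "pooled")$proportion, 0)
  none <- tibble::tibble(n_female_adults = 0L, n_male_adults = 0L)
  expect_error(sex_ratio(none), "no adult wasps")
})

test_that("emergence proportions partition host outcomes", {
  rec <- tibble::tibble(n_female_adults = c(8L, 0L, 0L),
                        n_male_adults = c(0L, 0L, 3L),
                        n_flies_emerged = c(1L, 5L, 0L),
                        n_fly_pupae_unemerged = c(1L, 0L, 0L),
                        n_hosts = c(12L, 5L, 3L))
  em <- emergence_proportions(rec)
  expect_equal(em$adult_wasp_proportion, c(0.8, 0, 1))
  expect_equal(em$non_emerged_pupa_proportion, c(0.1, 0, 0))
  emh <- emergence_proportions(rec, denominator = "hosts")
  expect_equal(emh$adult_wasp_proportion[1], 8 / 12)
  zero <- tibble::tibble(n_female_adults = 0L, n_male_adults = 0L,
                         n_flies_emerged = 0L, n_fly_pupae_unemerged = 0L)
  expect_true(is.na(emergence_proportions(zero)$adult_wasp_proportion))
})

test_that("proportion comparisons are exact, symmetric, and match asymptotics", {
  a <- proportion_result(350, 781); b <- proportion_result(343, 559)
  expect_equal(compare_proportions(a, b), compare_proportions(b, a))
  expect_lt(compare_proportions(a, b), 1e-4)
  expect_equal(compare_proportions(a, a), 1)
  # exact and normal tests agree within 10% for large balanced samples
  c1 <- proportion_result(1000, 2000); c2 <- proportion_result(1060, 2000)
  p_exact <- compare_proportions(c1, c2)
  p_norm <- compare_proportions(c1, c2, method = "normal")
  expect_lt(abs(p_exact - p_norm) / p_norm, 0.10)
})

test_that("dead-wasp sexing pools to the published female fraction", {
  rec <- tibble::tibble(
    n_female_adults = rep(1L, 43), n_male_adults = rep(1L, 43),
    n_dead_wasps_female = c(rep(12L, 43))[1:43],
    n_dead_wasps_male = rep(2L, 43)
  )
  # scale one fixture to exactly 520 females / 85 males over 43 broods
  rec$n_dead_wasps_female <- c(rep(12L, 42), 16L)
  rec$n_dead_wasps_male <- c(rep(2L, 42), 1L)
  pr <- dead_wasp_female_proportion(rec)
  expect_equal(pr$numerator, 520)
  expect_equal(pr$denominator, 605)
  expect_equal(round(100 * pr$proportion), 86)
  # equals the count-weighted mean of per-brood fractions
  w <- rec$n_dead_wasps_female + rec$n_dead_wasps_male
  expect_equal(pr$proportion,
               sum(w * (rec$n_dead_wasps_female / w)) / sum(w))
  none <- tibble::tibble(n_dead_wasps_female = NA_integer_,
                         n_dead_wasps_male = NA_integer_)
  expect_error(dead_wasp_female_proportion(none), "no dissection")
})

test_that("zero-diploid probability is multiplicative and monotone", {
  expect_equal(zero_diploid_probability(0, 0.5), 1)
  expect_equal(zero_diploid_probability(17, 0), 1)
  expect_equal(zero_diploid_probability(3, 1), 0)
  # multiplicative over independent batches
  expect_equal(zero_diploid_probability(c(10, 20), c(0.2, 0.3)),
               zero_diploid_probability(10, 0.2) *
                 zero_diploid_probability(20, 0.3))
  # monotone decreasing in n and d
  expect_gt(zero_diploid_probability(10, 0.3),
            zero_diploid_probability(11, 0.3))
  expect_gt(zero_diploid_probability(10, 0.3),
            zero_diploid_probability(10, 0.31))
  # log-domain agreement at the study's scale
  p <- zero_diploid_probability(80, 0.5)
  p_log <- exp(80 * log1p(-0.5))
  expect_lt(abs(p - p_log) / p_log, 1e-12)
  expect_lt(p, 1e-20)
})

test_that("detection power from simulation behaves sensibly", {
  sch <- cross_scheme_preset("heterotoma", n_bs = 1)
  # no CSD: the power statistic is identically 1
  s0 <- run_simulation(sch, csd_params(1, csd_enabled = FALSE),
                       brood_model(), 300, seed = 21)
  expect_equal(power_from_simulation(s0, c("M-S" = 80))$p_zero, 1)
  # sl-CSD: testing 80 males after M-S makes zero diploids very unlikely
  s1 <- run_simulation(sch, csd_params(1), brood_model(), 300, seed = 21)
  pw <- power_from_simulation(s1, c("M-S" = 80))
  expect_lt(pw$p_zero, 0.001)
  # monotone decreasing in the number tested
  pw_small <- power_from_simulation(s1, c("M-S" = 5))
  expect_gt(pw_small$p_zero, pw$p_zero)
  expect_error(power_from_simulation(s1, c(40)), "named")
  expect_error(power_from_simulation(s1, c("B-S 9" = 40)), "named")
})
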