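test_that("relative titer handles both input forms consistently", {
  expect_equal(relative_titer(gssb_quantity = 3, ef1a_quantity = 3), 2)
  expect_equal(relative_titer(ct_gssb = 21, ct_ef1a = 21), 2)
  # delta-Ct of 1.63 at perfect doubling lands in the untreated-female range
  expect_equal(relative_titer(ct_gssb = 20, ct_ef1a = 21.63),
               2 * 2^1.63, tolerance = 1e-12)
  expect_gt(relative_titer(ct_gssb = 20, ct_ef1a = 21.63), 6.1)
  expect_lt(relative_titer(ct_gssb = 20, ct_ef1a = 21.63), 6.4)
  # scale invariance
  set.seed(1)
  g <- runif(20, 0.1, 5); e <- runif(20, 0.1, 5); c_ <- runif(20, 0.5, 10)
  expect_equal(relative_titer(g * c_, e * c_), relative_titer(g, e))
  expect_error(relative_titer(gssb_quantity = 1, ef1a_quantity = 0), "> 0")
  expect_error(relative_titer(ct_gssb = -1, ct_ef1a = 2), ">= 0")
  expect_error(relative_titer(gssb_quantity = 1, ef1a_quantity = 1,
                              ct_gssb = 1, ct_ef1a = 1), "not both")
})

test_that("egg fates follow the threshold logic", {
  one <- mechanism_model("one_step", t_dip = 1, s_dip = Inf)
  two <- mechanism_model("two_step", t_dip = 0.5, s_dip = Inf,
                         t_fem = 2.5, s_fem = Inf)
  # titer 0 never diploidizes
  expect_true(all(egg_fate(0, one, 50) == "haploid_male"))
  expect_equal(expected_category_fractions(0, two)$p_haploid_male, 1)
  # sharp two-step window: everything is a diploid male
  expect_true(all(egg_fate(1, two, 50) == "diploid_male"))
  win <- expected_category_fractions(c(0.4, 1, 3), two)
  expect_equal(win$p_diploid_male, c(0, 1, 0))
  # one-step can never make diploid males
  set.seed(4)
  expect_false(any(egg_fate(5, one, 200) == "diploid_male"))
  expect_equal(expected_category_fractions(c(0, 0.5, 2, 8),
                                           one)$p_diploid_male,
               rep(0, 4))
})

test_that("category fractions sum to one and match Monte Carlo", {
  set.seed(11)
  for (i in 1:10) {
    m <- mechanism_model(sample(c("one_step", "two_step"), 1),
                         t_dip = runif(1, 0.5, 4), s_dip = runif(1, 1, 8),
                         t_fem = runif(1, 0.5, 4), s_fem = runif(1, 1, 8))
    tt <- runif(1, 0, 8)
    p <- expected_category_fractions(tt, m)
    expect_equal(p$p_haploid_male + p$p_diploid_male + p$p_diploid_female, 1,
                 tolerance = 1e-12)
  }
  m <- mechanism_model("two_step", t_dip = 1, s_dip = 3, t_fem = 2, s_fem = 3)
  p <- expected_category_fractions(1.5, m)
  draws <- egg_fate(1.5, m, 1e5)
  for (cat_ in c("haploid_male", "diploid_male", "diploid_female")) {
    expected <- switch(cat_, haploid_male = p$p_haploid_male,
                       diploid_male = p$p_diploid_male,
                       diploid_female = p$p_diploid_female)
    expect_lt(abs(mean(draws == cat_) - expected), 3 * sqrt(0.25 / 1e5))
  }
})

test_that("dose-response simulation matches its closed form and is monotone", {
  m <- mechanism_model("one_step", t_dip = 2, s_dip = 5)
  # single dose, fixed titer (log_sd 0): aggregated sex fractions match
  tm <- tibble::tibble(dose = 0.2, mean_titer = 2, log_sd = 0)
  tab <- simulate_dose_response(m, tm, clutch_model(mean_offspring = 50),
                                n_mothers = 50, seed = 8)
  p_fem_exp <- expected_category_fractions(2, m)$p_diploid_female
  n <- tab$n_offspring
  expect_lt(abs(tab$n_female / n - p_fem_exp), 3 * sqrt(0.25 / n))
  # female proportion is non-decreasing in titer
  tm2 <- tibble::tibble(dose = c(1, 0.3, 0.1, 0), mean_titer = c(0.2, 1, 3, 8),
                        log_sd = 0)
  tab2 <- simulate_dose_response(m, tm2, clutch_model(mean_offspring = 80),
                                 n_mothers = 30, seed = 9)
  fr <- tab2$n_female / tab2$n_offspring
  expect_true(all(diff(fr) >= 0))
  # extreme titers: all-female at the plateau, all-male when cured
  expect_equal(fr[1], 0)
  expect_gt(fr[4], 0.99)
  # bookkeeping invariants
  expect_true(all(tab2$n_female + tab2$n_male == tab2$n_offspring))
  expect_true(all(tab2$n_diploid_males_found <= tab2$n_males_tested))
  expect_true(all(tab2$n_males_tested <= tab2$n_male))
})

test_that("the observed dose-response table classifies as one-step/coincident", {
  tab <- read_dose_response_csv(observed_dose_response_path())
  v <- classify_mechanism(tab)
  expect_identical(v$verdict, "one_step_or_coincident")
  expect_identical(v$n_diploid_found, 0L)
  # mixed-sex broods contributed 98 tested males, all haploid
  expect_equal(v$n_tested_intermediate, 98)
  expect_equal(v$p_zero_under_alternative, 0.5^98)
  # the 0.25 mg/g row shows the 65% male transition
  r <- tab[tab$dose == 0.25, ]
  expect_equal(round(100 * r$n_male / r$n_offspring), 65)
})

test_that("classification handles the other verdicts and degenerate input", {
  base <- tibble::tibble(dose = c(0, 0.3, 1), n_mothers = 3,
                         n_offspring = c(40L, 40L, 40L),
                         n_female = c(40L, 20L, 0L),
                         n_male = c(0L, 20L, 40L),
                         n_males_tested = c(0L, 10L, 10L),
                         n_diploid_males_found = c(0L, 3L, 0L),
                         n_flies_emerged = 5L, n_flies_unemerged = 1L)
  expect_identical(classify_mechanism(base)$verdict, "two_step_separated")
  # two tested males and none diploid cannot reject the alternative
  small <- base
  small$n_diploid_males_found <- 0L
  small$n_males_tested <- c(0L, 2L, 0L)
  v <- classify_mechanism(small, alpha = 0.05)
  expect_identical(v$verdict, "inconclusive")
  expect_equal(v$p_zero_under_alternative, 0.25)
  expect_error(classify_mechanism(base[0, ]), "empty")
  none <- base; none$n_males_tested <- 0L; none$n_diploid_males_found <- 0L
  expect_error(classify_mechanism(none), "no males tested")
})

test_that("mechanism recovery works across seeds", {
  # scaled-down version of the full recovery property (full strength runs
  # in the acceptance suite)
  one <- mechanism_model("one_step", t_dip = 2, s_dip = 5)
  two <- mechanism_model("two_step", t_dip = 0.4, s_dip = 8,
                         t_fem = 2.5, s_fem = 8)
  verdicts <- vapply(1:40, function(s) {
    t1 <- generate_dose_response_dataset(one, n_mothers = 3, seed = s)
    t2 <- generate_dose_response_dataset(two, n_mothers = 3, seed = 1000 + s)
    c(classify_mechanism(t1)$verdict, classify_mechanism(t2)$verdict)
  }, character(2))
  expect_gte(mean(verdicts[1, ] == "one_step_or_coincident"), 0.95)
  expect_gte(mean(verdicts[2, ] == "two_step_separated"), 0.95)
})
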