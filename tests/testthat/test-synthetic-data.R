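test_that("generated brood records satisfy the schema invariants", {
  cfg <- experiment_config(n_families = 6,
                           scheme = cross_scheme_preset("heterotoma", 2),
                           female_survival_multiplier = 0.9)
  d <- generate_inbreeding_dataset(cfg, seed = 42)
  rec <- d$records
  counts <- c("n_female_adults", "n_male_adults", "n_flies_emerged",
              "n_fly_pupae_unemerged", "n_hosts")
  for (cc in counts) expect_true(all(rec[[cc]] >= 0))
  # dissection counts never exceed the unemerged pupae they came from
  dis <- !is.na(rec$n_dead_wasps_female)
  expect_true(all(rec$n_dead_wasps_female[dis] + rec$n_dead_wasps_male[dis] <=
                    rec$n_fly_pupae_unemerged[dis]))
  expect_setequal(unique(rec$group), c("inbred", "control"))
  expect_true(all(rec$generation %in% cfg$scheme$generation))
  # the CSV dialect round-trips
  tmp <- tempfile(fileext = ".csv")
  write_brood_csv(rec, tmp)
  back <- read_brood_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  unlink(tmp)
})

test_that("universally unmated mothers give only all-male broods", {
  cfg <- experiment_config(n_families = 4, p_unmated_inbred = 1,
                           p_unmated_control = 1,
                           scheme = cross_scheme_preset("clavipes", 1))
  d <- generate_inbreeding_dataset(cfg, seed = 5)
  cat_ <- brood_category(d$records)
  expect_true(all(cat_ %in% c("all_male", "no_offspring")))
})

test_that("the null generator shows no inbred-control sex-ratio difference", {
  cfg <- experiment_config(
    n_families = 60, csd = csd_params(1, csd_enabled = FALSE),
    female_survival_multiplier = 1,
    scheme = cross_scheme_preset("heterotoma", 3))
  d <- generate_inbreeding_dataset(cfg, seed = 301)
  expect_true(all(d$ploidy_tests$n_diploid_found == 0))
  kept <- exclude_all_male(d$records)
  r <- kept$n_male_adults / (kept$n_male_adults + kept$n_female_adults)
  p <- stats::wilcox.test(r[kept$group == "inbred"],
                          r[kept$group == "control"])$p.value
  expect_gt(p, 0.01)
})

test_that("embedded single-locus CSD produces detectable diploid males", {
  cfg <- experiment_config(
    n_families = 40, csd = csd_params(1, csd_enabled = TRUE),
    scheme = cross_scheme_preset("heterotoma", 2))
  d <- generate_inbreeding_dataset(cfg, seed = 99)
  pt <- d$ploidy_tests
  inb <- pt[pt$group == "inbred" & pt$generation != "outcross", ]
  expect_gt(sum(inb$n_diploid_found), 0)
  # diploid fraction among inbred males tracks the pedigree expectation:
  # p_hom = 1/2 among fertilized eggs, fertilization ~ Beta(13, 7)
  f <- 13 / 20
  d_exp <- 0.5 * f / (1 - f + 0.5 * f)
  n <- sum(inb$n_males_tested)
  d_hat <- sum(inb$n_diploid_found) / n
  expect_lt(abs(d_hat - d_exp), 3 * sqrt(d_exp * (1 - d_exp) / n))
  # controls stay free of diploid males (outbred sires carry novel alleles)
  ctrl <- pt[pt$group == "control", ]
  expect_equal(sum(ctrl$n_diploid_found), 0)
})

test_that("qPCR generator puts noiseless titers exactly on the curve", {
  tm <- dose_titer_map(log_sd = 0)
  q <- generate_qpcr_dataset(tm, n_per_dose = 3, seed = 2)
  titer <- relative_titer(gssb_quantity = q$gssb_quantity,
                          ef1a_quantity = q$ef1a_quantity)
  expect_equal(titer, rep(tm$mean_titer, each = 3), tolerance = 1e-9)
  # mean titer decreases with dose
  expect_true(all(diff(tm$mean_titer[order(tm$dose)]) <= 0))
  # with noise, high-dose groups are distinguishable by rank test
  qn <- generate_qpcr_dataset(dose_titer_map(), n_per_dose = 10, seed = 3)
  tn <- relative_titer(gssb_quantity = qn$gssb_quantity,
                       ef1a_quantity = qn$ef1a_quantity)
  grp <- factor(qn$dose)
  kw <- stats::kruskal.test(tn, grp)
  expect_lt(kw$p.value, 1e-6)
  lo <- tn[qn$dose == 0]; hi <- tn[qn$dose == 1]
  expect_lt(stats::wilcox.test(lo, hi)$p.value, 1e-3)
})

test_that("dose-response generator round-trips through its CSV dialect", {
  tab <- generate_dose_response_dataset(mechanism_model("one_step"),
                                        n_mothers = 3, seed = 12)
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE)
  back <- read_dose_response_csv(tmp)
  expect_equal(as.data.frame(back)[names(tab)], as.data.frame(tab))
  unlink(tmp)
})

test_that("generators are reproducible under a seed", {
  d1 <- generate_inbreeding_dataset(experiment_config(n_families = 3),
                                    seed = 7)
  d2 <- generate_inbreeding_dataset(experiment_config(n_families = 3),
                                    seed = 7)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$ploidy_tests, d2$ploidy_tests)
})
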