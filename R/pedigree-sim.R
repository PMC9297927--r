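# Internal genotype coercions: the simulator's hot path keeps a diploid
# mother as a k x 2 integer matrix (rows sorted) and a haploid sire as a
# length-k integer vector.
.as_mother_mat <- function(x) {
  if (inherits(x, "csd_individual")) x <- x$genotype
  if (inherits(x, "csd_genotype")) {
    if (x$ploidy != 2L) stop("mother must be diploid", call. = FALSE)
    return(x$alleles)
  }
  stopifnot(is.matrix(x), ncol(x) == 2L)
  x
}

.as_father_vec <- function(x) {
  if (inherits(x, "csd_individual")) x <- x$genotype
  if (inherits(x, "csd_genotype")) {
    if (x$ploidy != 1L) stop("father must be haploid", call. = FALSE)
    return(x$alleles[, 1L])
  }
  stopifnot(is.numeric(x))
  as.integer(x)
}

#' Founding pair of the F0 outcross
#'
#' Every simulation starts with an outcross between a fully heterozygous
#' female (genotype A/B at every CSD locus) and an unrelated haploid male
#' carrying a novel C allele at every locus, so all diploid F1 offspring are
#' heterozygous (A/C or B/C) at each locus and F1 haploid sons are
#' hemizygous A or B.
#'
#' @param csd A [csd_params()].
#' @return List with `mother` and `father` as `csd_individual`s.
#' @examples
#' init_f0(csd_params(2))
#' @export
init_f0 <- function(csd = csd_params(1L)) {
  k <- csd$n_loci
  mother <- individual("F0-mother",
                       genotype(cbind(rep(1L, k), rep(2L, k))), csd)
  father <- individual("F0-father", genotype(rep(3L, k)), csd)
  list(mother = mother, father = father)
}

# Fast brood production on raw matrices. Returns a list with the brood's
# vectorized state; `sex` uses the CSD rule, `viable` drops inviable diploid
# males when requested.
.produce_brood_fast <- function(mother_mat, father_vec, n, f, csd) {
  k <- nrow(mother_mat)
  if (n == 0L) {
    return(list(n = 0L, f = f, fertilized = logical(0),
                maternal = matrix(integer(0), nrow = k), paternal = father_vec,
                sex = character(0), viable = logical(0)))
  }
  fertilized <- stats::runif(n) < f
  pick <- sample.int(2L, k * n, replace = TRUE)
  idx <- rep(seq_len(k), n) + (pick - 1L) * k
  maternal <- matrix(mother_mat[idx], nrow = k)
  sex <- rep("haploid_male", n)
  if (any(fertilized)) {
    if (csd$csd_enabled) {
      hom <- colSums(maternal[, fertilized, drop = FALSE] != father_vec) == 0L
      sex[fertilized] <- ifelse(hom, "diploid_male", "female")
    } else {
      sex[fertilized] <- "female"
    }
  }
  viable <- rep(TRUE, n)
  if (!csd$diploid_male_viable) viable[sex == "diploid_male"] <- FALSE
  list(n = n, f = f, fertilized = fertilized, maternal = maternal,
       paternal = father_vec, sex = sex, viable = viable)
}

#' Produce one brood from a mated pair
#'
#' Draws a brood size and a fertilization proportion from the brood model,
#' then fertilizes each egg independently with that proportion. Fertilized
#' eggs are diploid fusions of a maternal gamete with the sire's genotype;
#' unfertilized eggs develop as haploid males from a maternal gamete alone.
#' Sexes follow the CSD rule; inviable diploid males (if
#' `csd$diploid_male_viable` is `FALSE`) are flagged non-viable.
#'
#' @param mother Diploid `csd_individual`, `csd_genotype`, or k x 2 matrix.
#' @param father Haploid `csd_individual`, `csd_genotype`, or length-k vector.
#' @param brood_model A [brood_model()].
#' @param csd A [csd_params()].
#' @return An object of class `csd_brood`: list with `n` (brood size), `f`
#'   (drawn fertilization), `fertilized` (logical per egg), `maternal`
#'   (k x n matrix of maternal gamete alleles), `paternal` (sire alleles),
#'   `sex` (per egg), `viable` (per egg). A drawn brood size of 0 yields an
#'   empty brood. Uses the current RNG state.
#' @seealso [brood_individuals()] to materialize offspring as
#'   `csd_individual`s.
#' @export
produce_brood <- function(mother, father, brood_model = csdsim::brood_model(),
                          csd = csd_params(1L)) {
  mm <- .as_mother_mat(mother)
  fv <- .as_father_vec(father)
  if (nrow(mm) != length(fv)) stop("parents disagree on k", call. = FALSE)
  if (nrow(mm) != csd$n_loci) stop("parents disagree with csd$n_loci", call. = FALSE)
  bp <- draw_brood_params(brood_model)
  b <- .produce_brood_fast(mm, fv, bp$n, bp$f, csd)
  class(b) <- "csd_brood"
  b
}

#' @export
print.csd_brood <- function(x, ...) {
  cat("Brood of ", x$n, " eggs (fertilization draw ", round(x$f, 3), "): ",
      sum(x$sex == "female"), " female, ",
      sum(x$sex == "haploid_male"), " haploid male, ",
      sum(x$sex == "diploid_male"), " diploid male\n", sep = "")
  invisible(x)
}

#' Materialize brood members as individuals
#'
#' @param brood A `csd_brood`.
#' @param which Indices of brood members (default all).
#' @param csd A [csd_params()] consistent with the brood.
#' @return List of `csd_individual`s.
#' @export
brood_individuals <- function(brood, which = seq_len(brood$n),
                              csd = csd_params(nrow(brood$maternal))) {
  lapply(which, function(j) {
    g <- if (brood$fertilized[j]) {
      genotype(cbind(brood$maternal[, j], brood$paternal))
    } else {
      genotype(brood$maternal[, j], ploidy = 1L)
    }
    individual(paste0("off-", j), g, csd)
  })
}

# indices of the next breeding pair, or NULL on extinction
.next_pair_idx <- function(brood, step) {
  males <- which(brood$sex == "haploid_male" & brood$viable)
  if (length(males) == 0L) return(NULL)
  son <- if (length(males) == 1L) males else sample(males, 1L)
  if (step == "mother_son") return(list(daughter = NA_integer_, son = son))
  daughters <- which(brood$sex == "female" & brood$viable)
  if (length(daughters) == 0L) return(NULL)
  d <- if (length(daughters) == 1L) daughters else sample(daughters, 1L)
  list(daughter = d, son = son)
}

#' Select the next breeding pair from a brood
#'
#' For a mother-son cross the current mother is retained and mated to a
#' haploid son drawn uniformly from her brood; for a brother-sister cross a
#' female and a haploid male are drawn uniformly from the same brood. If no
#' suitable female or haploid male exists the lineage is extinct and `NULL`
#' is returned.
#'
#' @param brood A `csd_brood`.
#' @param step `"mother_son"` or `"brother_sister"`.
#' @param current_mother The brood's mother (any form accepted by
#'   [produce_brood()]); required for `"mother_son"`.
#' @param csd A [csd_params()].
#' @return List with `mother` and `father` as `csd_individual`s, or `NULL`
#'   if the lineage is extinct.
#' @export
next_pair <- function(brood, step = c("mother_son", "brother_sister"),
                      current_mother = NULL,
                      csd = csd_params(nrow(brood$maternal))) {
  step <- match.arg(step)
  idx <- .next_pair_idx(brood, step)
  if (is.null(idx)) return(NULL)
  father <- brood_individuals(brood, idx$son, csd)[[1L]]
  mother <- if (step == "mother_son") {
    if (is.null(current_mother)) {
      stop("`current_mother` is required for a mother-son cross", call. = FALSE)
    }
    if (inherits(current_mother, "csd_individual")) current_mother
    else individual("mother", genotype(.as_mother_mat(current_mother)), csd)
  } else {
    brood_individuals(brood, idx$daughter, csd)[[1L]]
  }
  list(mother = mother, father = father)
}

# canonical strings for the diploid offspring of a brood (genotype
# recording for oracle-equivalence checks)
.diploid_genotype_keys <- function(brood) {
  j <- which(brood$fertilized)
  if (length(j) == 0L) return(character(0))
  lo <- pmin(brood$maternal[, j, drop = FALSE], brood$paternal)
  hi <- pmax(brood$maternal[, j, drop = FALSE], brood$paternal)
  apply(rbind(lo, hi), 2L, function(col) {
    k <- length(col) / 2L
    paste(paste(allele_label(col[seq_len(k)]),
                allele_label(col[k + seq_len(k)]), sep = "/"), collapse = ";")
  })
}

#' Simulate one replicate lineage along a cross scheme
#'
#' Runs a single lineage: the F0 outcross, then the scheme's inbreeding
#' crosses, producing one brood per generation. When a cross cannot be set
#' up (no female or no haploid male available) the lineage is extinct and
#' later generations are flagged accordingly.
#'
#' @param scheme A [cross_scheme()].
#' @param csd A [csd_params()].
#' @param brood_model A [brood_model()].
#' @param record_genotypes If `TRUE`, attach per-generation counts of
#'   diploid offspring genotypes (canonical strings) as attribute
#'   `"genotypes"` for comparison against [enumerate_cross()].
#' @return Tibble with one row per generation: `generation`, `brood_size`,
#'   `fertilization`, `n_female`, `n_haploid_male`, `n_diploid_male` (viable
#'   adults), `osr` (proportion male among adults), `diploid_sr` (proportion
#'   diploid males among diploids; `NA` when no diploids), `extinct`.
#' @export
run_replicate <- function(scheme, csd = csd_params(1L),
                          brood_model = csdsim::brood_model(),
                          record_genotypes = FALSE) {
  core <- .run_replicate_core(scheme, csd, brood_model, record_genotypes)
  res <- tibble::as_tibble(core[setdiff(names(core), "geno")])
  if (record_genotypes) attr(res, "genotypes") <- core$geno
  res
}

.run_replicate_core <- function(scheme, csd, brood_model, record_genotypes) {
  stopifnot(inherits(scheme, "cross_scheme"))
  k <- csd$n_loci
  n_gen <- length(scheme$steps)
  mother_mat <- cbind(rep(1L, k), rep(2L, k))
  father_vec <- rep(3L, k)
  geno <- if (record_genotypes) vector("list", n_gen)
  brood_size <- rep(NA_integer_, n_gen)
  fertilization <- osr <- diploid_sr <- rep(NA_real_, n_gen)
  n_female <- n_haploid_male <- n_diploid_male <- rep(NA_integer_, n_gen)
  extinct <- rep(TRUE, n_gen)
  for (j in seq_len(n_gen)) {
    bp <- draw_brood_params(brood_model)
    b <- .produce_brood_fast(mother_mat, father_vec, bp$n, bp$f, csd)
    nf <- sum(b$sex == "female" & b$viable)
    nhm <- sum(b$sex == "haploid_male" & b$viable)
    ndm <- sum(b$sex == "diploid_male" & b$viable)
    tot <- nf + nhm + ndm
    brood_size[j] <- b$n
    fertilization[j] <- b$f
    n_female[j] <- nf; n_haploid_male[j] <- nhm; n_diploid_male[j] <- ndm
    osr[j] <- if (tot > 0) (nhm + ndm) / tot else NA_real_
    diploid_sr[j] <- if (nf + ndm > 0) ndm / (nf + ndm) else NA_real_
    extinct[j] <- FALSE
    if (record_genotypes) {
      keys <- .diploid_genotype_keys(b)
      geno[[j]] <- if (length(keys)) table(keys) else table(character(0))
    }
    if (j == n_gen) break
    idx <- .next_pair_idx(b, scheme$steps[j + 1L])
    if (is.null(idx)) break
    if (scheme$steps[j + 1L] == "brother_sister") {
      mother_mat <- cbind(b$maternal[, idx$daughter], b$paternal)
      swap <- mother_mat[, 1L] > mother_mat[, 2L]
      if (any(swap)) mother_mat[swap, ] <- mother_mat[swap, 2:1, drop = FALSE]
    }
    father_vec <- b$maternal[, idx$son]
  }
  list(
    generation = scheme$generation,
    brood_size = brood_size, fertilization = fertilization,
    n_female = n_female, n_haploid_male = n_haploid_male,
    n_diploid_male = n_diploid_male, osr = osr, diploid_sr = diploid_sr,
    extinct = extinct, geno = if (record_genotypes) geno
  )
}

#' Replicated pedigree simulation with percentile bands
#'
#' Replicates [run_replicate()] `n_replicates` times and summarizes, per
#' generation, the operational sex ratio (proportion of males, haploid plus
#' diploid, among adults) and the diploid sex ratio (proportion of diploid
#' males among diploid adults), each with a 95% percentile band (2.5 and
#' 97.5 percentiles across replicates). Extinct replicates contribute no
#' ratios from extinction onward; survivorship is reported per generation.
#'
#' Reproducibility: the master `seed` deterministically derives one
#' sub-seed per replicate, so results are identical across runs and
#' insensitive to summary-stage computations.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicate lineages (>= 1).
#' @param seed Integer master seed.
#' @return Object of class `csd_simulation`: list with `summary` (tibble:
#'   `generation`, `n_surviving`, `mean_osr`, `osr_lo`, `osr_hi`,
#'   `mean_diploid_sr`, `dsr_lo`, `dsr_hi`, `n_diploid_defined`),
#'   `replicates` (tibble with a `replicate` column), `scheme`, `csd`,
#'   `brood_model`, `n_replicates`, `seed`, and (when recorded)
#'   `genotype_counts`: per-generation aggregated diploid genotype counts.
#' @examples
#' sim <- run_simulation(cross_scheme_preset("heterotoma", n_bs = 2),
#'                       csd_params(1), brood_model(),
#'                       n_replicates = 200, seed = 42)
#' sim$summary
#' @export
run_simulation <- function(scheme, csd = csd_params(1L),
                           brood_model = csdsim::brood_model(),
                           n_replicates = 10000L, seed = 1L,
                           record_genotypes = FALSE) {
  stopifnot(n_replicates >= 1L)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  reps <- vector("list", n_replicates)
  n_gen <- length(scheme$steps)
  geno_acc <- if (record_genotypes) {
    lapply(seq_len(n_gen), function(j) numeric(0))
  }
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    rr <- .run_replicate_core(scheme, csd, brood_model, record_genotypes)
    if (record_genotypes) {
      for (j in seq_len(n_gen)) {
        tb <- rr$geno[[j]]
        if (is.null(tb) || length(tb) == 0L) next
        v <- geno_acc[[j]]
        for (nm in names(tb)) {
          v[nm] <- (if (is.na(v[nm])) 0 else v[nm]) + tb[[nm]]
        }
        geno_acc[[j]] <- v
      }
    }
    rr$geno <- NULL
    reps[[r]] <- rr
  }
  cols <- setdiff(names(reps[[1L]]), "geno")
  replicates <- tibble::as_tibble(c(
    list(replicate = rep(seq_len(n_replicates), each = n_gen)),
    stats::setNames(lapply(cols, function(cc) {
      unlist(lapply(reps, `[[`, cc), use.names = FALSE)
    }), cols)
  ))
  if (record_genotypes) names(geno_acc) <- scheme$generation
  gens <- scheme$generation
  summ <- do.call(rbind, lapply(gens, function(g) {
    x <- replicates[replicates$generation == g & !replicates$extinct, ]
    osr <- x$osr[!is.na(x$osr)]
    dsr <- x$diploid_sr[!is.na(x$diploid_sr)]
    tibble::tibble(
      generation = g,
      n_surviving = nrow(x),
      mean_osr = if (length(osr)) mean(osr) else NA_real_,
      osr_lo = if (length(osr)) unname(stats::quantile(osr, 0.025)) else NA_real_,
      osr_hi = if (length(osr)) unname(stats::quantile(osr, 0.975)) else NA_real_,
      mean_diploid_sr = if (length(dsr)) mean(dsr) else NA_real_,
      dsr_lo = if (length(dsr)) unname(stats::quantile(dsr, 0.025)) else NA_real_,
      dsr_hi = if (length(dsr)) unname(stats::quantile(dsr, 0.975)) else NA_real_,
      n_diploid_defined = length(dsr)
    )
  }))
  structure(
    list(summary = summ, replicates = replicates, scheme = scheme, csd = csd,
         brood_model = brood_model, n_replicates = n_replicates, seed = seed,
         genotype_counts = geno_acc),
    class = "csd_simulation"
  )
}

#' @export
print.csd_simulation <- function(x, ...) {
  cat("CSD pedigree simulation: scheme '", x$scheme$label, "', k = ",
      x$csd$n_loci, ", ", x$n_replicates, " replicates (seed ", x$seed,
      ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Overlap of observed sex ratios with simulated bands
#'
#' Flags, per generation, whether an observed confidence interval overlaps
#' the simulated 95% percentile band, separately for the operational and
#' the diploid sex ratio. Observed values without an interval are treated
#' as degenerate (point) intervals.
#'
#' @param sim A `csd_simulation`.
#' @param observed Tibble/data frame with column `generation` plus any of
#'   `osr`, `osr_lo`, `osr_hi`, `diploid_sr`, `dsr_lo`, `dsr_hi`.
#'   Generation labels must match the simulation's.
#' @return Tibble with `generation`, `osr_overlap`, `dsr_overlap` (logical,
#'   `NA` where either side is undefined).
#' @export
compare_to_observed <- function(sim, observed) {
  stopifnot(inherits(sim, "csd_simulation"))
  if (!all(observed$generation %in% sim$summary$generation)) {
    stop("observed generation labels do not match the simulation",
         call. = FALSE)
  }
  s <- sim$summary[match(observed$generation, sim$summary$generation), ]
  grab <- function(df, main, lo, hi) {
    m <- if (main %in% names(df)) df[[main]] else rep(NA_real_, nrow(df))
    l <- if (lo %in% names(df)) df[[lo]] else m
    h <- if (hi %in% names(df)) df[[hi]] else m
    list(lo = ifelse(is.na(l), m, l), hi = ifelse(is.na(h), m, h))
  }
  ob_osr <- grab(observed, "osr", "osr_lo", "osr_hi")
  ob_dsr <- grab(observed, "diploid_sr", "dsr_lo", "dsr_hi")
  overlap <- function(alo, ahi, blo, bhi) {
    ifelse(is.na(alo) | is.na(blo), NA, alo <= bhi & blo <= ahi)
  }
  tibble::tibble(
    generation = observed$generation,
    osr_overlap = overlap(ob_osr$lo, ob_osr$hi, s$osr_lo, s$osr_hi),
    dsr_overlap = overlap(ob_dsr$lo, ob_dsr$hi, s$dsr_lo, s$dsr_hi)
  )
}
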