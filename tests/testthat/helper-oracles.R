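# Independent oracles: brute-force propagation over the explicit genotype
# space (small k), kept deliberately separate from the package's
# symmetry-reduced and vectorized implementations.

# all 2^k maternal gametes of a k x 2 allele matrix, with probabilities
oracle_gametes <- function(m) {
  k <- nrow(m)
  grid <- as.matrix(expand.grid(rep(list(1:2), k)))
  lapply(seq_len(nrow(grid)), function(i) {
    list(g = m[cbind(seq_len(k), grid[i, ])], p = 1 / nrow(grid))
  })
}

oracle_genotype_key <- function(lo, hi) {
  lab <- function(i) ifelse(i <= 26, LETTERS[i], paste0("<", i, ">"))
  paste(paste(lab(lo), lab(hi), sep = "/"), collapse = ";")
}

# Exact pedigree propagation over explicit (mother genotype, sire genotype)
# pair states. Selection for brother-sister steps conditions globally on the
# chosen daughter being heterozygous at >= 1 locus. Returns, per generation,
# the diploid offspring genotype distribution (named probabilities) and the
# expected homozygous fraction among diploid eggs.
oracle_pedigree <- function(steps, k) {
  stopifnot(steps[1] == "outcross", k <= 3)
  enc <- function(m, f) paste(c(t(m), f), collapse = "-")
  states <- list()
  states[[enc(cbind(rep(1L, k), rep(2L, k)), rep(3L, k))]] <-
    list(m = cbind(rep(1L, k), rep(2L, k)), f = rep(3L, k), p = 1)
  out <- vector("list", length(steps))
  for (j in seq_along(steps)) {
    dip <- numeric(0)
    p_hom <- 0
    for (s in states) {
      for (g in oracle_gametes(s$m)) {
        lo <- pmin(g$g, s$f); hi <- pmax(g$g, s$f)
        key <- oracle_genotype_key(lo, hi)
        dip[key] <- (if (is.na(dip[key])) 0 else dip[key]) + s$p * g$p
        if (all(lo == hi)) p_hom <- p_hom + s$p * g$p
      }
    }
    out[[j]] <- list(diploid = dip, p_hom = p_hom)
    if (j == length(steps)) break
    nxt <- list()
    add <- function(m, f, p) {
      if (p <= 0) return(invisible())
      # canonicalize mother rows
      sw <- m[, 1] > m[, 2]
      if (any(sw)) m[sw, ] <- m[sw, 2:1, drop = FALSE]
      key <- enc(m, f)
      if (is.null(nxt[[key]])) nxt[[key]] <<- list(m = m, f = f, p = p)
      else nxt[[key]]$p <<- nxt[[key]]$p + p
    }
    if (steps[j + 1] == "mother_son") {
      for (s in states) {
        for (g in oracle_gametes(s$m)) add(s$m, g$g, s$p * g$p)
      }
    } else {
      for (s in states) {
        for (gd in oracle_gametes(s$m)) {
          daughter <- cbind(gd$g, s$f)
          if (!any(daughter[, 1] != daughter[, 2])) next  # not female
          for (gs in oracle_gametes(s$m)) {
            add(daughter, gs$g, s$p * gd$p * gs$p)
          }
        }
      }
      tot <- sum(vapply(nxt, function(s) s$p, numeric(1)))
      nxt <- lapply(nxt, function(s) { s$p <- s$p / tot; s })
    }
    states <- nxt
  }
  out
}

# total variation distance between two named count/probability vectors
tv_distance <- function(a, b) {
  a <- a / sum(a); b <- b / sum(b)
  keys <- union(names(a), names(b))
  av <- ifelse(is.na(a[keys]), 0, a[keys])
  bv <- ifelse(is.na(b[keys]), 0, b[keys])
  sum(abs(av - bv)) / 2
}

# reconstruct a minimal brood-record table from aggregate printed counts
broods_from_counts <- function(group, n_all_male, n_with_females,
                               females_per_brood = 5L, males_per_brood = 2L) {
  n <- n_all_male + n_with_females
  tibble::tibble(
    mother_id = sprintf("%s-%04d", group, seq_len(n)),
    group = group,
    generation = "pooled",
    n_female_adults = rep(c(0L, females_per_brood),
                          c(n_all_male, n_with_females)),
    n_male_adults = rep(c(7L, males_per_brood),
                        c(n_all_male, n_with_females)),
    n_flies_emerged = 1L, n_fly_pupae_unemerged = 1L, n_hosts = 12L,
    n_dead_wasps_female = NA_integer_, n_dead_wasps_male = NA_integer_
  )
}

observed_dose_response_path <- function() {
  system.file("extdata", "dose_response_observed.csv", package = "csdsim",
              mustWork = TRUE)
}
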