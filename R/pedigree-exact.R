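#' Inbreeding cross scheme
#'
#' An ordered pedigree of cross types. Every scheme starts with an outcross
#' of a fully heterozygous female to an unrelated sire; subsequent steps are
#' mother-son (M-S, the F0 mother remated to one of her sons) or
#' brother-sister (B-S, a daughter and a son drawn from the same brood).
#'
#' Two presets mirror the experimental regimes for the two study species:
#' `"heterotoma"` = outcross, M-S, then six B-S generations;
#' `"clavipes"` = outcross, then six B-S generations (no initial M-S, as
#' these females do not remate after cold storage).
#'
#' @param steps Character vector of steps from
#'   `c("outcross", "mother_son", "brother_sister")`. The first must be
#'   `"outcross"` and no later step may be.
#' @param label Scheme label.
#' @return An object of class `cross_scheme` with fields `label`, `steps`
#'   and `generation` (display labels: `"outcross"`, `"M-S"`, `"B-S 1"`...).
#' @examples
#' cross_scheme_preset("heterotoma")
#' cross_scheme(c("outcross", "brother_sister"), label = "one B-S step")
#' @export
cross_scheme <- function(steps, label = "custom") {
  steps <- match.arg(steps, c("outcross", "mother_son", "brother_sister"),
                     several.ok = TRUE)
  if (length(steps) < 1L || steps[1L] != "outcross") {
    stop("a cross scheme must begin with an outcross", call. = FALSE)
  }
  if (any(steps[-1L] == "outcross")) {
    stop("only the first step may be an outcross", call. = FALSE)
  }
  gen <- character(length(steps))
  gen[1L] <- "outcross"
  bs <- 0L
  for (j in seq_along(steps)[-1L]) {
    gen[j] <- if (steps[j] == "mother_son") "M-S" else {
      bs <- bs + 1L
      paste("B-S", bs)
    }
  }
  structure(list(label = label, steps = steps, generation = gen),
            class = "cross_scheme")
}

#' @rdname cross_scheme
#' @param preset `"heterotoma"` or `"clavipes"`.
#' @param n_bs Number of brother-sister generations (default 6, as in the
#'   inbreeding experiments).
#' @export
cross_scheme_preset <- function(preset = c("heterotoma", "clavipes"),
                                n_bs = 6L) {
  preset <- match.arg(preset)
  steps <- switch(preset,
                  heterotoma = c("outcross", "mother_son",
                                 rep("brother_sister", n_bs)),
                  clavipes = c("outcross", rep("brother_sister", n_bs)))
  cross_scheme(steps, label = preset)
}

#' @export
print.cross_scheme <- function(x, ...) {
  cat("Cross scheme '", x$label, "': ", paste(x$generation, collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

# --- Exact propagation of the pedigree genotype distribution ----------------
#
# Per locus, the breeding pair (diploid mother, haploid sire) falls into one
# of four relationship classes, invariant under relabelling of alleles:
#   het_in : mother heterozygous, sire allele is one of hers   ({A,B} x A)
#   het_out: mother heterozygous, sire allele is not hers      ({A,B} x C)
#   hom_in : mother homozygous, sire allele matches            ({A,A} x A)
#   hom_out: mother homozygous, sire allele differs            ({A,A} x B)
# The chance a fertilized egg is homozygous at that locus is 1/2, 0, 1, 0
# respectively. Class transitions under M-S (same mother, son = maternal
# gamete) and B-S (daughter and son from the brood) depend only on the class
# and are independent across loci, so the joint chain over k loci is
# lumpable to class *compositions* (n_het_in, n_het_out, n_hom_in,
# n_hom_out). The only coupling across loci is the selection rule that the
# next mother must be a female, i.e. heterozygous at >= 1 locus, which is a
# function of the composition and is applied by conditioning.

.classes <- c("het_in", "het_out", "hom_in", "hom_out")

# transition probabilities P(new class | old class) per cross type
.trans <- list(
  mother_son = rbind(
    het_in  = c(het_in = 1,   het_out = 0,   hom_in = 0,    hom_out = 0),
    het_out = c(het_in = 1,   het_out = 0,   hom_in = 0,    hom_out = 0),
    hom_in  = c(het_in = 0,   het_out = 0,   hom_in = 1,    hom_out = 0),
    hom_out = c(het_in = 0,   het_out = 0,   hom_in = 1,    hom_out = 0)
  ),
  brother_sister = rbind(
    het_in  = c(het_in = 1/2, het_out = 0,   hom_in = 1/4,  hom_out = 1/4),
    het_out = c(het_in = 1/2, het_out = 1/2, hom_in = 0,    hom_out = 0),
    hom_in  = c(het_in = 0,   het_out = 0,   hom_in = 1,    hom_out = 0),
    hom_out = c(het_in = 1,   het_out = 0,   hom_in = 0,    hom_out = 0)
  )
)

.comp_key <- function(n) paste(n, collapse = ",")

# enumerate multinomial outcomes of n trials over classes with prob p
.multinom_outcomes <- function(n, p) {
  nz <- which(p > 0)
  if (length(nz) == 1L) {
    out <- integer(4L); out[nz] <- n
    return(list(list(counts = out, prob = 1)))
  }
  res <- list()
  recurse <- function(idx, left, counts, prob) {
    if (idx == length(nz)) {
      counts[nz[idx]] <- left
      prob <- prob * p[nz[idx]]^left
      res[[length(res) + 1L]] <<- list(counts = counts, prob = prob)
      return(invisible())
    }
    for (m in 0:left) {
      c2 <- counts; c2[nz[idx]] <- m
      recurse(idx + 1L, left - m, c2,
              prob * choose(left, m) * p[nz[idx]]^m)
    }
  }
  recurse(1L, n, integer(4L), 1)
  res
}

# one pedigree step: map composition distribution to the next
.step_composition <- function(dist, type) {
  tm <- .trans[[type]]
  out <- new.env(parent = emptyenv())
  for (key in ls(dist)) {
    p0 <- dist[[key]]
    n <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    # convolve multinomial splits of each old class
    partial <- list(list(counts = integer(4L), prob = 1))
    for (cls in seq_along(.classes)) {
      if (n[cls] == 0L) next
      splits <- .multinom_outcomes(n[cls], tm[.classes[cls], ])
      nxt <- list()
      for (a in partial) for (b in splits) {
        nxt[[length(nxt) + 1L]] <- list(counts = a$counts + b$counts,
                                        prob = a$prob * b$prob)
      }
      partial <- nxt
    }
    for (a in partial) {
      k2 <- .comp_key(a$counts)
      out[[k2]] <- (if (is.null(out[[k2]])) 0 else out[[k2]]) + p0 * a$prob
    }
  }
  if (type == "brother_sister") {
    # condition on the selected daughter being female: heterozygous at >= 1
    # locus, i.e. composition has at least one het_* locus
    tot <- 0
    for (key in ls(out)) {
      n <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
      if (n[1L] + n[2L] == 0L) rm(list = key, envir = out)
      else tot <- tot + out[[key]]
    }
    if (tot <= 0) stop("pedigree distribution degenerate: no heterozygous ",
                       "daughters available", call. = FALSE)
    for (key in ls(out)) out[[key]] <- out[[key]] / tot
  }
  out
}

.p_hom_composition <- function(dist) {
  p <- 0
  for (key in ls(dist)) {
    n <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    if (n[2L] == 0L && n[4L] == 0L) p <- p + dist[[key]] * 0.5^n[1L]
  }
  p
}

#' Expected homozygous fraction of fertilized eggs along a pedigree
#'
#' Exact per-generation expectation of the proportion of fertilized
#' (diploid) eggs homozygous at all CSD loci, propagating the joint parental
#' genotype distribution along an inbreeding scheme. Mothers are conditioned
#' on being females (heterozygous at one or more loci) and sires on being
#' haploid, matching how breeding pairs are drawn in the experiments.
#'
#' Under single-locus CSD the value is 0 in the outcross generation, 50%
#' in the generation following a mother-son cross, and never exceeds 50% at
#' any generation of any mother-son / brother-sister scheme; with more loci
#' it is lower but approaches 50% over successive inbreeding generations.
#'
#' The computation is exact for any `k <= 10` (loci are collapsed to
#' relationship classes between the pair's genotypes, which the cross
#' dynamics provably preserve); longer pedigrees than 8 generations are
#' refused — use the Monte Carlo simulator [run_simulation()] instead.
#'
#' @param scheme A [cross_scheme()].
#' @param csd A [csd_params()]; only `n_loci` is used.
#' @return A tibble with columns `generation` (label), `step` (cross type
#'   producing that brood) and `p_homozygous` (expected homozygous fraction
#'   among fertilized eggs of that generation's brood).
#' @examples
#' homozygous_fraction_pedigree(cross_scheme_preset("heterotoma"),
#'                              csd_params(1))
#' @export
homozygous_fraction_pedigree <- function(scheme, csd = csd_params(1L)) {
  stopifnot(inherits(scheme, "cross_scheme"), inherits(csd, "csd_params"))
  k <- csd$n_loci
  if (k > 10L) {
    stop("enumeration guard exceeded (k > 10): use Monte Carlo via ",
         "run_simulation()", call. = FALSE)
  }
  if (length(scheme$steps) > 8L) {
    stop("enumeration guard exceeded (> 8 generations): use Monte Carlo via ",
         "run_simulation()", call. = FALSE)
  }
  # F0 pair: mother A/B at all loci, unrelated sire C at all loci -> het_out^k
  dist <- new.env(parent = emptyenv())
  dist[[.comp_key(c(0L, k, 0L, 0L))]] <- 1
  p <- numeric(length(scheme$steps))
  p[1L] <- .p_hom_composition(dist)   # outcross brood: 0
  for (j in seq_along(scheme$steps)[-1L]) {
    dist <- .step_composition(dist, scheme$steps[j])
    p[j] <- .p_hom_composition(dist)
  }
  tibble::tibble(generation = scheme$generation, step = scheme$steps,
                 p_homozygous = p)
}
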