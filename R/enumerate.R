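#' Distribution over genotypes
#'
#' A discrete probability distribution over `csd_genotype`s, used as input
#' to the exact cross enumerator. Genotypes are canonicalized and duplicate
#' entries are merged.
#'
#' @param genotypes List of `csd_genotype`s (all the same ploidy and k).
#' @param prob Numeric vector of probabilities summing to 1.
#' @return An object of class `genotype_distribution` with fields
#'   `genotypes`, `prob` and `key` (canonical string forms).
#' @export
genotype_distribution <- function(genotypes, prob = rep(1 / length(genotypes),
                                                        length(genotypes))) {
  if (inherits(genotypes, "csd_genotype")) genotypes <- list(genotypes)
  if (length(genotypes) == 0L) stop("empty genotype distribution", call. = FALSE)
  stopifnot(length(genotypes) == length(prob))
  if (any(prob < 0) || abs(sum(prob) - 1) > 1e-9) {
    stop("probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  pl <- vapply(genotypes, function(g) g$ploidy, integer(1))
  kk <- vapply(genotypes, n_loci, integer(1))
  if (length(unique(pl)) != 1L || length(unique(kk)) != 1L) {
    stop("all genotypes must share ploidy and number of loci", call. = FALSE)
  }
  key <- vapply(genotypes, format_genotype, character(1))
  if (anyDuplicated(key)) {
    agg <- rowsum(prob, key)
    keep <- match(rownames(agg), key)
    genotypes <- genotypes[keep]
    prob <- as.numeric(agg)
    key <- rownames(agg)
  }
  structure(list(genotypes = genotypes, prob = prob, key = key),
            class = "genotype_distribution")
}

#' Exact gamete distribution of a diploid genotype
#'
#' Enumerates all `2^k` equally likely maternal gamete draws (one allele per
#' locus, independent loci) and merges identical gametes.
#'
#' @param g A diploid `csd_genotype` with `k <= 20` loci.
#' @return A `genotype_distribution` over haploid genotypes.
#' @export
gamete_distribution <- function(g) {
  stopifnot(inherits(g, "csd_genotype"))
  if (g$ploidy != 2L) stop("gamete distributions come from diploids", call. = FALSE)
  k <- n_loci(g)
  if (k > 20L) stop("enumeration guard: k too large; use Monte Carlo", call. = FALSE)
  het <- heterozygous_loci(g)
  choices <- lapply(seq_len(k), function(l) {
    if (het[l]) g$alleles[l, ] else g$alleles[l, 1L]
  })
  grid <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  gams <- lapply(seq_len(nrow(grid)), function(r) genotype(grid[r, ], ploidy = 1L))
  genotype_distribution(gams, rep(1 / nrow(grid), nrow(grid)))
}

#' Exact offspring distribution of a cross
#'
#' Enumerates every maternal-gamete x sire combination to give the exact
#' offspring genotype distribution of a cross between a (distribution over)
#' diploid mother(s) and a (distribution over) haploid sire(s), with each
#' egg fertilized with probability `f`. Fertilized eggs are diploid fusions;
#' unfertilized eggs are haploid maternal gametes. Serves as the exact
#' oracle for the stochastic brood simulator.
#'
#' @param mother A diploid `csd_genotype`, or a `genotype_distribution` of
#'   diploids.
#' @param father A haploid `csd_genotype`, or a `genotype_distribution` of
#'   haploids.
#' @param f Fertilization rate in `[0, 1]`.
#' @param csd A `csd_params` (defaults to single-locus CSD with the
#'   genotype's k).
#' @return An object of class `offspring_distribution`: a list with
#'   * `table`: tibble with columns `ploidy`, `genotype` (canonical string),
#'     `prob`, and `sex` under the CSD rule;
#'   * `p_homozygous_given_diploid`: exact chance a fertilized (diploid) egg
#'     is homozygous at all loci (`NA` if `f = 0`);
#'   * `p_female`, `p_haploid_male`, `p_diploid_male`: marginal sex-category
#'     probabilities.
#' @examples
#' # mother A/B x her son A: half of the diploid brood is homozygous
#' enumerate_cross(genotype(cbind(1L, 2L)), genotype(1L), f = 0.6)
#' @export
enumerate_cross <- function(mother, father, f,
                            csd = NULL) {
  if (inherits(mother, "csd_genotype")) mother <- genotype_distribution(mother)
  if (inherits(father, "csd_genotype")) father <- genotype_distribution(father)
  stopifnot(inherits(mother, "genotype_distribution"),
            inherits(father, "genotype_distribution"))
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    stop("`f` must be a single fertilization rate in [0, 1]", call. = FALSE)
  }
  if (mother$genotypes[[1L]]$ploidy != 2L) {
    stop("mother entries must be diploid", call. = FALSE)
  }
  if (father$genotypes[[1L]]$ploidy != 1L) {
    stop("father entries must be haploid", call. = FALSE)
  }
  k <- n_loci(mother$genotypes[[1L]])
  if (k != n_loci(father$genotypes[[1L]])) {
    stop("mother and father genotypes have different k", call. = FALSE)
  }
  if (is.null(csd)) csd <- csd_params(k)

  acc <- new.env(parent = emptyenv())
  add <- function(key, g, p) {
    if (p <= 0) return(invisible())
    cur <- acc[[key]]
    if (is.null(cur)) acc[[key]] <- list(g = g, p = p)
    else acc[[key]]$p <- cur$p + p
  }
  for (mi in seq_along(mother$genotypes)) {
    gd <- gamete_distribution(mother$genotypes[[mi]])
    pm <- mother$prob[mi]
    for (gi in seq_along(gd$genotypes)) {
      gam <- gd$genotypes[[gi]]
      pg <- pm * gd$prob[gi]
      # unfertilized: haploid son with the maternal gamete genotype
      add(paste0("1|", gd$key[gi]), gam, pg * (1 - f))
      # fertilized: fuse with each possible sire
      for (fi in seq_along(father$genotypes)) {
        z <- fuse(gam, father$genotypes[[fi]])
        add(paste0("2|", format_genotype(z)), z, pg * f * father$prob[fi])
      }
    }
  }
  keys <- ls(acc)
  gs <- lapply(keys, function(kk) acc[[kk]]$g)
  ps <- vapply(keys, function(kk) acc[[kk]]$p, numeric(1))
  pl <- vapply(gs, function(g) g$ploidy, integer(1))
  sex <- vapply(gs, determine_sex, character(1), csd = csd)
  hom <- vapply(gs, function(g) g$ploidy == 2L && !any(heterozygous_loci(g)),
                logical(1))
  tab <- tibble::tibble(
    ploidy = pl,
    genotype = vapply(gs, format_genotype, character(1)),
    prob = unname(ps),
    sex = sex,
    homozygous = hom
  )
  tab <- tab[order(tab$ploidy, tab$genotype), ]
  p_dip <- sum(tab$prob[tab$ploidy == 2L])
  p_hom_dip <- if (p_dip > 0) sum(tab$prob[tab$homozygous]) / p_dip else NA_real_
  structure(
    list(
      table = tab,
      p_homozygous_given_diploid = p_hom_dip,
      p_female = sum(tab$prob[tab$sex == "female"]),
      p_haploid_male = sum(tab$prob[tab$sex == "haploid_male"]),
      p_diploid_male = sum(tab$prob[tab$sex == "diploid_male"])
    ),
    class = "offspring_distribution"
  )
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat("Offspring distribution (", nrow(x$table), " genotypes)\n", sep = "")
  print(x$table, n = 20)
  cat("P(homozygous | diploid) =", format(x$p_homozygous_given_diploid), "\n")
  cat("P(female) =", format(x$p_female),
      " P(haploid male) =", format(x$p_haploid_male),
      " P(diploid male) =", format(x$p_diploid_male), "\n")
  invisible(x)
}
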