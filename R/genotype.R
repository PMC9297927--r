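#' CSD model parameters
#'
#' Parameters of the complementary sex determination (CSD) rule used
#' throughout the package: the number of unlinked CSD loci, whether diploid
#' males are viable, and whether CSD operates at all (when disabled every
#' diploid develops as a female, the arrhenotokous null model).
#'
#' @param n_loci Number of unlinked CSD loci (k >= 1). Single-locus CSD is
#'   `n_loci = 1`; multilocus CSD uses more. Typical settings are 1, 2, 5, 10.
#' @param diploid_male_viable Logical; if `FALSE`, diploid males die before
#'   adulthood and are removed from broods.
#' @param csd_enabled Logical; if `FALSE`, all diploids develop as females
#'   regardless of genotype (no CSD).
#' @return An object of class `csd_params`.
#' @examples
#' csd_params(n_loci = 1)
#' csd_params(n_loci = 2, csd_enabled = FALSE)
#' @export
csd_params <- function(n_loci = 1L, diploid_male_viable = TRUE,
                       csd_enabled = TRUE) {
  n_loci <- as.integer(n_loci)
  if (length(n_loci) != 1L || is.na(n_loci) || n_loci < 1L) {
    stop("`n_loci` must be a single integer >= 1", call. = FALSE)
  }
  stopifnot(is.logical(diploid_male_viable), length(diploid_male_viable) == 1L,
            is.logical(csd_enabled), length(csd_enabled) == 1L)
  structure(
    list(n_loci = n_loci, diploid_male_viable = diploid_male_viable,
         csd_enabled = csd_enabled),
    class = "csd_params"
  )
}

#' @export
print.csd_params <- function(x, ...) {
  cat("CSD parameters: ", x$n_loci, " locus/loci; diploid males ",
      if (x$diploid_male_viable) "viable" else "inviable", "; CSD ",
      if (x$csd_enabled) "enabled" else "disabled", "\n", sep = "")
  invisible(x)
}

#' Construct a genotype at k CSD loci
#'
#' A genotype stores the allelic state at each of k unlinked CSD loci.
#' Alleles are opaque small-integer labels (1 = "A", 2 = "B", 3 = "C", ...).
#' Haploid genotypes carry one allele per locus, diploid genotypes an
#' unordered pair; diploid pairs are canonicalized by sorting so that equal
#' genotypes have identical representations.
#'
#' @param alleles For haploids, an integer vector of length k. For diploids,
#'   a k x 2 integer matrix (one row per locus).
#' @param ploidy 1 or 2. Inferred from the shape of `alleles` when missing.
#' @return An object of class `csd_genotype` with fields `ploidy` and
#'   `alleles` (a k x ploidy integer matrix with sorted rows for diploids).
#' @examples
#' genotype(c(1, 2))                      # haploid A;B at two loci
#' genotype(rbind(c(1, 2), c(3, 3)))      # diploid A/B ; C/C
#' @export
genotype <- function(alleles, ploidy = NULL) {
  if (is.null(dim(alleles))) {
    alleles <- matrix(as.integer(alleles), ncol = 1L)
  } else {
    alleles <- matrix(as.integer(alleles), nrow = nrow(alleles))
  }
  if (is.null(ploidy)) ploidy <- ncol(alleles)
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2", call. = FALSE)
  if (ncol(alleles) != ploidy) {
    stop("allele matrix has ", ncol(alleles), " column(s) but ploidy is ",
         ploidy, call. = FALSE)
  }
  if (anyNA(alleles) || any(alleles < 1L)) {
    stop("allele labels must be positive integers", call. = FALSE)
  }
  if (ploidy == 2L) {
    swap <- alleles[, 1L] > alleles[, 2L]
    if (any(swap)) alleles[swap, ] <- alleles[swap, 2:1]
  }
  structure(list(ploidy = ploidy, alleles = alleles), class = "csd_genotype")
}

n_loci <- function(g) nrow(g$alleles)

allele_label <- function(i) {
  ifelse(i <= 26L, LETTERS[i], paste0("<", i, ">"))
}

#' Compact string form of a genotype
#'
#' Loci are ";"-separated; diploid loci are written as "X/Y" with sorted
#' allele labels so equal genotypes format identically.
#'
#' @param g A `csd_genotype`.
#' @return A single string such as `"A/B;C/C"` or `"A;C"`.
#' @export
format_genotype <- function(g) {
  stopifnot(inherits(g, "csd_genotype"))
  if (g$ploidy == 1L) {
    paste(allele_label(g$alleles[, 1L]), collapse = ";")
  } else {
    paste(paste(allele_label(g$alleles[, 1L]), allele_label(g$alleles[, 2L]),
                sep = "/"), collapse = ";")
  }
}

#' @export
format.csd_genotype <- function(x, ...) format_genotype(x)

#' @export
print.csd_genotype <- function(x, ...) {
  cat(if (x$ploidy == 1L) "haploid " else "diploid ", format_genotype(x),
      "\n", sep = "")
  invisible(x)
}

#' Is a diploid genotype heterozygous at each locus?
#'
#' @param g A diploid `csd_genotype`.
#' @return Logical vector of length k: `TRUE` where the two alleles differ.
#' @export
heterozygous_loci <- function(g) {
  stopifnot(inherits(g, "csd_genotype"))
  if (g$ploidy != 2L) stop("heterozygosity is defined for diploids", call. = FALSE)
  g$alleles[, 1L] != g$alleles[, 2L]
}

#' An individual wasp
#'
#' Bundles a genotype with its sex category (consistent with
#' [determine_sex()]) and optional parent identifiers.
#'
#' @param id Identifier.
#' @param genotype A `csd_genotype`.
#' @param csd A `csd_params` used to assign the sex category.
#' @param mother_id,father_id Optional parent identifiers.
#' @return An object of class `csd_individual` with fields `id`, `genotype`,
#'   `sex` (one of `"female"`, `"haploid_male"`, `"diploid_male"`),
#'   `mother_id`, `father_id`.
#' @export
individual <- function(id, genotype, csd = csd_params(n_loci(genotype)),
                       mother_id = NA_character_, father_id = NA_character_) {
  stopifnot(inherits(genotype, "csd_genotype"))
  structure(
    list(id = as.character(id), genotype = genotype,
         sex = determine_sex(genotype, csd),
         mother_id = as.character(mother_id),
         father_id = as.character(father_id)),
    class = "csd_individual"
  )
}

#' @export
print.csd_individual <- function(x, ...) {
  cat(x$id, " [", x$sex, "] ", format_genotype(x$genotype), "\n", sep = "")
  invisible(x)
}

#' Mendelian gamete formation
#'
#' Forms one haploid gamete from a diploid parent: at each locus one of the
#' parent's two alleles is chosen uniformly, independently across loci (all
#' CSD loci segregate independently; no linkage is modelled).
#'
#' @param parent A diploid `csd_genotype` or a `csd_individual` with one.
#' @return A haploid `csd_genotype`. Uses the current R random number
#'   generator state; seed with [set.seed()] for reproducibility.
#' @examples
#' set.seed(1)
#' make_gamete(genotype(rbind(c(1, 2), c(3, 3))))
#' @export
make_gamete <- function(parent) {
  if (inherits(parent, "csd_individual")) parent <- parent$genotype
  stopifnot(inherits(parent, "csd_genotype"))
  if (parent$ploidy != 2L) {
    stop("gametes are formed from diploid parents; haploid males transmit ",
         "their whole genotype (see `fuse()`)", call. = FALSE)
  }
  k <- n_loci(parent)
  pick <- sample.int(2L, k, replace = TRUE)
  genotype(parent$alleles[cbind(seq_len(k), pick)], ploidy = 1L)
}

#' Fertilization: fuse two haploid genotypes
#'
#' Combines a maternal gamete with a (haploid) paternal genotype into a
#' diploid genotype with unordered, canonicalized allele pairs per locus.
#' Symmetric in its arguments.
#'
#' @param maternal_gamete,paternal_genotype Haploid `csd_genotype`s with the
#'   same number of loci.
#' @return A diploid `csd_genotype`.
#' @examples
#' fuse(genotype(1L), genotype(3L))  # A x C -> A/C
#' @export
fuse <- function(maternal_gamete, paternal_genotype) {
  stopifnot(inherits(maternal_gamete, "csd_genotype"),
            inherits(paternal_genotype, "csd_genotype"))
  if (maternal_gamete$ploidy != 1L || paternal_genotype$ploidy != 1L) {
    stop("both gametes must be haploid", call. = FALSE)
  }
  if (n_loci(maternal_gamete) != n_loci(paternal_genotype)) {
    stop("gametes have different numbers of loci", call. = FALSE)
  }
  genotype(cbind(maternal_gamete$alleles[, 1L], paternal_genotype$alleles[, 1L]))
}

#' The CSD sex determination rule
#'
#' Haploid (hemizygous) individuals develop as males. Diploids develop as
#' females if heterozygous at one or more CSD loci and as diploid males if
#' homozygous at every locus. With `csd$csd_enabled = FALSE` every diploid
#' develops as a female (the no-CSD null).
#'
#' @param genotype A `csd_genotype`.
#' @param csd A `csd_params`; its `n_loci` must match the genotype.
#' @return One of `"female"`, `"haploid_male"`, `"diploid_male"`.
#' @examples
#' determine_sex(genotype(1L), csd_params(1))                  # haploid male
#' determine_sex(genotype(cbind(1L, 2L)), csd_params(1))       # female
#' determine_sex(genotype(cbind(1L, 1L)), csd_params(1))       # diploid male
#' @export
determine_sex <- function(genotype, csd) {
  stopifnot(inherits(genotype, "csd_genotype"), inherits(csd, "csd_params"))
  if (n_loci(genotype) != csd$n_loci) {
    stop("genotype has ", n_loci(genotype), " loci but csd expects ",
         csd$n_loci, call. = FALSE)
  }
  if (genotype$ploidy == 1L) return("haploid_male")
  if (!csd$csd_enabled) return("female")
  if (any(genotype$alleles[, 1L] != genotype$alleles[, 2L])) "female"
  else "diploid_male"
}
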