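#' Parameters for closed-form offspring proportions
#'
#' Three scenarios describe the expected composition of a brood in a
#' haplodiploid with fertilization rate `f`: no CSD, CSD with inviable
#' diploid males, and CSD with viable diploid males. `h` is the chance that
#' a fertilized egg is homozygous at all CSD loci, and `i` the proportion of
#' all eggs lost as inviable diploid males (so `i <= f`; when driven from the
#' genotype model with fully lethal diploid males, `i = h * f`).
#'
#' @param f Fertilization rate in `[0, 1]`.
#' @param h Chance of homozygosity at all CSD loci in `[0, 1]`.
#' @param i Proportion of inviable diploid males in `[0, f]` (only used by
#'   `scenario = "csd_inviable_dm"`; defaults to `h * f`).
#' @param scenario One of `"no_csd"`, `"csd_inviable_dm"`, `"csd_viable_dm"`.
#' @return An object of class `table1_params`.
#' @seealso [expected_proportions()]
#' @export
table1_params <- function(f, h = 0, i = h * f,
                          scenario = c("no_csd", "csd_inviable_dm",
                                       "csd_viable_dm")) {
  scenario <- match.arg(scenario)
  for (nm in c("f", "h", "i")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a single number in [0, 1]", call. = FALSE)
    }
  }
  if (scenario == "csd_inviable_dm" && i > f) {
    stop("`i` (inviable diploid males) cannot exceed the fertilization rate `f`",
         call. = FALSE)
  }
  structure(list(f = f, h = h, i = i, scenario = scenario),
            class = "table1_params")
}

#' Expected offspring proportions and progeny sex ratio
#'
#' Closed-form expected proportions of diploid females (F), haploid males
#' (M) and diploid males (D) among offspring, and the progeny sex ratio
#' (proportion male among surviving adults), for the three CSD scenarios:
#'
#' * no CSD: `F = f`, `M = 1 - f`, `D = 0`, `SR = (1 - f)`.
#' * CSD, inviable diploid males: `F = f - i`, `M = 1 - f`, `D = 0`,
#'   `SR = (1 - f) / ((f - i) + (1 - f))` — the denominator counts surviving
#'   adults only, so proportions sum to `1 - i`.
#' * CSD, viable diploid males: `F = (1 - h) f`, `M = 1 - f`, `D = h f`,
#'   `SR = ((1 - f) + h f) / ((1 - h) f + (1 - f) + h f)`.
#'
#' @param params A [table1_params()] object.
#' @return An object of class `sex_proportions`: list with `p_female`,
#'   `p_haploid_male`, `p_diploid_male` (fractions of eggs laid) and
#'   `sex_ratio` (proportion male among surviving adults).
#' @examples
#' expected_proportions(table1_params(f = 0.6, h = 0.5,
#'                                    scenario = "csd_viable_dm"))
#' @export
expected_proportions <- function(params) {
  stopifnot(inherits(params, "table1_params"))
  f <- params$f; h <- params$h; i <- params$i
  res <- switch(
    params$scenario,
    no_csd = list(p_female = f, p_haploid_male = 1 - f, p_diploid_male = 0,
                  sex_ratio = 1 - f),
    csd_inviable_dm = {
      surv <- (f - i) + (1 - f)
      list(p_female = f - i, p_haploid_male = 1 - f, p_diploid_male = 0,
           sex_ratio = if (surv == 0) NA_real_ else (1 - f) / surv)
    },
    csd_viable_dm = list(
      p_female = (1 - h) * f, p_haploid_male = 1 - f, p_diploid_male = h * f,
      sex_ratio = ((1 - f) + h * f) / ((1 - h) * f + (1 - f) + h * f)
    )
  )
  structure(res, class = "sex_proportions")
}

#' @export
print.sex_proportions <- function(x, digits = 4, ...) {
  cat("Expected proportions: F =", signif(x$p_female, digits),
      " M =", signif(x$p_haploid_male, digits),
      " D =", signif(x$p_diploid_male, digits),
      " sex ratio =", signif(x$sex_ratio, digits), "\n")
  invisible(x)
}
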