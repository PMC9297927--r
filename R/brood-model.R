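#' Brood size and fertilization model
#'
#' Generative model for one brood: a brood size and a fertilization
#' proportion are drawn once per brood, then each egg is independently
#' fertilized with that proportion. Two sources are supported:
#'
#' * `"empirical"`: joint resampling (with replacement) of observed
#'   `(brood_size, fertilization)` pairs, e.g. from a control pedigree,
#'   preserving any size-fertilization correlation;
#' * `"parametric"`: brood size from a negative binomial (mean and
#'   dispersion `size`), fertilization from a beta distribution.
#'
#' @param source `"parametric"` or `"empirical"`.
#' @param empirical Data frame with columns `brood_size`, `fertilization`
#'   (required when `source = "empirical"`).
#' @param mean_size,dispersion Negative binomial mean and dispersion (the
#'   `size` parameter of [stats::rnbinom()]; smaller = more overdispersed).
#' @param beta_a,beta_b Beta shape parameters of the fertilization
#'   distribution. The defaults give mean 0.65 with moderate spread,
#'   matching progeny sex ratios of roughly one third male.
#' @return An object of class `brood_model`.
#' @examples
#' brood_model()                                       # parametric defaults
#' brood_model("empirical",
#'             empirical = data.frame(brood_size = c(8, 12),
#'                                    fertilization = c(0.7, 0.6)))
#' @export
brood_model <- function(source = c("parametric", "empirical"),
                        empirical = NULL,
                        mean_size = 10, dispersion = 5,
                        beta_a = 13, beta_b = 7) {
  source <- match.arg(source)
  if (source == "empirical") {
    if (is.null(empirical) || nrow(empirical) == 0L) {
      stop("`empirical` must be a non-empty data frame with columns ",
           "brood_size and fertilization", call. = FALSE)
    }
    if (!all(c("brood_size", "fertilization") %in% names(empirical))) {
      stop("empirical brood table needs columns brood_size, fertilization",
           call. = FALSE)
    }
    if (any(empirical$brood_size < 0) ||
        any(empirical$fertilization < 0 | empirical$fertilization > 1)) {
      stop("brood sizes must be >= 0 and fertilization in [0, 1]",
           call. = FALSE)
    }
  } else {
    stopifnot(mean_size > 0, dispersion > 0, beta_a > 0, beta_b > 0)
  }
  structure(list(source = source, empirical = empirical,
                 mean_size = mean_size, dispersion = dispersion,
                 beta_a = beta_a, beta_b = beta_b),
            class = "brood_model")
}

# one (brood_size, fertilization) draw
draw_brood_params <- function(bm) {
  stopifnot(inherits(bm, "brood_model"))
  if (bm$source == "empirical") {
    i <- sample.int(nrow(bm$empirical), 1L)
    list(n = as.integer(bm$empirical$brood_size[i]),
         f = bm$empirical$fertilization[i])
  } else {
    list(n = as.integer(stats::rnbinom(1L, mu = bm$mean_size,
                                       size = bm$dispersion)),
         f = stats::rbeta(1L, bm$beta_a, bm$beta_b))
  }
}

#' @export
print.brood_model <- function(x, ...) {
  if (x$source == "empirical") {
    cat("Empirical brood model:", nrow(x$empirical), "resampled broods\n")
  } else {
    cat("Parametric brood model: size ~ NegBin(mean ", x$mean_size,
        ", dispersion ", x$dispersion, "), fertilization ~ Beta(",
        x$beta_a, ", ", x$beta_b, ") [mean ",
        round(x$beta_a / (x$beta_a + x$beta_b), 3), "]\n", sep = "")
  }
  invisible(x)
}
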