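# CSV schemas used across the pipeline. All files are plain UTF-8 CSV with
# a header row, "." decimal separator, optional cells left blank.

.brood_required <- c("mother_id", "group", "generation",
                     "n_female_adults", "n_male_adults")
.brood_optional <- c("n_flies_emerged", "n_fly_pupae_unemerged", "n_hosts",
                     "n_dead_wasps_female", "n_dead_wasps_male")

#' Read and validate a brood-record CSV
#'
#' Schema: `mother_id, group, generation, n_female_adults, n_male_adults`
#' (required) plus optional `n_flies_emerged, n_fly_pupae_unemerged,
#' n_hosts, n_dead_wasps_female, n_dead_wasps_male`; missing optional cells
#' may be blank. Count columns must be non-negative; violations are
#' reported with their row number.
#'
#' @param path CSV file path.
#' @return Tibble with the full schema (absent optional columns are `NA`).
#' @export
read_brood_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("brood CSV is empty: ", path, call. = FALSE)
  missing_cols <- setdiff(.brood_required, names(df))
  if (length(missing_cols)) {
    stop("brood CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in .brood_optional) if (!cc %in% names(df)) df[[cc]] <- NA_integer_
  for (cc in c(.brood_required[4:5], .brood_optional)) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    bad <- which(!is.na(df[[cc]]) & df[[cc]] != "" & is.na(v) |
                   (!is.na(v) & v < 0))
    if (length(bad)) {
      stop("brood CSV column ", cc, ": invalid count at row ", bad[1L],
           call. = FALSE)
    }
    df[[cc]] <- v
  }
  tibble::as_tibble(df[, c(.brood_required, .brood_optional)])
}

#' @rdname read_brood_csv
#' @param records Brood table to write.
#' @export
write_brood_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a qPCR sample CSV
#'
#' Schema: `individual_id, dose` plus either `gssb_quantity, ef1a_quantity`
#' or `ct_gssb, ct_ef1a` (optionally `efficiency`).
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_qpcr_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("individual_id", "dose") %in% names(df))) {
    stop("qPCR CSV needs columns individual_id, dose", call. = FALSE)
  }
  has_q <- all(c("gssb_quantity", "ef1a_quantity") %in% names(df))
  has_ct <- all(c("ct_gssb", "ct_ef1a") %in% names(df))
  if (!has_q && !has_ct) {
    stop("qPCR CSV needs gssb_quantity/ef1a_quantity or ct_gssb/ct_ef1a",
         call. = FALSE)
  }
  df
}

#' Read a dose-response CSV
#'
#' Schema mirrors a published antibiotic-treatment table: `dose, n_mothers,
#' n_offspring, n_female, n_male, n_males_tested, n_diploid_males_found,
#' n_flies_emerged, n_flies_unemerged` (`n_female` may be omitted and is
#' recovered as `n_offspring - n_male`).
#'
#' @param path CSV file path.
#' @return A `dose_response_table` tibble.
#' @export
read_dose_response_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("dose", "n_offspring", "n_male", "n_males_tested",
            "n_diploid_males_found")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("dose-response CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"n_female" %in% names(df)) df$n_female <- df$n_offspring - df$n_male
  if (any(df$n_female + df$n_male != df$n_offspring)) {
    stop("n_female + n_male must equal n_offspring", call. = FALSE)
  }
  if (any(df$n_diploid_males_found > df$n_males_tested) ||
      any(df$n_males_tested > df$n_male)) {
    stop("need n_diploid_males_found <= n_males_tested <= n_male",
         call. = FALSE)
  }
  class(df) <- c("dose_response_table", class(df))
  df
}

#' Read a simulation/synthesis configuration (YAML or JSON)
#'
#' Recognized keys: `scheme` (`preset` or `steps`, `n_bs`), `csd`
#' (`n_loci`, `enabled`, `diploid_male_viable`), `brood` (`source`,
#' `empirical_csv`, `negbin: {mean, dispersion}`, `beta: {a, b}`),
#' `n_replicates`, `seed`. Unknown top-level keys are rejected.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return List with elements `scheme` ([cross_scheme()]), `csd`
#'   ([csd_params()]), `brood` ([brood_model()]), `n_replicates`, `seed`.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("scheme", "csd", "brood", "n_replicates", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "), call. = FALSE)
  }
  scheme <- if (!is.null(cfg$scheme$preset)) {
    cross_scheme_preset(cfg$scheme$preset,
                        n_bs = if (!is.null(cfg$scheme$n_bs))
                          cfg$scheme$n_bs else 6L)
  } else if (!is.null(cfg$scheme$steps)) {
    cross_scheme(cfg$scheme$steps)
  } else {
    cross_scheme_preset("heterotoma")
  }
  csd <- csd_params(
    n_loci = if (!is.null(cfg$csd$n_loci)) cfg$csd$n_loci else 1L,
    diploid_male_viable = !isFALSE(cfg$csd$diploid_male_viable),
    csd_enabled = !isFALSE(cfg$csd$enabled)
  )
  brood <- if (identical(cfg$brood$source, "empirical")) {
    brood_model("empirical",
                empirical = utils::read.csv(cfg$brood$empirical_csv))
  } else {
    brood_model(
      mean_size = if (!is.null(cfg$brood$negbin$mean))
        cfg$brood$negbin$mean else 10,
      dispersion = if (!is.null(cfg$brood$negbin$dispersion))
        cfg$brood$negbin$dispersion else 5,
      beta_a = if (!is.null(cfg$brood$beta$a)) cfg$brood$beta$a else 13,
      beta_b = if (!is.null(cfg$brood$beta$b)) cfg$brood$beta$b else 7
    )
  }
  list(scheme = scheme, csd = csd, brood = brood,
       n_replicates = if (!is.null(cfg$n_replicates))
         as.integer(cfg$n_replicates) else 10000L,
       seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L)
}

#' Write a run manifest
#'
#' Every pipeline run writes exactly one JSON manifest recording the
#' subcommand, configuration echo, seed, output paths, timestamp and
#' package version, enabling exact replay.
#'
#' @param dir Output directory.
#' @param subcommand Name of the pipeline stage.
#' @param config Configuration echo (any JSON-serializable list).
#' @param seed Integer seed used.
#' @param outputs Character vector of files written.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, subcommand, config = list(), seed = NA,
                           outputs = character(0)) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(subcommand = subcommand, config = config, seed = seed,
         outputs = outputs,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package_version = as.character(utils::packageVersion("csdsim"))),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", force = TRUE
  )
  invisible(path)
}
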