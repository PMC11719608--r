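#' Chocolate sample tables: validation and I/O
#'
#' A sample table holds one row per analysed chocolate product with columns
#' `sample_id` (character), `chocolate_type` (`"milk"` or `"dark"`),
#' `cacao_pct` (cacao content, percent, in \[0, 100\]) and `cd_conc`
#' (cadmium concentration, mg/kg, non-negative). `validate_samples()` checks
#' an existing data frame; `read_samples()` reads and validates a CSV file;
#' `write_samples()` writes one back so that read and write round-trip.
#'
#' `chocolate_type` is stored explicitly rather than derived from
#' `cacao_pct`, because consumption rates are reported per product type while
#' regulatory categories follow cacao content. When the two disagree (e.g. a
#' "milk" product with 55 % cacao) a warning is emitted, not an error.
#'
#' @param x A data frame with the four columns above (any column order).
#' @param path Path to a CSV file with a header row.
#' @param samples A validated sample table.
#' @return A validated tibble with the four sample columns.
#' @examples
#' s <- tibble::tibble(
#'   sample_id = c("S1", "S2"), chocolate_type = c("dark", "milk"),
#'   cacao_pct = c(72, 35), cd_conc = c(0.29, 0.021)
#' )
#' validate_samples(s)
#' @export
validate_samples <- function(x) {
  required <- c("sample_id", "chocolate_type", "cacao_pct", "cd_conc")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0(
        "Sample table is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "chocrisk_schema_error"
    )
  }
  x <- tibble::as_tibble(x)[required]
  x$sample_id <- as.character(x$sample_id)
  x$chocolate_type <- as.character(x$chocolate_type)
  x$cacao_pct <- as.numeric(x$cacao_pct)
  x$cd_conc <- as.numeric(x$cd_conc)

  problems <- character(0)
  bad_type <- which(!x$chocolate_type %in% c("milk", "dark"))
  if (length(bad_type) > 0) {
    problems <- c(problems, paste0(
      "row ", bad_type, ": chocolate_type must be 'milk' or 'dark' (got '",
      x$chocolate_type[bad_type], "')"
    ))
  }
  bad_cacao <- which(is.na(x$cacao_pct) | x$cacao_pct < 0 | x$cacao_pct > 100)
  if (length(bad_cacao) > 0) {
    problems <- c(problems, paste0(
      "row ", bad_cacao, ": cacao_pct must be in [0, 100] (got ",
      x$cacao_pct[bad_cacao], ")"
    ))
  }
  bad_conc <- which(is.na(x$cd_conc) | x$cd_conc < 0)
  if (length(bad_conc) > 0) {
    problems <- c(problems, paste0(
      "row ", bad_conc, ": cd_conc must be a non-negative number (got ",
      x$cd_conc[bad_conc], ")"
    ))
  }
  if (length(problems) > 0) {
    rlang::abort(
      paste0(
        "Invalid sample rows:\n",
        paste0("  - ", problems, collapse = "\n")
      ),
      class = "chocrisk_validation_error"
    )
  }

  inconsistent <- (x$chocolate_type == "dark" & x$cacao_pct < 50) |
    (x$chocolate_type == "milk" & x$cacao_pct >= 50)
  if (any(inconsistent)) {
    rlang::warn(paste0(
      "chocolate_type and cacao_pct disagree in row(s) ",
      paste(which(inconsistent), collapse = ", "),
      " (dark is expected at >= 50 % cacao); rows kept as labelled"
    ))
  }
  x
}

#' @rdname validate_samples
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Sample file not found: ", path))
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_samples(x)
}

#' @rdname validate_samples
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  readr::write_csv(samples, path)
  invisible(path)
}

#' EU maximum residue levels for cadmium in chocolate
#'
#' Regulation (EU) 2023/915 sets the cadmium MRL by cacao content: 0.1 mg/kg
#' below 30 % cacao, 0.3 mg/kg from 30 to below 50 %, and 0.8 mg/kg at 50 %
#' and above. Categories are half-open with the boundary belonging to the
#' higher category, so 30 % falls in the middle band and 50 % in the top one.
#'
#' @return `mrl_table()` returns a tibble with one row per regulatory
#'   category (`category`, `cacao_low`, `cacao_high`, `mrl`); the top
#'   category is closed at 100.
#' @export
mrl_table <- function() {
  tibble::tibble(
    category = c("milk_lt30", "milk_30to50", "dark_ge50"),
    cacao_low = c(0, 30, 50),
    cacao_high = c(30, 50, 100),
    mrl = c(0.1, 0.3, 0.8)
  )
}

#' @rdname mrl_table
#' @param cacao_pct Cacao content, percent; vectorized.
#' @param schedule MRL schedule as returned by [mrl_table()]; override to
#'   apply a different regulation.
#' @return `mrl_for()` returns the MRL in mg/kg for each element of
#'   `cacao_pct`.
#' @examples
#' mrl_for(c(25, 30, 72))
#' @export
mrl_for <- function(cacao_pct, schedule = mrl_table()) {
  if (any(is.na(cacao_pct)) || any(cacao_pct < 0 | cacao_pct > 100)) {
    rlang::abort("cacao_pct must lie in [0, 100]")
  }
  # boundary belongs to the upper category; the last interval is closed
  idx <- findInterval(cacao_pct, schedule$cacao_low)
  schedule$mrl[idx]
}

#' Check regulatory compliance of sample concentrations
#'
#' Compares each sample's cadmium concentration against the MRL of its
#' cacao-content category. A sample is compliant when `cd_conc <= mrl`
#' (the boundary itself is compliant); `margin = mrl - cd_conc`, so a
#' negative margin quantifies the exceedance.
#'
#' @inheritParams validate_samples
#' @inheritParams mrl_for
#' @return The sample table with `mrl`, `compliant` and `margin` columns
#'   appended.
#' @export
check_compliance <- function(samples, schedule = mrl_table()) {
  samples <- validate_samples(samples)
  samples$mrl <- mrl_for(samples$cacao_pct, schedule)
  samples$compliant <- samples$cd_conc <= samples$mrl
  samples$margin <- samples$mrl - samples$cd_conc
  samples
}

#' Limits of detection and quantification from procedural blanks
#'
#' LOD and LOQ are defined as 3 and 10 times the standard deviation of the
#' procedural blank responses divided by the slope of the calibration curve,
#' so LOQ/LOD = 10/3 by construction.
#'
#' @param blank_sd Standard deviation of blank responses, signal units.
#' @param slope Calibration slope, signal units per concentration unit.
#' @return A named list with `lod` and `loq` in concentration units.
#' @examples
#' lod_loq(blank_sd = 0.0003, slope = 1)
#' @export
lod_loq <- function(blank_sd, slope) {
  if (blank_sd < 0) rlang::abort("blank_sd must be non-negative")
  if (slope <= 0) rlang::abort("slope must be strictly positive")
  list(lod = 3 * blank_sd / slope, loq = 10 * blank_sd / slope)
}

#' Substitute concentrations below the limit of quantification
#'
#' Optional censoring policy: values below `loq` are replaced by `loq / 2`.
#' This is off by default throughout the package — reported concentrations
#' are taken as given, since the study's minimum (0.010 mg/kg) is well above
#' its LOQ (0.001 mg/kg) — but is provided for reuse with noisier datasets.
#'
#' @inheritParams validate_samples
#' @param loq Limit of quantification, mg/kg.
#' @return The sample table with sub-LOQ `cd_conc` values replaced.
#' @export
censor_below_loq <- function(samples, loq) {
  samples <- validate_samples(samples)
  below <- samples$cd_conc < loq
  if (any(below)) {
    message(sum(below), " concentration(s) below LOQ replaced by LOQ/2")
    samples$cd_conc[below] <- loq / 2
  }
  samples
}

#' Toxicological constants for the cadmium risk models
#'
#' Bundles every constant the exposure equations use, with the study's
#' values as defaults:
#' \describe{
#'   \item{ptwi}{provisional tolerable weekly intake, ug/kg bw/week (EFSA, 2.5)}
#'   \item{rfd}{oral reference dose, mg/kg/day (1e-3; USEPA-cited value,
#'     recorded here as an assumption since sources print it inconsistently)}
#'   \item{csf}{cancer slope factor, (mg/kg/day)^-1 (6.1)}
#'   \item{cf}{unit conversion factor, 1e-3 (grams to kilograms)}
#'   \item{ef}{exposure frequency, days/year (350)}
#'   \item{at_c}{carcinogenic averaging time, days (25550 = 70 y x 365 d)}
#'   \item{mrl}{named MRL schedule, mg/kg, by cacao category}
#' }
#' Constants can be stored in and read from a YAML file so a whole analysis
#' is reproducible from config + seed.
#'
#' @param path Path to a YAML config file.
#' @param constants A constants list as returned by [default_constants()].
#' @return A validated named list of class `tox_constants`.
#' @examples
#' consts <- default_constants()
#' consts$ptwi
#' @export
default_constants <- function() {
  validate_constants(list(
    ptwi = 2.5,
    rfd = 1e-3,
    csf = 6.1,
    cf = 1e-3,
    ef = 350,
    at_c = 25550,
    mrl = list(milk_lt30 = 0.1, milk_30to50 = 0.3, dark_ge50 = 0.8)
  ))
}

#' @rdname default_constants
#' @export
validate_constants <- function(constants) {
  required <- c("ptwi", "rfd", "csf", "cf", "ef", "at_c", "mrl")
  missing_fields <- setdiff(required, names(constants))
  if (length(missing_fields) > 0) {
    rlang::abort(paste0(
      "Constants config is missing field(s): ",
      paste(missing_fields, collapse = ", ")
    ), class = "chocrisk_schema_error")
  }
  scalars <- c("ptwi", "rfd", "csf", "cf", "ef", "at_c")
  for (f in scalars) {
    v <- constants[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      rlang::abort(paste0("Constant '", f, "' must be a single positive number"))
    }
  }
  if (any(unlist(constants$mrl) <= 0)) {
    rlang::abort("All MRL values must be positive")
  }
  structure(constants[required], class = "tox_constants")
}

#' @rdname default_constants
#' @export
read_constants <- function(path) {
  validate_constants(yaml::read_yaml(path))
}

#' @rdname default_constants
#' @export
write_constants <- function(constants, path) {
  constants <- validate_constants(constants)
  yaml::write_yaml(unclass(constants), path)
  invisible(path)
}

#' Consumer population groups and their consumption parameters
#'
#' One row per consumer class with weekly chocolate ingestion rates
#' (`ingr_w_milk`, `ingr_w_dark`, kg chocolate per kg body weight per week),
#' exposure duration (`ed_years`) and a nominal body weight (`bw_nominal`,
#' kg, used only in absolute-intake mode).
#'
#' The default table carries the study's seven Serbian consumer groups with
#' the published weekly ingestion rates and exposure durations (2 y for
#' toddlers, 5 y other children, 7 y adolescents, 15 y elderly, 30 y adults,
#' pregnant women and vegetarians). Nominal body weights are EFSA default
#' values (12, 23, 43.4 and 70 kg), an assumption documented here because
#' the source study does not print them.
#'
#' @param x,path A data frame, or a CSV path, holding the five columns above.
#' @return A validated tibble with columns `group`, `ingr_w_milk`,
#'   `ingr_w_dark`, `ed_years`, `bw_nominal`.
#' @export
default_population <- function() {
  validate_population(tibble::tibble(
    group = c(
      "toddlers", "other_children", "adolescents", "adults",
      "elderly", "pregnant_women", "vegetarians"
    ),
    ingr_w_milk = c(0.00703, 0.00589, 0.00350, 0.00259, 0.00179, 0.00186, 0.00322),
    ingr_w_dark = c(0.00525, 0.00547, 0.00157, 0.00154, 0.00134, 0.00214, 0.00211),
    ed_years = c(2, 5, 7, 30, 15, 30, 30),
    bw_nominal = c(12, 23, 43.4, 70, 70, 70, 70)
  ))
}

#' @rdname default_population
#' @export
validate_population <- function(x) {
  required <- c("group", "ingr_w_milk", "ingr_w_dark", "ed_years", "bw_nominal")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "Population table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "chocrisk_schema_error")
  }
  x <- tibble::as_tibble(x)[required]
  bad <- which(
    x$ingr_w_milk < 0 | x$ingr_w_dark < 0 | x$ed_years <= 0 | x$bw_nominal <= 0
  )
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Invalid population rows (ingestion rates must be >= 0, ",
      "ed_years and bw_nominal > 0): row(s) ", paste(bad, collapse = ", ")
    ), class = "chocrisk_validation_error")
  }
  if (anyDuplicated(x$group)) rlang::abort("Duplicate group names in population table")
  x
}

#' @rdname default_population
#' @export
read_population <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("Population file not found: ", path))
  validate_population(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname default_population
#' @param population A validated population table.
#' @export
write_population <- function(population, path) {
  population <- validate_population(population)
  readr::write_csv(population, path)
  invisible(path)
}
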