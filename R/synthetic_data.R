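#' Fit a lognormal distribution from its arithmetic mean and median
#'
#' For a lognormal variable, median = exp(mu) and mean = exp(mu + sigma^2/2),
#' so mu = ln(median) and sigma = sqrt(2 ln(mean/median)). This is the
#' closed-form bridge from published group summary statistics to the
#' lognormal concentration model: no raw data are needed. A mean below the
#' median is infeasible for a lognormal and raises an error.
#'
#' @param arith_mean Arithmetic mean, same units as `median`, positive.
#' @param median Median, positive, at most `arith_mean`.
#' @return A list with `meanlog` and `sdlog`.
#' @examples
#' fit_lognormal_from_summary(0.057, 0.042)
#' @export
fit_lognormal_from_summary <- function(arith_mean, median) {
  if (!(median > 0)) rlang::abort("median must be strictly positive")
  if (arith_mean < median) {
    rlang::abort(
      "arith_mean < median: no lognormal distribution has these summaries",
      class = "chocrisk_infeasible_error"
    )
  }
  list(meanlog = log(median), sdlog = sqrt(2 * log(arith_mean / median)))
}

#' Published per-category cadmium summary statistics
#'
#' The group structure of the study's concentration data: three regulatory
#' categories with sample count, concentration range, mean and median
#' (mg/kg). The milk <30 % category's published median exceeds its own
#' published maximum — an internal inconsistency in the source table — so
#' it is stored as `NA` and the generator falls back to the range midpoint
#' for that group.
#'
#' @return A tibble with columns `category`, `chocolate_type`, `cacao_low`,
#'   `cacao_high`, `n`, `c_min`, `c_max`, `c_mean`, `c_median`.
#' @export
published_category_summaries <- function() {
  tibble::tibble(
    category = c("milk_lt30", "milk_30to50", "dark_ge50"),
    chocolate_type = c("milk", "milk", "dark"),
    cacao_low = c(0, 30, 50),
    cacao_high = c(30, 50, 100),
    n = c(3L, 98L, 49L),
    c_min = c(0.013, 0.010, 0.014),
    c_max = c(0.030, 0.17, 0.29),
    c_mean = c(0.024, 0.028, 0.057),
    c_median = c(NA, 0.023, 0.042)
  )
}

validate_specs <- function(specs) {
  required <- c(
    "category", "chocolate_type", "cacao_low", "cacao_high",
    "n", "c_min", "c_max", "c_mean", "c_median"
  )
  missing_cols <- setdiff(required, names(specs))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "Summary spec table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "chocrisk_schema_error")
  }
  bad <- which(
    specs$n < 1 |
      specs$c_min > specs$c_max |
      specs$c_mean < specs$c_min | specs$c_mean > specs$c_max |
      (!is.na(specs$c_median) &
        (specs$c_median < specs$c_min | specs$c_median > specs$c_max))
  )
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Invalid summary spec row(s): ", paste(bad, collapse = ", "),
      " (need n >= 1 and c_min <= c_mean/c_median <= c_max)"
    ), class = "chocrisk_validation_error")
  }
  specs
}

# Rejection sampling from a lognormal truncated to [lower, upper]: draws
# never touch the bounds by clamping, so the truncated density has no
# boundary atoms. Errors out if the acceptance probability is < 1e-4.
draw_truncated_lognormal <- function(n, meanlog, sdlog, lower, upper, label = "") {
  if (lower == upper) {
    # degenerate range: exp(meanlog) equals the bound up to rounding
    if (abs(exp(meanlog) - lower) > 1e-9 * max(lower, 1)) {
      rlang::abort(paste0("Degenerate range excludes the fitted median for ", label))
    }
    return(rep(lower, n))
  }
  if (sdlog == 0) {
    x <- exp(meanlog)
    if (x < lower || x > upper) {
      rlang::abort(paste0("Degenerate lognormal outside bounds for ", label))
    }
    return(rep(x, n))
  }
  p_accept <- stats::plnorm(upper, meanlog, sdlog) -
    stats::plnorm(lower, meanlog, sdlog)
  if (p_accept < 1e-4) {
    rlang::abort(
      paste0(
        "Infeasible truncation for group '", label,
        "': acceptance probability ", signif(p_accept, 3), " < 1e-4"
      ),
      class = "chocrisk_infeasible_error"
    )
  }
  out <- numeric(0)
  while (length(out) < n) {
    batch <- ceiling((n - length(out)) / p_accept) + 16L
    x <- stats::rlnorm(batch, meanlog, sdlog)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic per-sample concentration dataset
#'
#' For each summary-spec row, fits a lognormal from the group's mean and
#' median (falling back to the range midpoint, with a message, when the
#' median is missing or inconsistent with the range) and draws `n x scale`
#' concentrations from it truncated to \[c_min, c_max\] by rejection, so
#' every generated value respects the published range. Cacao content is
#' drawn uniformly within the category's bounds; it determines the MRL
#' category but not the risk indices. Identical seeds yield identical
#' datasets.
#'
#' @param specs Summary spec table, see [published_category_summaries()].
#' @param seed Integer seed.
#' @param scale Sample-count multiplier (e.g. `scale = 100` to study the
#'   generator's large-sample behaviour).
#' @return A validated sample table ([validate_samples()]) with
#'   `sum(round(n * scale))` rows.
#' @examples
#' samples <- generate_cd_dataset(published_category_summaries(), seed = 1)
#' table(samples$chocolate_type)
#' @export
generate_cd_dataset <- function(specs, seed, scale = 1) {
  specs <- validate_specs(specs)
  withr::with_seed(as.integer(seed), {
    rows <- purrr::pmap(specs, function(category, chocolate_type, cacao_low,
                                        cacao_high, n, c_min, c_max, c_mean,
                                        c_median) {
      n_draw <- max(1L, as.integer(round(n * scale)))
      med <- c_median
      if (is.na(med) || med > c_max || med < c_min || med > c_mean) {
        med <- (c_min + c_max) / 2
        message(
          "Group '", category, "': published median unusable; ",
          "fitting from mean and range midpoint (", med, " mg/kg)"
        )
      }
      fit <- fit_lognormal_from_summary(c_mean, med)
      conc <- draw_truncated_lognormal(
        n_draw, fit$meanlog, fit$sdlog, c_min, c_max,
        label = category
      )
      tibble::tibble(
        chocolate_type = chocolate_type,
        cacao_pct = stats::runif(n_draw, cacao_low, cacao_high),
        cd_conc = conc
      )
    })
    out <- dplyr::bind_rows(rows)
    out$sample_id <- sprintf("SYN-%03d", seq_len(nrow(out)))
    validate_samples(out)
  })
}

#' Built-in synthetic study fixture
#'
#' Bundles everything the pipeline needs into one reproducible input set:
#' a 150-sample synthetic concentration table generated from the published
#' per-category summary statistics (3 + 98 + 49 samples), the seven-group
#' population table with the published weekly ingestion rates and exposure
#' durations, and the default toxicological constants. The concentration
#' values are synthetic — drawn to match the published group summaries, not
#' measured — which is what makes every downstream stage testable without
#' the unpublished raw data.
#'
#' @param seed Integer seed for the concentration draws.
#' @return A list with elements `samples`, `population`, `constants`.
#' @examples
#' fx <- builtin_study_fixture(seed = 1)
#' nrow(fx$samples)
#' @export
builtin_study_fixture <- function(seed = 20240101) {
  list(
    samples = suppressMessages(generate_cd_dataset(published_category_summaries(), seed = seed)),
    population = default_population(),
    constants = default_constants()
  )
}
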