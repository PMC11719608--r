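#' Estimated weekly intake of cadmium
#'
#' EWI = IngR_w x C, where C is the cadmium concentration in ug/kg and
#' IngR_w the weekly chocolate ingestion rate in kg chocolate per kg body
#' weight per week, giving ug Cd per kg bw per week. Callers working from
#' mg/kg concentrations multiply by 1000 before the call.
#'
#' @param c_ugkg Cadmium concentration, ug/kg; vectorized.
#' @param ingr_w Weekly ingestion rate, kg/kg bw/week; vectorized.
#' @return Estimated weekly intake, ug/kg bw/week.
#' @examples
#' ewi(290, 0.00525) # the study's maximum dark-chocolate intake for toddlers
#' @export
ewi <- function(c_ugkg, ingr_w) {
  if (any(c_ugkg < 0) || any(ingr_w < 0)) {
    rlang::abort("Concentration and ingestion rate must be non-negative")
  }
  c_ugkg * ingr_w
}

#' Weekly intake as a percentage of the tolerable limit
#'
#' @param ewi_value Estimated weekly intake, ug/kg bw/week; vectorized.
#' @param ptwi Provisional tolerable weekly intake, ug/kg bw/week
#'   (EFSA value for cadmium: 2.5).
#' @return 100 * ewi / ptwi, percent.
#' @examples
#' pct_ptwi(ewi(290, 0.00525), 2.5)
#' @export
pct_ptwi <- function(ewi_value, ptwi = 2.5) {
  if (ptwi <= 0) rlang::abort("ptwi must be strictly positive")
  100 * ewi_value / ptwi
}

#' Convert a weekly per-body-weight ingestion rate to a daily one
#'
#' Inverts the weekly aggregation used for EWI: a rate in kg chocolate per
#' kg bw per week divided by seven days and converted from kg to g gives
#' g/kg bw/day, the unit the dose equations use.
#'
#' @param ingr_w Weekly ingestion rate, kg/kg bw/week; vectorized.
#' @return Daily ingestion rate, g/kg bw/day.
#' @export
daily_from_weekly <- function(ingr_w) {
  if (any(ingr_w < 0)) rlang::abort("ingr_w must be non-negative")
  ingr_w / 7 * 1000
}

#' Non-carcinogenic hazard quotient for chronic cadmium exposure
#'
#' HQ = (EF x ED x C x IngR_d x CF) / (AT_nc x BW x RfD), the USEPA chronic
#' dose over the oral reference dose. The non-carcinogenic averaging time
#' AT_nc is always derived internally as 365 x ED days, which makes HQ
#' algebraically independent of the exposure duration:
#' HQ = (EF / 365) x C x IngR_d x CF / (BW x RfD).
#'
#' Two intake conventions are supported. In the default per-body-weight
#' mode (`bw = NULL`) `ingr_d` is in g chocolate per kg bw per day and BW is
#' omitted from the equation. In absolute mode `ingr_d` is in g/day and is
#' divided by the body weight `bw` in kg; this is the form under which body
#' weight can be treated as an uncertain input in the Monte Carlo model.
#'
#' @param c_mgkg Cadmium concentration, mg/kg; vectorized.
#' @param ingr_d Daily ingestion rate: g/kg bw/day (per-bw mode) or g/day
#'   (absolute mode); vectorized.
#' @param constants Toxicological constants, see [default_constants()].
#' @param ed_years Exposure duration, years (cancels out of HQ; kept in the
#'   signature because the dose numerator is defined with it).
#' @param bw Body weight in kg for absolute mode, or `NULL` (default) for
#'   per-body-weight mode.
#' @return Dimensionless hazard quotient; values above 1 flag potential
#'   non-carcinogenic effects.
#' @examples
#' hq(0.29, 0.75, default_constants(), ed_years = 2)
#' @export
hq <- function(c_mgkg, ingr_d, constants = default_constants(), ed_years, bw = NULL) {
  constants <- validate_constants(constants)
  if (any(c_mgkg < 0) || any(ingr_d < 0)) {
    rlang::abort("Concentration and ingestion rate must be non-negative")
  }
  if (any(ed_years <= 0)) rlang::abort("ed_years must be strictly positive")
  bw_div <- if (is.null(bw)) 1 else bw
  if (any(bw_div <= 0)) rlang::abort("bw must be strictly positive")
  # AT_nc = 365 * ED makes ED cancel exactly; evaluating the reduced form
  # keeps the invariance bit-exact instead of merely approximate
  (constants$ef * c_mgkg * ingr_d * constants$cf) /
    (365 * bw_div * constants$rfd)
}

#' Incremental lifetime cancer risk from cadmium exposure
#'
#' CR = (EF x ED x C x IngR_d x CF x CSF) / (AT_c x BW), the lifetime
#' average daily dose times the cancer slope factor, averaged over the
#' carcinogenic averaging time AT_c (25,550 days, a 70-year lifetime).
#' Unlike HQ, CR grows linearly with the exposure duration. Intake modes
#' are as for [hq()].
#'
#' @inheritParams hq
#' @return Dimensionless incremental lifetime cancer probability.
#' @examples
#' cr(0.29, 0.75, default_constants(), ed_years = 30)
#' @export
cr <- function(c_mgkg, ingr_d, constants = default_constants(), ed_years, bw = NULL) {
  constants <- validate_constants(constants)
  if (any(c_mgkg < 0) || any(ingr_d < 0)) {
    rlang::abort("Concentration and ingestion rate must be non-negative")
  }
  if (any(ed_years <= 0)) rlang::abort("ed_years must be strictly positive")
  bw_div <- if (is.null(bw)) 1 else bw
  if (any(bw_div <= 0)) rlang::abort("bw must be strictly positive")
  (constants$ef * ed_years * c_mgkg * ingr_d * constants$cf * constants$csf) /
    (constants$at_c * bw_div)
}

#' Risk classification thresholds
#'
#' HQ at or below 1 is classified `safe`, above 1 `adverse`. CR at or below
#' 1e-6 is `negligible`, up to 1e-4 `moderate`, and above 1e-4
#' `unacceptable`. Boundaries are inclusive on the lower-risk side, as the
#' guidance phrases them.
#'
#' @param hq_value,cr_value Index values; vectorized.
#' @return A character vector of class labels (ordered factors would hide
#'   the threshold logic; plain characters keep the table exportable).
#' @examples
#' classify_hq(c(0.165, 1, 2))
#' classify_cr(c(1e-7, 2e-5, 2e-4))
#' @export
classify_hq <- function(hq_value) {
  if (any(hq_value < 0)) rlang::abort("HQ must be non-negative")
  ifelse(hq_value <= 1, "safe", "adverse")
}

#' @rdname classify_hq
#' @export
classify_cr <- function(cr_value) {
  if (any(cr_value < 0)) rlang::abort("CR must be non-negative")
  dplyr::case_when(
    cr_value <= 1e-6 ~ "negligible",
    cr_value <= 1e-4 ~ "moderate",
    .default = "unacceptable"
  )
}

#' Point-estimate risk indices for every sample x group combination
#'
#' Evaluates EWI, %PTWI, HQ and CR for each sample under each population
#' group, using the ingestion rate that matches the sample's chocolate type
#' (milk-chocolate rates for milk samples, dark for dark). In per-bw mode
#' daily rates are derived from the weekly ones; in absolute mode they are
#' additionally scaled by the group's nominal body weight, which then
#' divides the dose again — the two modes agree at the nominal body weight.
#'
#' @inheritParams check_compliance
#' @param population Population table, see [default_population()].
#' @param constants Toxicological constants, see [default_constants()].
#' @param mode `"per_bw"` (default) or `"absolute"` intake convention.
#' @return A long tibble with one row per sample x group: identifiers, the
#'   four indices, and `hq_class` / `cr_class` labels.
#' @examples
#' fx <- builtin_study_fixture(seed = 1)
#' risk <- risk_table(fx$samples, fx$population, fx$constants)
#' head(risk)
#' @export
risk_table <- function(samples, population = default_population(),
                       constants = default_constants(),
                       mode = c("per_bw", "absolute")) {
  mode <- match.arg(mode)
  samples <- validate_samples(samples)
  population <- validate_population(population)
  constants <- validate_constants(constants)

  grid <- tidyr::crossing(
    samples,
    tidyr::nest(population, group_data = -"group")
  )
  grid <- tidyr::unnest(grid, "group_data")

  ingr_w <- ifelse(grid$chocolate_type == "milk", grid$ingr_w_milk, grid$ingr_w_dark)
  ingr_d <- daily_from_weekly(ingr_w)
  bw <- NULL
  if (mode == "absolute") {
    ingr_d <- ingr_d * grid$bw_nominal
    bw <- grid$bw_nominal
  }

  ewi_v <- ewi(grid$cd_conc * 1000, ingr_w)
  tibble::tibble(
    sample_id = grid$sample_id,
    group = grid$group,
    chocolate_type = grid$chocolate_type,
    ewi = ewi_v,
    pct_ptwi = pct_ptwi(ewi_v, constants$ptwi),
    hq = hq(grid$cd_conc, ingr_d, constants, grid$ed_years, bw),
    cr = cr(grid$cd_conc, ingr_d, constants, grid$ed_years, bw)
  ) |>
    dplyr::mutate(
      hq_class = classify_hq(.data$hq),
      cr_class = classify_cr(.data$cr)
    )
}

#' Summarize risk indices per population group
#'
#' Collapses a long risk table to min/mean/max per group and endpoint, plus
#' the fraction of samples in each cancer-risk class. Summaries pool milk
#' and dark samples (each evaluated under its own type's ingestion rate);
#' set `by_type = TRUE` to additionally stratify by chocolate type.
#'
#' @param risk A long risk table from [risk_table()].
#' @param by_type Also stratify by `chocolate_type`?
#' @return A tibble with one row per group (x type) x endpoint holding
#'   `min`, `mean`, `max`, and for CR the class fractions
#'   `frac_negligible`, `frac_moderate`, `frac_unacceptable`.
#' @export
summarize_risk <- function(risk, by_type = FALSE) {
  if (nrow(risk) == 0) rlang::abort("Cannot summarize an empty risk table")
  keys <- if (by_type) c("group", "chocolate_type") else "group"
  long <- tidyr::pivot_longer(
    risk,
    cols = c("ewi", "pct_ptwi", "hq", "cr"),
    names_to = "endpoint", values_to = "value"
  )
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "endpoint")))) |>
    dplyr::summarise(
      min = min(.data$value),
      mean = mean(.data$value),
      max = max(.data$value),
      .groups = "drop"
    )
  fracs <- risk |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      frac_negligible = mean(.data$cr_class == "negligible"),
      frac_moderate = mean(.data$cr_class == "moderate"),
      frac_unacceptable = mean(.data$cr_class == "unacceptable"),
      .groups = "drop"
    )
  dplyr::left_join(out, fracs, by = keys) |>
    dplyr::mutate(dplyr::across(
      dplyr::starts_with("frac_"),
      ~ ifelse(.data$endpoint == "cr", .x, NA_real_)
    ))
}
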