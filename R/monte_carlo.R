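#' Declarative random-variable specifications
#'
#' The Monte Carlo engine describes every model input with one of three
#' distribution families, mirroring common spreadsheet risk tools: a
#' degenerate `point` value for fixed constants, a `triangular`
#' (min, mode, max) for bounded judgement-based inputs such as ingestion
#' rates and exposure frequency, and a `lognormal` for strictly positive
#' skewed quantities such as concentrations and body weight.
#'
#' Two alternative lognormal constructors fit the log-scale parameters from
#' summary statistics: `dist_lognormal_from_summary()` from the arithmetic
#' mean and the median (meanlog = ln median, sdlog = sqrt(2 ln(mean/median)),
#' from mean = exp(mu + sigma^2/2) and median = exp(mu)), and
#' `dist_lognormal_from_cv()` from the arithmetic mean and the coefficient
#' of variation (sdlog = sqrt(ln(1 + cv^2))).
#'
#' @param value Point value (finite).
#' @param min,mode,max Triangular parameters, min <= mode <= max.
#' @param meanlog,sdlog Log-scale mean and standard deviation, sdlog >= 0.
#' @param arith_mean,median,cv Summary statistics on the natural scale.
#' @return A `dist_spec` object.
#' @examples
#' dist_triangular(300, 350, 365)
#' dist_lognormal_from_summary(0.057, 0.042)
#' @export
dist_point <- function(value) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value)) {
    rlang::abort("Point value must be a single finite number")
  }
  new_dist("point", value = value)
}

#' @rdname dist_point
#' @export
dist_triangular <- function(min, mode, max) {
  if (!(min <= mode && mode <= max)) {
    rlang::abort("Triangular parameters must satisfy min <= mode <= max")
  }
  new_dist("triangular", min = min, mode = mode, max = max)
}

#' @rdname dist_point
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  if (sdlog < 0) rlang::abort("sdlog must be non-negative")
  new_dist("lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @rdname dist_point
#' @export
dist_lognormal_from_summary <- function(arith_mean, median) {
  fit <- fit_lognormal_from_summary(arith_mean, median)
  dist_lognormal(fit$meanlog, fit$sdlog)
}

#' @rdname dist_point
#' @export
dist_lognormal_from_cv <- function(arith_mean, cv) {
  if (arith_mean <= 0 || cv < 0) {
    rlang::abort("arith_mean must be positive and cv non-negative")
  }
  sdlog <- sqrt(log(1 + cv^2))
  dist_lognormal(log(arith_mean) - sdlog^2 / 2, sdlog)
}

new_dist <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  params <- x[setdiff(names(x), "kind")]
  cat(
    "<dist_spec> ", x$kind, "(",
    paste(names(params), signif(unlist(params), 6), sep = " = ", collapse = ", "),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' Draw from a distribution specification
#'
#' Point specs return a constant vector; triangular draws use the inverse
#' CDF so every draw lies in \[min, max\]; lognormal draws are
#' `exp(rnorm(meanlog, sdlog))`. With `seed` given, draws are produced on a
#' private RNG stream and are reproducible without disturbing the caller's
#' RNG state.
#'
#' @param dist A `dist_spec`.
#' @param n Number of draws.
#' @param seed Optional integer seed for a private stream.
#' @return A numeric vector of length `n`.
#' @examples
#' sample_dist(dist_triangular(1, 2, 3), 5, seed = 1)
#' @export
sample_dist <- function(dist, n, seed = NULL) {
  if (!inherits(dist, "dist_spec")) rlang::abort("dist must be a dist_spec")
  if (n < 1) rlang::abort("n must be at least 1")
  draw <- function() {
    switch(dist$kind,
      point = rep(dist$value, n),
      triangular = qtri(stats::runif(n), dist$min, dist$mode, dist$max),
      lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
      rlang::abort(paste0("Unknown distribution kind: ", dist$kind))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Triangular quantile function (inverse CDF) on [a, b] with mode m.
# No installed package provides one; the closed form is standard.
qtri <- function(p, a, m, b) {
  if (a == b) {
    return(rep(a, length(p)))
  }
  fc <- (m - a) / (b - a)
  ifelse(
    p < fc,
    a + sqrt(p * (b - a) * (m - a)),
    b - sqrt((1 - p) * (b - a) * (b - m))
  )
}

#' Build the default Monte Carlo model for one group and endpoint
#'
#' Assembles the distribution assignments of the probabilistic risk model:
#' concentrations lognormal (fitted per chocolate type from the sample
#' data's arithmetic mean and median), ingestion rates and exposure
#' frequency triangular, body weight lognormal, and every remaining
#' constant a point value. The families follow the probabilistic model
#' specification; the spreads are this package's documented defaults, since
#' no spread parameters are published: triangular ingestion rates at
#' (0.8, 1.0, 1.2) x nominal, exposure frequency at (300, 350, 365)
#' days/year, body weight lognormal with CV 0.2 around the nominal weight.
#'
#' In `absolute` mode (the default, and the only mode in which a body-weight
#' distribution is meaningful) ingestion rates are in g/day and body weight
#' divides the dose; in `per_bw` mode rates are in g/kg bw/day and the model
#' carries no BW symbol.
#'
#' @param endpoint `"HQ"` or `"CR"`.
#' @param group Population group name (must appear in `population`).
#' @param samples Sample table used to fit the concentration distributions.
#' @param population Population table, see [default_population()].
#' @param constants Toxicological constants, see [default_constants()].
#' @param iterations Number of Monte Carlo repetitions (default 10,000).
#' @param seed Root seed; per-symbol streams are derived from it so adding
#'   a symbol does not perturb the other symbols' draws.
#' @param mode Intake convention, `"absolute"` or `"per_bw"`.
#' @param ingr_spread Half-width of the ingestion-rate triangular, as a
#'   fraction of the nominal rate.
#' @param ef_tri Exposure-frequency triangular (min, mode, max), days/year.
#' @param bw_cv Coefficient of variation of the body-weight lognormal.
#' @return An `mcs_model` list: endpoint, group, mode, iterations, seed and
#'   a named list of `dist_spec`s for every symbol of the dose equation.
#' @examples
#' fx <- builtin_study_fixture(seed = 1)
#' m <- default_mcs_model("HQ", "adults", fx$samples, fx$population, fx$constants,
#'   iterations = 1000, seed = 42
#' )
#' names(m$dists)
#' @export
default_mcs_model <- function(endpoint = c("HQ", "CR"), group, samples,
                              population = default_population(),
                              constants = default_constants(),
                              iterations = 10000, seed = 1,
                              mode = c("absolute", "per_bw"),
                              ingr_spread = 0.2, ef_tri = c(300, 350, 365),
                              bw_cv = 0.2) {
  endpoint <- match.arg(endpoint)
  mode <- match.arg(mode)
  samples <- validate_samples(samples)
  population <- validate_population(population)
  constants <- validate_constants(constants)
  row <- population[population$group == group, ]
  if (nrow(row) != 1) rlang::abort(paste0("Unknown population group: ", group))

  conc_dist <- function(type) {
    x <- samples$cd_conc[samples$chocolate_type == type]
    if (length(x) == 0) {
      return(dist_point(0))
    }
    m <- mean(x)
    med <- stats::median(x)
    if (m >= med && med > 0) {
      dist_lognormal_from_summary(m, med)
    } else {
      # empirical mean below median: not lognormal-feasible from these two
      # summaries, fall back to a mean/CV fit
      dist_lognormal_from_cv(m, stats::sd(x) / m)
    }
  }

  ingr_dist <- function(weekly) {
    nominal <- daily_from_weekly(weekly)
    if (mode == "absolute") nominal <- nominal * row$bw_nominal
    if (nominal == 0) {
      return(dist_point(0))
    }
    dist_triangular((1 - ingr_spread) * nominal, nominal, (1 + ingr_spread) * nominal)
  }

  dists <- list(
    C_milk = conc_dist("milk"),
    C_dark = conc_dist("dark"),
    IngR_milk = ingr_dist(row$ingr_w_milk),
    IngR_dark = ingr_dist(row$ingr_w_dark),
    EF = dist_triangular(ef_tri[1], ef_tri[2], ef_tri[3]),
    ED = dist_point(row$ed_years),
    CF = dist_point(constants$cf)
  )
  if (mode == "absolute") {
    dists$BW <- dist_lognormal_from_cv(row$bw_nominal, bw_cv)
  }
  if (endpoint == "HQ") {
    dists$RfD <- dist_point(constants$rfd)
  } else {
    dists$CSF <- dist_point(constants$csf)
    dists$AT <- dist_point(constants$at_c)
  }

  structure(
    list(
      endpoint = endpoint, group = group, mode = mode,
      iterations = iterations, seed = seed, dists = dists
    ),
    class = "mcs_model"
  )
}

# Stable sub-seed for a symbol's private stream: a change to one symbol's
# spec or the addition of a symbol leaves every other stream untouched.
symbol_seed <- function(seed, name) {
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 104729L
  (abs(as.integer(seed)) %% 1000003L) * 1009L + h
}

#' Run a seeded Monte Carlo simulation of the HQ or CR model
#'
#' Draws every symbol of the dose equation independently on its own
#' seed-derived stream and evaluates the endpoint per iteration. Milk and
#' dark chocolate exposures are evaluated with their own concentration and
#' ingestion-rate draws and summed into one intake term. For HQ the
#' non-carcinogenic averaging time is derived as 365 x ED per iteration, so
#' the point-collapse identity with the deterministic [hq()] holds exactly.
#' Non-positive reference-dose draws (possible only with a user-supplied
#' stochastic RfD spec) are rejected and redrawn, with a message.
#'
#' @param model An `mcs_model`, e.g. from [default_mcs_model()].
#' @return An `mcs_result` list: `draws` (tibble, iterations x symbols),
#'   `output` (numeric vector), `percentiles` (tibble of the requested
#'   percentiles), plus the model echo (`endpoint`, `group`, `mode`,
#'   `iterations`, `seed`, `model`).
#' @param probs Percentiles to report, in \[0, 100\].
#' @examples
#' fx <- builtin_study_fixture(seed = 1)
#' m <- default_mcs_model("HQ", "toddlers", fx$samples, fx$population, fx$constants,
#'   iterations = 2000, seed = 7
#' )
#' res <- run_mcs(m)
#' res$percentiles
#' @export
run_mcs <- function(model, probs = c(5, 50, 90, 95, 99)) {
  if (!inherits(model, "mcs_model")) rlang::abort("model must be an mcs_model")
  if (model$iterations < 1) rlang::abort("iterations must be at least 1")
  required <- c("C_milk", "C_dark", "IngR_milk", "IngR_dark", "EF", "ED", "CF")
  required <- c(required, if (model$mode == "absolute") "BW")
  required <- c(required, if (model$endpoint == "HQ") "RfD" else c("CSF", "AT"))
  missing_syms <- setdiff(required, names(model$dists))
  if (length(missing_syms) > 0) {
    rlang::abort(paste0(
      "Model is missing distribution spec(s) for: ",
      paste(missing_syms, collapse = ", ")
    ), class = "chocrisk_spec_error")
  }

  n <- model$iterations
  draws <- lapply(required, function(sym) {
    sample_dist(model$dists[[sym]], n, seed = symbol_seed(model$seed, sym))
  })
  names(draws) <- required

  if (model$endpoint == "HQ") {
    bad <- draws$RfD <= 0
    tries <- 0
    while (any(bad) && tries < 100) {
      tries <- tries + 1
      message("Redrawing ", sum(bad), " non-positive RfD draw(s)")
      draws$RfD[bad] <- sample_dist(
        model$dists$RfD, sum(bad),
        seed = symbol_seed(model$seed, paste0("RfD_redraw_", tries))
      )
      bad <- draws$RfD <= 0
    }
    if (any(bad)) rlang::abort("RfD spec keeps producing non-positive draws")
  }

  intake <- draws$C_milk * draws$IngR_milk + draws$C_dark * draws$IngR_dark
  bw_div <- if (model$mode == "absolute") draws$BW else 1
  output <- if (model$endpoint == "HQ") {
    # AT_nc = 365 * ED cancels ED; reduced form matches hq() bit-exactly
    (draws$EF * intake * draws$CF) / (365 * bw_div * draws$RfD)
  } else {
    (draws$EF * draws$ED * intake * draws$CF * draws$CSF) /
      (draws$AT * bw_div)
  }

  structure(
    list(
      endpoint = model$endpoint,
      group = model$group,
      mode = model$mode,
      iterations = n,
      seed = model$seed,
      draws = tibble::as_tibble(draws),
      output = output,
      percentiles = tibble::tibble(
        p = probs,
        value = percentile(output, probs)
      ),
      model = model
    ),
    class = "mcs_result"
  )
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(
    "<mcs_result> ", x$endpoint, " for ", x$group, " (", x$mode, " mode, ",
    x$iterations, " iterations, seed ", x$seed, ")\n",
    sep = ""
  )
  print(x$percentiles)
  invisible(x)
}

#' Percentile of a sample by linear interpolation
#'
#' Linear interpolation between order statistics (the "type 7" quantile
#' convention, R's default), stated explicitly because percentile
#' definitions differ between risk tools: p = 0 returns the minimum and
#' p = 100 the maximum.
#'
#' @param values Non-empty numeric vector.
#' @param p Percentile(s) in \[0, 100\].
#' @return Interpolated percentile value(s).
#' @examples
#' percentile(c(0, 10), 90)
#' @export
percentile <- function(values, p) {
  if (length(values) == 0) rlang::abort("values must be non-empty")
  if (any(p < 0 | p > 100)) rlang::abort("p must lie in [0, 100]")
  stats::quantile(values, probs = p / 100, type = 7, names = FALSE)
}

#' Monte Carlo percentile summary across groups and endpoints
#'
#' Convenience wrapper running [run_mcs()] for every group x endpoint
#' combination under the default model, returning one tidy percentile table
#' and (optionally) the full results for sensitivity analysis.
#'
#' @inheritParams default_mcs_model
#' @param endpoints Endpoints to simulate.
#' @param groups Groups to simulate; defaults to all groups in `population`.
#' @param probs Percentiles to report.
#' @param keep_results Also return the full `mcs_result` objects?
#' @param ... Passed on to [default_mcs_model()] (spread overrides).
#' @return A tibble (group, endpoint, p, value); with `keep_results = TRUE`,
#'   a list with elements `percentiles` and `results`.
#' @export
run_mcs_all <- function(samples, population = default_population(),
                        constants = default_constants(),
                        endpoints = c("HQ", "CR"), groups = NULL,
                        iterations = 10000, seed = 1,
                        mode = c("absolute", "per_bw"),
                        probs = c(5, 50, 90, 95, 99),
                        keep_results = FALSE, ...) {
  mode <- match.arg(mode)
  population <- validate_population(population)
  if (is.null(groups)) groups <- population$group
  combos <- tidyr::crossing(group = groups, endpoint = endpoints)
  results <- purrr::pmap(combos, function(group, endpoint) {
    model <- default_mcs_model(
      endpoint, group, samples, population, constants,
      iterations = iterations,
      seed = symbol_seed(seed, paste(group, endpoint)),
      mode = mode, ...
    )
    run_mcs(model, probs = probs)
  })
  pct <- purrr::map2_dfr(
    purrr::transpose(list(g = combos$group, e = combos$endpoint)), results,
    function(k, res) {
      tibble::tibble(group = k$g, endpoint = k$e, p = res$percentiles$p,
                     value = res$percentiles$value)
    }
  )
  if (keep_results) {
    names(results) <- paste(combos$group, combos$endpoint, sep = ".")
    list(percentiles = pct, results = results)
  } else {
    pct
  }
}
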