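#' Contribution-to-variance sensitivity analysis
#'
#' Attributes the variability of a Monte Carlo output to its stochastic
#' inputs using the spreadsheet-risk-tool convention: for each input factor
#' the Spearman rank correlation with the output is computed, the squared
#' correlations are normalized to sum to 100 %, and each share keeps the
#' sign of its correlation (so a factor that drives risk *down*, such as
#' body weight in absolute-intake mode, carries a negative contribution).
#' Constant (point-distributed) factors contribute exactly 0. If the output
#' itself has zero variance the result is flagged degenerate and all
#' contributions are 0.
#'
#' @param draws Draw matrix or data frame, iterations x factors, row-aligned
#'   with `output` (e.g. the `draws` element of an `mcs_result`).
#' @param output Numeric output vector, one value per iteration.
#' @return A `sensitivity_result` tibble (`factor`, `contribution` in
#'   signed percent) ordered by descending absolute contribution, with a
#'   `degenerate` attribute.
#' @examples
#' fx <- builtin_study_fixture(seed = 1)
#' m <- default_mcs_model("HQ", "adults", fx$samples, fx$population, fx$constants,
#'   iterations = 2000, seed = 3
#' )
#' res <- run_mcs(m)
#' contribution_to_variance(res$draws, res$output)
#' @export
contribution_to_variance <- function(draws, output) {
  draws <- as.data.frame(draws)
  if (nrow(draws) != length(output)) {
    rlang::abort("draws and output must have the same number of rows")
  }
  if (nrow(draws) < 2) rlang::abort("At least 2 iterations are required")

  degenerate <- stats::var(output) == 0
  rho <- vapply(draws, function(x) {
    if (degenerate || stats::var(x) == 0) {
      return(0)
    }
    stats::cor(x, output, method = "spearman")
  }, numeric(1))

  total <- sum(rho^2)
  contribution <- if (total > 0) sign(rho) * 100 * rho^2 / total else rho * 0

  out <- tibble::tibble(factor = names(rho), contribution = unname(contribution))
  out <- out[order(-abs(out$contribution), out$factor), ]
  structure(out,
    class = c("sensitivity_result", class(out)),
    degenerate = degenerate
  )
}

#' Rank factors by absolute contribution
#'
#' @param result A `sensitivity_result` from [contribution_to_variance()].
#' @return Factor names in descending order of absolute contribution; ties
#'   are broken alphabetically.
#' @export
rank_factors <- function(result) {
  if (!inherits(result, "sensitivity_result")) {
    rlang::abort("result must come from contribution_to_variance()")
  }
  result$factor[order(-abs(result$contribution), result$factor)]
}

#' Sensitivity of an MCS result
#'
#' Convenience wrapper extracting the draw matrix and output vector of an
#' [run_mcs()] result.
#'
#' @param result An `mcs_result`.
#' @return A `sensitivity_result`, see [contribution_to_variance()].
#' @export
mcs_sensitivity <- function(result) {
  if (!inherits(result, "mcs_result")) rlang::abort("result must be an mcs_result")
  contribution_to_variance(result$draws, result$output)
}
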