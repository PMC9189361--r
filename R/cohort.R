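#' Default stage-structured cohort parameters
#'
#' One row per group with the sample size, the truncated-Gaussian methylation
#' model (`meth_mean`, `meth_sd`) and the linear links generating expression
#' from the methylation rate:
#' `mir23 = mir23_slope * meth + mir23_intercept + N(0, mir23_noise_sd)` and
#' likewise for `upa`. The four myeloma stage groups use the published
#' per-stage regression coefficients as generating links (miR-23 declining
#' and uPA rising with methylation), with group sizes 35/42/38/21; the B-cell
#' control group (n = 20) has no methylation-expression link (slope 0) and
#' sits at the extremes: lowest methylation and uPA, highest miR-23. Link
#' noise defaults to `|slope| * meth_sd`, i.e. a within-group signal-to-noise
#' ratio of 1 (per-link R^2 of about 0.5, matching the strongly significant
#' but noisy per-stage fits such data show).
#'
#' @return A tibble with columns `group`, `n`, `meth_mean`, `meth_sd`,
#'   `mir23_slope`, `mir23_intercept`, `mir23_noise_sd`, `upa_slope`,
#'   `upa_intercept`, `upa_noise_sd`.
#' @export
default_cohort_params <- function() {
  p <- tibble(
    group = c("Intraosseous", "Blood", "BoneTumor", "ExtraosseousTumor", "BCell"),
    n = c(35L, 42L, 38L, 21L, 20L),
    meth_mean = c(0.20, 0.70, 0.70, 0.85, 0.08),
    meth_sd = c(0.10, 0.10, 0.10, 0.10, 0.04),
    mir23_slope = c(-2.315, -10.39, -15.18, -49.70, 0),
    mir23_intercept = c(6.758, 12.61, 13.51, 21.43, 8.0),
    upa_slope = c(0.1224, 0.05848, 0.04807, 0.07975, 0),
    upa_intercept = c(0.4664, 1.879, 0.5024, 2.919, 0.25)
  )
  p |> mutate(
    mir23_noise_sd = ifelse(.data$mir23_slope == 0, 0.5,
                            abs(.data$mir23_slope) * .data$meth_sd),
    upa_noise_sd = ifelse(.data$upa_slope == 0, 0.05,
                          abs(.data$upa_slope) * .data$meth_sd)
  )
}

mm_groups <- function() c("Intraosseous", "Blood", "BoneTumor", "ExtraosseousTumor")

rnorm_trunc01 <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- out < 0 | out > 1
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < 0 | out > 1
  }
  out
}

#' Simulate a stage-structured cohort
#'
#' Draws, per group, methylation rates from a Gaussian truncated to `[0, 1]`
#' and expression values from the group's linear links with additive Gaussian
#' noise (see [default_cohort_params()]). `noise_scale` multiplies every link
#' noise SD (0 gives noiseless lines, useful for exact recovery checks).
#'
#' @param params Parameter tibble shaped like [default_cohort_params()];
#'   rows with unknown group labels are an error.
#' @param noise_scale Non-negative multiplier on the link noise SDs.
#' @param seed Integer seed.
#' @return A tibble of class `cohort_table` with columns `sample_id`,
#'   `group`, `meth_rate`, `mir23`, `upa`.
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' dplyr::count(cohort, group)
simulate_cohort <- function(params = default_cohort_params(), noise_scale = 1,
                            seed = NULL) {
  known <- c(mm_groups(), "BCell")
  bad <- setdiff(params$group, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown group label(s): %s.", paste(bad, collapse = ", ")))
  }
  stopifnot(all(params$n >= 3), all(params$meth_sd > 0), noise_scale >= 0)
  with_seed(seed, {
    rows <- purrr::pmap(params, function(group, n, meth_mean, meth_sd,
                                         mir23_slope, mir23_intercept,
                                         mir23_noise_sd, upa_slope,
                                         upa_intercept, upa_noise_sd, ...) {
      meth <- rnorm_trunc01(n, meth_mean, meth_sd)
      tibble(
        group = group,
        meth_rate = meth,
        mir23 = mir23_slope * meth + mir23_intercept +
          rnorm(n, 0, mir23_noise_sd * noise_scale),
        upa = upa_slope * meth + upa_intercept +
          rnorm(n, 0, upa_noise_sd * noise_scale)
      )
    })
    out <- bind_rows(rows) |>
      mutate(sample_id = sprintf("S%03d", dplyr::row_number()), .before = 1)
    class(out) <- c("cohort_table", class(out))
    out
  })
}

#' Read/write cohort tables as TSV
#'
#' Columns: `sample_id`, `group`, `meth_rate`, `mir23`, `upa`.
#'
#' @param cohort A `cohort_table` tibble.
#' @param path File path.
#' @return `path` (write) or a `cohort_table` (read).
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(as_tibble(cohort), path)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = "c", group = "c", meth_rate = "d",
                           mir23 = "d", upa = "d"))
  if (anyDuplicated(out$sample_id)) abort("Duplicate sample_id in cohort table.")
  class(out) <- c("cohort_table", class(out))
  out
}
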