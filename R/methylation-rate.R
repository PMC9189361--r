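#' Per-site methylation call summary
#'
#' Tabulates, for every CpG site, the number of methylated (`M`),
#' unmethylated (`U`) and uninformative (`N`) read calls and the site rate
#' `n_M / (n_M + n_U)`; `N` calls never enter the rate.
#'
#' @param calls A `methylation_calls` tibble from [call_reads()] (or any
#'   tibble with `site` and `call` columns).
#' @return A tibble with columns `site`, `n_M`, `n_U`, `n_N`, `site_rate`.
#' @export
site_summary <- function(calls) {
  stopifnot(all(c("site", "call") %in% names(calls)))
  as_tibble(calls) |>
    group_by(site) |>
    summarise(
      n_M = sum(.data$call == "M"),
      n_U = sum(.data$call == "U"),
      n_N = sum(.data$call == "N"),
      .groups = "drop"
    ) |>
    mutate(site_rate = ifelse(.data$n_M + .data$n_U > 0,
                              .data$n_M / (.data$n_M + .data$n_U), NA_real_)) |>
    arrange(.data$site)
}

#' Region methylation rate
#'
#' The methylation rate of a region is the number of methylated CpG calls
#' divided by the total number of informative CpG calls. Two conventions are
#' provided: `"pooled"` (default) pools all read-level calls across sites, so
#' deeper sites carry more weight and the rate is well defined at uneven
#' coverage; `"per_site"` averages the per-site rates. The two agree when all
#' sites share the same informative depth.
#'
#' @param calls A `methylation_calls` tibble from [call_reads()].
#' @param mode `"pooled"` or `"per_site"`.
#' @return A single rate in `[0, 1]`.
#' @export
#' @examples
#' calls <- tibble::tibble(read_id = "r", site = c(0L, 0L, 2L, 2L),
#'                         call = c("M", "M", "U", "U"))
#' methylation_rate(calls)  # 0.5
methylation_rate <- function(calls, mode = c("pooled", "per_site")) {
  mode <- match.arg(mode)
  s <- site_summary(calls)
  informative <- sum(s$n_M + s$n_U)
  if (informative == 0) {
    abort("All calls are uninformative (N); the methylation rate is undefined.")
  }
  if (mode == "pooled") {
    sum(s$n_M) / informative
  } else {
    mean(s$site_rate, na.rm = TRUE)
  }
}

#' Summarise methylation rates across samples
#'
#' Multi-specimen results are conventionally reported as mean +/- SD of the
#' per-specimen region rates.
#'
#' @param rates Numeric vector of per-sample region rates.
#' @return A tibble with `mean`, `sd` and `n`.
#' @export
summarise_rates <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) >= 1)
  tibble(mean = mean(rates), sd = sd(rates), n = length(rates))
}

#' Write the per-site methylation table
#'
#' Emits `site_offset`, `genomic_pos` (1-based, using the region span),
#' `n_M`, `n_U`, `n_N`, `site_rate` as TSV.
#'
#' @param calls A `methylation_calls` tibble carrying its region attribute.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(calls, path) {
  region <- attr(calls, "region")
  s <- site_summary(calls) |>
    mutate(genomic_pos = if (!is.null(region)) region$span$start + .data$site
           else NA_integer_) |>
    select(site_offset = "site", "genomic_pos", "n_M", "n_U", "n_N", "site_rate")
  readr::write_tsv(s, path)
  invisible(path)
}
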