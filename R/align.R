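#' Bisulfite-aware converted reference
#'
#' Fully converts the plus-strand reference for alignment: non-CpG cytosines
#' become thymine, while CpG cytosines are kept as `C` but flagged as
#' ambiguous (`C` or `T` both count as a match), so reads from methylated and
#' unmethylated templates align equally well.
#'
#' @param region A [promoter_region].
#' @return List with `sequence` (converted reference) and `wildcard` (logical
#'   per-base flag, `TRUE` at CpG cytosines).
#' @export
converted_reference <- function(region) {
  stopifnot(inherits(region, "promoter_region"))
  chars <- strsplit(region$sequence, "", fixed = TRUE)[[1]]
  wildcard <- rep(FALSE, length(chars))
  wildcard[region$cpg_sites + 1L] <- TRUE
  chars[chars == "C" & !wildcard] <- "T"
  list(sequence = paste(chars, collapse = ""), wildcard = wildcard)
}

#' Align a read to a promoter region
#'
#' Global Needleman-Wunsch alignment of a bisulfite read against the fully
#' converted reference (see [converted_reference()]), with linear gap
#' penalties and a deterministic traceback tie-break (diagonal, then
#' reference-consuming gap, then read-consuming gap). Low-scoring alignments
#' are flagged, never errors.
#'
#' @param read Read sequence (uppercase DNA).
#' @param region A [promoter_region].
#' @param read_id Identifier recorded in the result.
#' @param match,mismatch,gap Scoring parameters (alignment score units).
#' @param min_score_frac Alignments scoring below
#'   `min_score_frac * match * nchar(read)` are flagged.
#'
#' @return An object of class `bs_alignment`: list with `read_id`, `read`,
#'   `score`, `flagged`, and `pairs`, a tibble of aligned columns with
#'   0-based `ref`/`read` offsets (`NA` marks a gap).
#' @export
#' @examples
#' region <- promoter_region("ACGTACGTACGT", name = "toy")
#' align_read(converted_reference(region)$sequence, region)$score
align_read <- function(read, region, read_id = "read", match = 1,
                       mismatch = -1, gap = -2, min_score_frac = 0.5) {
  assert_dna(read, "read")
  conv <- converted_reference(region)
  res <- nw_align_cpp(conv$sequence, read, conv$wildcard, match, mismatch, gap)
  pairs <- tibble(
    ref = ifelse(res$ref < 0, NA_integer_, res$ref),
    read = ifelse(res$read < 0, NA_integer_, res$read)
  )
  structure(list(
    read_id = read_id,
    read = read,
    score = res$score,
    flagged = res$score < min_score_frac * match * nchar(read),
    pairs = pairs
  ), class = "bs_alignment")
}

#' @export
print.bs_alignment <- function(x, ...) {
  cat(sprintf("<bs_alignment> %s: score %.1f over %d columns%s\n", x$read_id,
              x$score, nrow(x$pairs), if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Call methylation states from one aligned read
#'
#' Applies the C/T read-out rule at every CpG site covered by the alignment:
#' a read base `C` means the site was protected (methylated, `M`), `T` means
#' converted (unmethylated, `U`); any other base or a gap is uninformative
#' (`N`). Sites not covered by the read are absent from the result.
#'
#' @param alignment A `bs_alignment` from [align_read()].
#' @param region The [promoter_region] the alignment refers to.
#' @return A tibble with columns `read_id`, `site` (0-based CpG offset) and
#'   `call` (`"M"`, `"U"` or `"N"`).
#' @export
call_read <- function(alignment, region) {
  stopifnot(inherits(alignment, "bs_alignment"),
            inherits(region, "promoter_region"))
  pairs <- alignment$pairs
  hit <- pairs$ref %in% region$cpg_sites & !is.na(pairs$ref)
  sites <- pairs$ref[hit]
  read_chars <- strsplit(alignment$read, "", fixed = TRUE)[[1]]
  base <- ifelse(is.na(pairs$read[hit]), "-", read_chars[pairs$read[hit] + 1L])
  call <- dplyr::case_when(base == "C" ~ "M", base == "T" ~ "U", TRUE ~ "N")
  tibble(read_id = alignment$read_id, site = as.integer(sites), call = call)
}

#' Align and call a full read set
#'
#' Convenience wrapper running [align_read()] and [call_read()] over every
#' read, producing the per-read, per-site call table consumed by
#' [methylation_rate()].
#'
#' @param reads Tibble with `read_id` and `sequence` columns (e.g. from
#'   [simulate_bisulfite_reads()] or [read_fastq()]).
#' @param region A [promoter_region].
#' @inheritParams align_read
#' @return A tibble of class `methylation_calls` with columns `read_id`,
#'   `site`, `call`; the region and the number of reads are attached as
#'   attributes.
#' @export
call_reads <- function(reads, region, match = 1, mismatch = -1, gap = -2) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  calls <- purrr::map2(reads$sequence, reads$read_id, function(s, id) {
    aln <- align_read(s, region, read_id = id, match = match,
                      mismatch = mismatch, gap = gap)
    call_read(aln, region)
  })
  out <- bind_rows(calls)
  attr(out, "region") <- region
  attr(out, "n_reads") <- nrow(reads)
  class(out) <- c("methylation_calls", class(out))
  out
}
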