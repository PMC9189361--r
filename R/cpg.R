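#' CpG island detection criteria
#'
#' Thresholds for the sliding-window CpG island detector. Defaults follow the
#' Gardiner-Garden & Frommer convention implemented by most primer-design
#' tools: islands are at least 200 bp with GC content of at least 50% and an
#' observed/expected CpG ratio of at least 0.6.
#'
#' @param min_length Minimum island length, in bases.
#' @param min_gc Minimum GC fraction in `[0, 1]`.
#' @param min_obs_exp Minimum observed/expected CpG ratio, where
#'   obs/exp = (N_CG * L) / (N_C * N_G) over a segment of length L.
#' @param window Sliding window width, in bases.
#' @param step Window step, in bases.
#'
#' @return An object of class `island_criteria`.
#' @export
#' @examples
#' island_criteria()
island_criteria <- function(min_length = 200, min_gc = 0.50,
                            min_obs_exp = 0.60, window = 200, step = 1) {
  stopifnot(window >= 1, step >= 1, min_length >= window,
            min_gc >= 0, min_gc <= 1, min_obs_exp >= 0)
  structure(list(min_length = as.integer(min_length), min_gc = min_gc,
                 min_obs_exp = min_obs_exp, window = as.integer(window),
                 step = as.integer(step)),
            class = "island_criteria")
}

#' Locate CpG sites in a DNA sequence
#'
#' A CpG site is the 0-based offset of a cytosine immediately followed by a
#' guanine on the same strand; these are the positions interrogated by
#' bisulfite sequencing.
#'
#' @param sequence A single uppercase DNA string over `A`, `C`, `G`, `T`.
#'
#' @return Sorted integer vector of 0-based offsets of the `C` of each `CG`
#'   dinucleotide (possibly empty).
#' @export
#' @examples
#' find_cpg_sites("ACGTCG")  # 1, 4
find_cpg_sites <- function(sequence) {
  assert_dna(sequence)
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) - 1L
}

# Per-base indicator vectors used by the window scan.
cpg_indicators <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_c <- chars == "C"
  is_g <- chars == "G"
  n <- length(chars)
  is_cg <- c(is_c[-n] & is_g[-1], FALSE)  # CG starting at each position
  list(c = is_c, g = is_g, cg = is_cg, n = n)
}

# Criteria evaluation for the 0-based half-open interval [start, end).
segment_stats <- function(ind, start, end) {
  i <- (start + 1L):end
  n_c <- sum(ind$c[i])
  n_g <- sum(ind$g[i])
  # CG dinucleotides fully inside the interval
  j <- if (end - start >= 2L) (start + 1L):(end - 1L) else integer(0)
  n_cg <- sum(ind$cg[j])
  len <- end - start
  gc <- (n_c + n_g) / len
  obs_exp <- if (n_c > 0 && n_g > 0) (n_cg * len) / (n_c * n_g) else 0
  list(gc = gc, obs_exp = obs_exp, n_cpg = n_cg, length = len)
}

segment_ok <- function(ind, start, end, criteria) {
  s <- segment_stats(ind, start, end)
  s$length >= criteria$min_length && s$gc >= criteria$min_gc &&
    s$obs_exp >= criteria$min_obs_exp
}

#' Detect CpG islands by sliding-window scan
#'
#' Scans the sequence with a fixed-width window, marks windows meeting the GC
#' and observed/expected CpG thresholds, merges overlapping qualifying
#' windows, and trims merged intervals from the ends until the whole interval
#' meets the criteria. Intervals shorter than `min_length` after trimming are
#' dropped.
#'
#' @inheritParams find_cpg_sites
#' @param criteria An [island_criteria()] object.
#'
#' @return A tibble with one row per island: 0-based half-open `start`/`end`,
#'   `length`, `gc`, `obs_exp` and `n_cpg` (CpG sites fully inside).
#' @export
#' @examples
#' find_cpg_islands(strrep("CG", 150))
find_cpg_islands <- function(sequence, criteria = island_criteria()) {
  assert_dna(sequence)
  ind <- cpg_indicators(sequence)
  n <- ind$n
  w <- criteria$window
  if (n < w) abort("Sequence is shorter than the scan window.")

  cum_c <- cumsum(ind$c)
  cum_g <- cumsum(ind$g)
  cum_cg <- cumsum(ind$cg)
  starts <- seq.int(0L, n - w, by = criteria$step)  # 0-based window starts
  at <- function(cum, i) ifelse(i >= 1L, cum[pmin(i, n)], 0)
  n_c <- at(cum_c, starts + w) - at(cum_c, starts)
  n_g <- at(cum_g, starts + w) - at(cum_g, starts)
  n_cg <- at(cum_cg, starts + w - 1L) - at(cum_cg, starts)
  gc <- (n_c + n_g) / w
  obs_exp <- ifelse(n_c > 0 & n_g > 0, n_cg * w / (n_c * n_g), 0)
  ok <- gc >= criteria$min_gc & obs_exp >= criteria$min_obs_exp

  empty <- tibble(start = integer(0), end = integer(0), length = integer(0),
                  gc = double(0), obs_exp = double(0), n_cpg = integer(0))
  if (!any(ok)) return(empty)

  # Merge qualifying windows into maximal runs.
  ok_starts <- starts[ok]
  gaps <- which(diff(ok_starts) > w)  # disjoint if next window starts past end
  run_first <- ok_starts[c(1L, gaps + 1L)]
  run_last <- ok_starts[c(gaps, length(ok_starts))]
  intervals <- Map(function(s, e) c(s, e + w), run_first, run_last)

  out <- purrr::map(intervals, function(iv) {
    s <- iv[1]; e <- iv[2]
    # Trim the weaker end one base at a time until the interval qualifies.
    while (e - s > criteria$min_length && !segment_ok(ind, s, e, criteria)) {
      probe <- min(10L, e - s - criteria$min_length)
      head_gc <- segment_stats(ind, s, s + probe)$gc
      tail_gc <- segment_stats(ind, e - probe, e)$gc
      if (head_gc < tail_gc) s <- s + 1L else e <- e - 1L
    }
    if (!segment_ok(ind, s, e, criteria)) return(NULL)
    st <- segment_stats(ind, s, e)
    tibble(start = as.integer(s), end = as.integer(e),
           length = as.integer(st$length), gc = st$gc, obs_exp = st$obs_exp,
           n_cpg = as.integer(st$n_cpg))
  })
  out <- purrr::compact(out)
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Write CpG islands to a BED file
#'
#' Coordinates are written 0-based half-open per the BED convention, offset by
#' the genomic start of the region when `region` is supplied.
#'
#' @param islands Tibble as returned by [find_cpg_islands()].
#' @param path Output file path.
#' @param region Optional [promoter_region] used to name records and offset
#'   coordinates to genomic space.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path, region = NULL) {
  offset <- 0L
  chrom <- "region"
  if (!is.null(region)) {
    offset <- region$span$start - 1L  # genomic start is 1-based inclusive
    chrom <- region$span$chrom
  }
  bed <- tibble(
    chrom = chrom,
    start = islands$start + offset,
    end = islands$end + offset,
    name = sprintf("island_%d", seq_len(nrow(islands)))
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
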