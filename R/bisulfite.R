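#' In-silico bisulfite conversion
#'
#' Applies the bisulfite rule to the plus strand: every cytosine is deaminated
#' to thymine unless it is a methylated CpG cytosine listed in
#' `methylated_positions`. Other bases are untouched and length is preserved.
#'
#' @param sequence Uppercase DNA string.
#' @param methylated_positions 0-based offsets of methylated CpG cytosines;
#'   must be a subset of [find_cpg_sites()] of `sequence`.
#'
#' @return The converted sequence.
#' @export
#' @examples
#' bisulfite_convert("ACGTCCG", methylated_positions = 1)  # "ACGTTTG"
bisulfite_convert <- function(sequence, methylated_positions = integer(0)) {
  assert_dna(sequence)
  sites <- find_cpg_sites(sequence)
  methylated_positions <- as.integer(methylated_positions)
  bad <- setdiff(methylated_positions, sites)
  if (length(bad) > 0) {
    abort(sprintf("Position(s) %s are not CpG cytosines.",
                  paste(bad, collapse = ", ")))
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  convert <- chars == "C"
  convert[methylated_positions + 1L] <- FALSE
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Per-site methylation profile
#'
#' Pairs CpG site offsets with per-site methylation probabilities; the
#' template drawn for each simulated read methylates site `i` independently
#' with probability `probabilities[i]`.
#'
#' @param positions 0-based CpG cytosine offsets (sorted, unique).
#' @param probabilities Per-site methylation probabilities in `[0, 1]`;
#'   recycled if length 1.
#' @return A tibble with columns `position` and `probability`, of class
#'   `methylation_profile`.
#' @export
#' @examples
#' methylation_profile(c(10, 42), 0.7)
methylation_profile <- function(positions, probabilities) {
  positions <- as.integer(positions)
  stopifnot(!is.unsorted(positions, strictly = TRUE))
  if (length(probabilities) == 1) {
    probabilities <- rep(probabilities, length(positions))
  }
  stopifnot(length(probabilities) == length(positions))
  purrr::walk(probabilities, assert_scalar_prob, name = "probabilities")
  structure(tibble(position = positions, probability = as.double(probabilities)),
            class = c("methylation_profile", "tbl_df", "tbl", "data.frame"))
}

#' Simulate amplicon bisulfite-sequencing reads
#'
#' Emulates single-end amplicon reads from the plus strand of a
#' bisulfite-converted template. For each read a template molecule is drawn:
#' each CpG site in `profile` is methylated independently with its site
#' probability; unmethylated cytosines (CpG or not) convert to thymine with
#' probability `conversion_rate`; substitution sequencing errors are then
#' applied uniformly at `seq_error_rate` per base. Reads of `read_length`
#' bases start uniformly over valid offsets; `read_length = NULL` (default)
#' makes every read span the whole amplicon so `depth` is the per-site
#' coverage.
#'
#' @param region A [promoter_region] (the amplicon).
#' @param profile A [methylation_profile()] whose positions are a subset of
#'   the region's CpG sites.
#' @param depth Number of reads.
#' @param read_length Read length in bases, or `NULL` for amplicon-spanning
#'   reads.
#' @param seq_error_rate Per-base substitution error probability.
#' @param conversion_rate Probability that an unmethylated cytosine is
#'   converted (1 = complete conversion).
#' @param seed Integer seed.
#'
#' @return A tibble of class `bisulfite_reads` with columns `read_id`,
#'   `start` (0-based offset on the region), `sequence` and `quality`
#'   (Phred+33). The source region is attached as attribute `region`.
#' @export
#' @examples
#' region <- generate_promoter(seed = 1)
#' amp <- subregion(region, region$islands$start[1], 200)
#' prof <- methylation_profile(amp$cpg_sites, 0.7)
#' reads <- simulate_bisulfite_reads(amp, prof, depth = 50, seed = 2)
simulate_bisulfite_reads <- function(region, profile, depth = 200,
                                     read_length = NULL, seq_error_rate = 0,
                                     conversion_rate = 1, seed = NULL) {
  stopifnot(inherits(region, "promoter_region"))
  if (!all(profile$position %in% region$cpg_sites)) {
    abort("Profile positions must be a subset of the region's CpG sites.")
  }
  if (depth < 1) abort("`depth` must be at least 1.")
  assert_scalar_prob(seq_error_rate, "seq_error_rate")
  assert_scalar_prob(conversion_rate, "conversion_rate")
  L <- length(region)
  read_length <- if (is.null(read_length)) L else as.integer(read_length)
  if (read_length < 1 || read_length > L) {
    abort("`read_length` must be between 1 and the region length.")
  }

  ref_chars <- strsplit(region$sequence, "", fixed = TRUE)[[1]]
  is_c <- ref_chars == "C"
  sites1 <- profile$position + 1L  # 1-based index of CpG cytosines
  qual_char <- if (seq_error_rate > 0) {
    rawToChar(as.raw(33L + min(41L, max(2L, round(-10 * log10(seq_error_rate))))))
  } else "I"  # constant Q40 when no error model is active

  with_seed(seed, {
    starts <- if (read_length == L) rep(0L, depth)
              else sample.int(L - read_length + 1L, depth, replace = TRUE) - 1L
    seqs <- character(depth)
    for (r in seq_len(depth)) {
      tmpl <- ref_chars
      meth <- sites1[runif(length(sites1)) < profile$probability]
      conv <- is_c
      conv[meth] <- FALSE
      if (conversion_rate < 1) {
        conv[conv] <- runif(sum(conv)) < conversion_rate
      }
      tmpl[conv] <- "T"
      idx <- (starts[r] + 1L):(starts[r] + read_length)
      read <- tmpl[idx]
      if (seq_error_rate > 0) {
        hit <- which(runif(read_length) < seq_error_rate)
        for (h in hit) {
          read[h] <- sample(setdiff(c("A", "C", "G", "T"), read[h]), 1)
        }
      }
      seqs[r] <- paste(read, collapse = "")
    }
    out <- tibble(
      read_id = sprintf("read_%05d", seq_len(depth)),
      start = starts,
      sequence = seqs,
      quality = strrep(qual_char, read_length)
    )
    attr(out, "region") <- region
    class(out) <- c("bisulfite_reads", class(out))
    out
  })
}

#' Read/write bisulfite reads as FASTQ (Phred+33)
#'
#' @param reads A `bisulfite_reads` tibble (or any tibble with `read_id`,
#'   `sequence`, `quality`).
#' @param path File path.
#' @return `path` (write) or a tibble with `read_id`, `sequence`, `quality`
#'   (read).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # suppress the harmless note about dropped metadata columns
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(read_id = names(x), sequence = unname(as.character(x)),
         quality = unname(as.character(Biostrings::quality(x))))
}
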