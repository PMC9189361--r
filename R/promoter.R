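#' Promoter region objects
#'
#' A `promoter_region` bundles a named DNA sequence with its genomic span,
#' strand, CpG site offsets and detected CpG islands. The default span mirrors
#' a 2-kb upstream promoter on the plus strand of hg38 chr9; all offsets are
#' 0-based internally, with 1-based inclusive coordinates only at the genomic
#' boundary.
#'
#' @param sequence Uppercase DNA string.
#' @param name Region name.
#' @param assembly,chrom,start,strand Genomic span of base 1 of `sequence`
#'   (`start` is 1-based inclusive; the end is implied by the length).
#' @param criteria [island_criteria()] used to annotate islands.
#' @param meta Optional named list of free-form metadata carried verbatim.
#'
#' @return An object of class `promoter_region` with fields `name`,
#'   `sequence`, `span` (`assembly`, `chrom`, `start`, `end`), `strand`,
#'   `cpg_sites` (0-based), `islands` (tibble) and `meta`.
#' @export
#' @examples
#' promoter_region(strrep("ACGT", 100), name = "toy")
promoter_region <- function(sequence, name = "promoter",
                            assembly = "hg38", chrom = "chr9",
                            start = 95083208L, strand = "+",
                            criteria = island_criteria(), meta = list()) {
  assert_dna(sequence)
  stopifnot(strand %in% c("+", "-"))
  n <- nchar(sequence)
  islands <- if (n >= criteria$window) find_cpg_islands(sequence, criteria)
             else find_cpg_islands(sequence, island_criteria(
               min_length = n, window = n))
  structure(list(
    name = name,
    sequence = sequence,
    span = list(assembly = assembly, chrom = chrom,
                start = as.integer(start), end = as.integer(start) + n - 1L),
    strand = strand,
    cpg_sites = find_cpg_sites(sequence),
    islands = islands,
    meta = meta
  ), class = "promoter_region")
}

#' @export
print.promoter_region <- function(x, ...) {
  cat(sprintf("<promoter_region> %s\n", x$name))
  cat(sprintf("  %s %s:%s-%s (%s strand), %d bp\n", x$span$assembly,
              x$span$chrom, format(x$span$start, big.mark = ","),
              format(x$span$end, big.mark = ","), x$strand,
              nchar(x$sequence)))
  cat(sprintf("  %d CpG sites, %d CpG islands\n",
              length(x$cpg_sites), nrow(x$islands)))
  invisible(x)
}

#' @export
length.promoter_region <- function(x) nchar(x$sequence)

# --- synthetic promoter construction ---------------------------------------

# Background letters with controlled GC and no CG dinucleotides: a G is never
# emitted directly after a C, so the background observed/expected CpG ratio is
# exactly zero and cannot seed an island call.
sample_background <- function(n, gc) {
  if (n == 0) return(character(0))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(n)
  prev_c <- FALSE
  letters4 <- names(p)
  for (i in seq_len(n)) {
    if (prev_c) {
      q <- p[c("A", "C", "T")] / sum(p[c("A", "C", "T")])
      out[i] <- sample(names(q), 1, prob = q)
    } else {
      out[i] <- sample(letters4, 1, prob = p)
    }
    prev_c <- out[i] == "C"
  }
  out
}

# Emission probability of a "CG" dinucleotide that achieves the requested
# observed/expected ratio at the requested GC fraction. Single bases fill the
# remainder with P(C) = P(G) = g_emit / 2.
solve_island_q <- function(island_gc, obs_exp) {
  g_emit <- function(q) ((1 + q) * island_gc - 2 * q) / (1 - q)
  f <- function(q) {
    g <- g_emit(q)
    if (g < 0 || g > 1) return(NA_real_)
    pc <- (q + (1 - q) * g / 2) / (1 + q)      # per-base C (and G) fraction
    pcg <- q / (1 + q)                         # per-base CG start fraction
    pcg / (pc * pc) - obs_exp
  }
  q_max <- island_gc / (2 - island_gc) - 1e-6  # keeps g_emit >= 0
  lo <- 1e-4
  if (is.na(f(lo)) || is.na(f(q_max))) abort("Island parameters are infeasible.")
  if (f(q_max) < 0) {
    abort(sprintf(
      "Requested island obs/exp CpG ratio %.2f is unreachable at GC %.2f.",
      obs_exp, island_gc))
  }
  if (f(lo) >= 0) return(lo)
  stats::uniroot(f, c(lo, q_max))$root
}

sample_island <- function(len, island_gc, obs_exp, criteria, max_attempts = 10000) {
  q <- solve_island_q(island_gc, obs_exp)
  g <- ((1 + q) * island_gc - 2 * q) / (1 - q)
  single <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  for (attempt in seq_len(max_attempts)) {
    pieces <- character(0)
    total <- 0L
    while (total < len) {
      if (runif(1) < q) piece <- "CG"
      else piece <- sample(names(single), 1, prob = single)
      pieces <- c(pieces, piece)
      total <- total + nchar(piece)
    }
    seg <- substr(paste(pieces, collapse = ""), 1, len)
    ind <- cpg_indicators(seg)
    st <- segment_stats(ind, 0L, len)
    # demand a margin over the detector thresholds so flank trimming is stable
    if (st$gc >= criteria$min_gc + 0.02 &&
        st$obs_exp >= criteria$min_obs_exp + 0.10 && st$n_cpg >= 2) {
      return(seg)
    }
  }
  abort("Could not sample an island segment meeting the criteria; relax the parameters.")
}

#' Generate a synthetic CpG-island-bearing promoter
#'
#' Builds a promoter-like sequence of known ground truth: `n_islands`
#' non-overlapping GC- and CpG-rich segments embedded in a background in which
#' the CG dinucleotide never occurs, so the island detector's answer is fixed
#' by construction. The generated sequence is verified with
#' [find_cpg_islands()] before it is returned.
#'
#' @param length Total sequence length in bases (default 2000, matching a
#'   -2000..-1 upstream promoter window).
#' @param n_islands Number of CpG islands to embed (default 3).
#' @param island_length Length of each island segment, in bases.
#' @param background_gc GC fraction of the CpG-free background.
#' @param island_gc GC fraction of island segments (must exceed the detector's
#'   `min_gc`).
#' @param island_obs_exp_cpg Target observed/expected CpG ratio of island
#'   segments.
#' @param criteria [island_criteria()] the result must satisfy.
#' @param seed Integer seed; the same seed always yields the same region.
#' @param name Region name.
#'
#' @return A [promoter_region] whose annotated `islands` has exactly
#'   `n_islands` rows, each containing at least two CpG sites.
#' @export
#' @examples
#' region <- generate_promoter(seed = 1)
#' nrow(region$islands)
generate_promoter <- function(length = 2000, n_islands = 3,
                              island_length = 300, background_gc = 0.40,
                              island_gc = 0.60, island_obs_exp_cpg = 1.2,
                              criteria = island_criteria(), seed = NULL,
                              name = "synthetic_promoter") {
  stopifnot(n_islands >= 0, length >= 1)
  if (n_islands > 0) {
    if (island_gc < criteria$min_gc) {
      abort("`island_gc` is below the detector's `min_gc`; islands would be undetectable.")
    }
    if (island_obs_exp_cpg < criteria$min_obs_exp) {
      abort("`island_obs_exp_cpg` is below the detector's `min_obs_exp`.")
    }
    gap_min <- criteria$window + 20L
    needed <- n_islands * island_length + (n_islands + 1L) * gap_min
    if (length < needed) {
      abort(sprintf(
        "`length` = %d cannot hold %d islands of %d bp with %d bp separation (need >= %d).",
        length, n_islands, island_length, gap_min, needed))
    }
  }

  with_seed(seed, {
    for (attempt in 1:50) {
      if (n_islands == 0) {
        seq_str <- paste(sample_background(length, background_gc), collapse = "")
      } else {
        slack <- length - n_islands * island_length - (n_islands + 1L) * gap_min
        share <- runif(n_islands + 1L)
        extra <- floor(slack * share / sum(share))
        extra[1] <- extra[1] + (slack - sum(extra))
        gaps <- gap_min + extra
        pieces <- character(2 * n_islands + 1L)
        pieces[1] <- paste(sample_background(gaps[1], background_gc), collapse = "")
        for (k in seq_len(n_islands)) {
          pieces[2 * k] <- sample_island(island_length, island_gc,
                                         island_obs_exp_cpg, criteria)
          pieces[2 * k + 1L] <- paste(
            sample_background(gaps[k + 1L], background_gc), collapse = "")
        }
        seq_str <- paste(pieces, collapse = "")
      }
      region <- promoter_region(seq_str, name = name, criteria = criteria)
      found <- nrow(region$islands)
      ok <- found == n_islands &&
        (n_islands == 0 || all(region$islands$n_cpg >= 2))
      if (ok) return(region)
    }
    abort("Failed to generate a promoter matching the requested island count.")
  })
}

#' Extract a subregion of a promoter
#'
#' Useful for carving a BSP amplicon out of a longer promoter: CpG sites and
#' islands are re-derived on the extracted sequence and the genomic span is
#' shifted accordingly.
#'
#' @param region A [promoter_region].
#' @param start 0-based start offset of the subregion.
#' @param width Width in bases.
#' @return A [promoter_region] covering `[start, start + width)`.
#' @export
subregion <- function(region, start, width) {
  stopifnot(inherits(region, "promoter_region"),
            start >= 0, width >= 1, start + width <= length(region))
  seq_str <- substr(region$sequence, start + 1L, start + width)
  crit <- island_criteria(
    min_length = min(200L, width), window = min(200L, width))
  promoter_region(seq_str, name = sprintf("%s[%d,%d)", region$name, start,
                                          start + width),
                  assembly = region$span$assembly, chrom = region$span$chrom,
                  start = region$span$start + as.integer(start),
                  strand = region$strand, criteria = crit, meta = region$meta)
}

#' Carve an amplicon centered on a CpG island
#'
#' Detected islands can extend into their flanks (windows straddling the
#' island boundary still qualify), so an amplicon anchored at the island
#' *start* may be CpG-poor. This helper centers the amplicon on the island
#' midpoint instead, which is where BSP primers are designed to point.
#'
#' @param region A [promoter_region] with at least `island` islands.
#' @param island Island index (1-based, in sequence order).
#' @param width Amplicon width in bases.
#' @return A [promoter_region] of length `width` containing CpG sites.
#' @export
#' @examples
#' region <- generate_promoter(seed = 1)
#' length(amplicon_around_island(region)$cpg_sites) > 0
amplicon_around_island <- function(region, island = 1, width = 240) {
  stopifnot(inherits(region, "promoter_region"))
  if (nrow(region$islands) < island) {
    abort(sprintf("Region has %d island(s); island %d requested.",
                  nrow(region$islands), island))
  }
  width <- min(as.integer(width), length(region))
  mid <- (region$islands$start[island] + region$islands$end[island]) / 2
  start <- max(0L, min(length(region) - width,
                       as.integer(round(mid - width / 2))))
  amp <- subregion(region, start, width)
  if (length(amp$cpg_sites) == 0) {
    abort("Amplicon contains no CpG sites; widen it or pick another island.")
  }
  amp
}

#' Read/write promoter FASTA
#'
#' @param region A [promoter_region].
#' @param path File path.
#' @return `path` (write) or a [promoter_region] (read).
#' @export
write_promoter_fasta <- function(region, path) {
  x <- Biostrings::DNAStringSet(setNames(region$sequence, region$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_promoter_fasta
#' @param ... Passed to [promoter_region()] (span, strand, criteria).
#' @export
read_promoter_fasta <- function(path, ...) {
  x <- Biostrings::readDNAStringSet(path)
  promoter_region(as.character(x[[1]]), name = names(x)[1], ...)
}
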