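test_that("aligning the converted reference to itself is gap-free and maximal", {
  region <- generate_promoter(seed = 7)
  amp <- subregion(region, 50, 60)
  conv <- converted_reference(amp)
  aln <- align_read(conv$sequence, amp)
  expect_equal(aln$score, nchar(conv$sequence))
  expect_false(any(is.na(aln$pairs$ref)))
  expect_false(any(is.na(aln$pairs$read)))
  expect_identical(aln$pairs$ref, aln$pairs$read)
  expect_false(aln$flagged)
})

test_that("a single substitution costs match minus mismatch", {
  region <- generate_promoter(seed = 7)
  amp <- subregion(region, 50, 60)
  conv <- converted_reference(amp)
  # substitute at a non-CpG position with a base different from the reference
  pos <- setdiff(seq_len(60), c(amp$cpg_sites + 1L))[10]
  chars <- strsplit(conv$sequence, "")[[1]]
  chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
  aln <- align_read(paste(chars, collapse = ""), amp)
  expect_equal(aln$score, (60 - 1) * 1 + 1 * (-1))
})

test_that("C and T both match at CpG sites (bisulfite-aware scoring)", {
  region <- promoter_region("AACGTTACGTT", name = "toy")
  conv <- converted_reference(region)
  as_c <- conv$sequence  # converted reference keeps C at CpG sites
  as_t <- conv$sequence
  for (s in region$cpg_sites) {
    substr(as_t, s + 1, s + 1) <- "T"
  }
  expect_equal(align_read(as_c, region)$score, nchar(as_c))
  expect_equal(align_read(as_t, region)$score, nchar(as_t))
})

test_that("a contained read aligns at the position an exhaustive search finds", {
  for (seed in 1:5) {
    region <- generate_promoter(length = 800, n_islands = 1,
                                island_length = 250, seed = seed)
    amp <- subregion(region, 10, 60)
    conv <- converted_reference(amp)
    read <- substr(conv$sequence, 16, 45)  # 30 bp starting at offset 15
    # exhaustive substring search on the converted reference
    hits <- which(vapply(1:31, function(i)
      substr(conv$sequence, i, i + 29) == read, logical(1)))
    expect_true(16 %in% hits)  # the 1-based position the read was cut from
    aln <- align_read(read, amp)
    aligned <- aln$pairs[!is.na(aln$pairs$ref) & !is.na(aln$pairs$read), ]
    expect_equal(min(aligned$ref), hits[1] - 1L)
    expect_equal(nrow(aligned), 30L)
  }
})

test_that("alignment scores agree with a quadratic-time R oracle", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(10:50, 1)
    m <- sample(5:50, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    read <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE), collapse = "")
    region <- promoter_region(ref, name = "rnd")
    conv <- converted_reference(region)
    aln <- align_read(read, region)
    expect_equal(aln$score,
                 nw_score_oracle(conv$sequence, read, conv$wildcard))
  }
})

test_that("per-site calls follow the C/T/other rule", {
  # reference with exactly 3 CpG sites
  region <- promoter_region("AACGTACGTACGTT", name = "toy3")
  sites <- region$cpg_sites
  expect_length(sites, 3)
  conv <- converted_reference(region)$sequence

  put <- function(base_by_site) {
    s <- conv
    for (i in seq_along(sites)) {
      substr(s, sites[i] + 1, sites[i] + 1) <- base_by_site[i]
    }
    s
  }
  all_c <- call_read(align_read(put(c("C", "C", "C")), region), region)
  expect_identical(all_c$call, c("M", "M", "M"))

  cct <- call_read(align_read(put(c("C", "C", "T")), region), region)
  expect_identical(cct$call, c("M", "M", "U"))
  expect_equal(mean(cct$call == "M"), 2 / 3)

  with_g <- call_read(align_read(put(c("C", "G", "T")), region), region)
  expect_identical(with_g$call, c("M", "N", "U"))
})

test_that("call table conserves covering reads per site", {
  region <- generate_promoter(seed = 13)
  amp <- amplicon_around_island(region, width = 120)
  reads <- simulate_bisulfite_reads(amp,
                                    methylation_profile(amp$cpg_sites, 0.5),
                                    depth = 30, seed = 3)
  calls <- call_reads(reads, amp)
  s <- site_summary(calls)
  expect_true(all(s$n_M + s$n_U + s$n_N == 30))
  expect_setequal(s$site, amp$cpg_sites)
})
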