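test_that("bisulfite conversion applies the C/T rule exactly", {
  expect_identical(bisulfite_convert("ACGTCCG", 1), "ACGTTTG")
  expect_identical(bisulfite_convert("GGGG"), "GGGG")

  seq <- "TACGACGGCA"
  sites <- find_cpg_sites(seq)
  all_meth <- bisulfite_convert(seq, sites)
  # CpG cytosines kept, every other C converted
  chars <- strsplit(all_meth, "")[[1]]
  orig <- strsplit(seq, "")[[1]]
  expect_true(all(chars[sites + 1] == "C"))
  non_cpg_c <- setdiff(which(orig == "C") - 1L, sites)
  expect_true(all(chars[non_cpg_c + 1] == "T"))
  expect_equal(nchar(all_meth), nchar(seq))

  expect_error(bisulfite_convert("ACGT", 0), "not CpG")
})

test_that("forced profiles produce all-C or all-T reads at CpG sites", {
  region <- generate_promoter(seed = 3)
  amp <- amplicon_around_island(region, width = 150)
  sites <- amp$cpg_sites

  full <- simulate_bisulfite_reads(amp, methylation_profile(sites, 1),
                                   depth = 20, seed = 1)
  none <- simulate_bisulfite_reads(amp, methylation_profile(sites, 0),
                                   depth = 20, seed = 1)
  for (r in seq_len(5)) {
    f <- strsplit(full$sequence[r], "")[[1]]
    u <- strsplit(none$sequence[r], "")[[1]]
    expect_true(all(f[sites + 1] == "C"))
    expect_true(all(u[sites + 1] == "T"))
  }
  # with conversion 1 and no methylation, no read contains any C at all
  expect_false(any(grepl("C", none$sequence, fixed = TRUE)))
})

test_that("read sets conserve depth and read length", {
  region <- generate_promoter(seed = 3)
  amp <- subregion(region, 0, 400)
  prof <- methylation_profile(amp$cpg_sites, 0.5)
  reads <- simulate_bisulfite_reads(amp, prof, depth = 37, read_length = 120,
                                    seed = 2)
  expect_equal(nrow(reads), 37L)
  expect_true(all(nchar(reads$sequence) == 120L))
  expect_true(all(nchar(reads$quality) == 120L))
  expect_true(all(reads$start >= 0 & reads$start + 120 <= 400))

  expect_error(simulate_bisulfite_reads(amp, prof, depth = 0), "depth")
  bad <- methylation_profile(c(1L), 0.5)
  expect_error(simulate_bisulfite_reads(amp, bad, depth = 5), "subset")
})

test_that("pooled per-site C fraction converges to the site probability", {
  region <- generate_promoter(seed = 6)
  amp <- amplicon_around_island(region, width = 200)
  sites <- amp$cpg_sites
  depth <- 200
  reads <- simulate_bisulfite_reads(amp, methylation_profile(sites, 0.7),
                                    depth = depth, seed = 8)
  mat <- do.call(rbind, strsplit(reads$sequence, ""))
  frac_c <- colMeans(mat[, sites + 1, drop = FALSE] == "C")
  expect_true(all(abs(frac_c - 0.7) < 4 / sqrt(depth)))
  expect_lt(abs(mean(frac_c) - 0.7), 0.05)
})

test_that("incomplete conversion leaves residual C at non-CpG cytosines", {
  region <- generate_promoter(seed = 6)
  amp <- subregion(region, 0, 300)
  non_cpg_c <- setdiff(which(strsplit(amp$sequence, "")[[1]] == "C") - 1L,
                       amp$cpg_sites)
  reads <- simulate_bisulfite_reads(
    amp, methylation_profile(amp$cpg_sites, 0), depth = 150,
    conversion_rate = 0.8, seed = 5)
  mat <- do.call(rbind, strsplit(reads$sequence, ""))
  resid <- mean(mat[, non_cpg_c + 1] == "C")
  expect_lt(abs(resid - 0.2), 4 / sqrt(150 * length(non_cpg_c)) + 0.02)
})

test_that("FASTQ round-trips with Phred+33 qualities", {
  region <- generate_promoter(seed = 3)
  amp <- subregion(region, 100, 80)
  reads <- simulate_bisulfite_reads(amp, methylation_profile(amp$cpg_sites, 0.5),
                                    depth = 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$sequence, reads$sequence)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$quality, reads$quality)
})
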