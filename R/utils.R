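# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
# All generators funnel their randomness through this so that a top-level seed
# fully determines the output.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code,
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection")
}

# Deterministic sub-stream seed for stage `k` of a run seeded with `seed`.
# Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

assert_dna <- function(sequence, name = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    abort(sprintf("`%s` must be a single non-empty string.", name))
  }
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    abort(sprintf("`%s` contains a non-ACGT character '%s' at position %d.",
                  name, substr(sequence, bad, bad), as.integer(bad)))
  }
  invisible(sequence)
}

# Format a fitted line the way clinical tables print it: "Y = -2.315*X + 6.758",
# coefficients at 4 significant digits.
format_equation <- function(slope, intercept, digits = 4) {
  a <- signif(slope, digits)
  b <- signif(intercept, digits)
  sprintf("Y = %s*X %s %s", format(a, scientific = FALSE),
          if (b < 0) "-" else "+", format(abs(b), scientific = FALSE))
}
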