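# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All exported stochastic operations route
# through this so a single top-level seed makes a whole study reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive per-library sub-seeds from one top-level seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# 1-based positions at which two equal-length strings differ.
mismatch_positions <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  which(ra != rb)
}

str_at <- function(x, pos) substring(x, pos, pos)

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Translate a codon with the standard genetic code ("*" = stop).
translate_codon <- function(codon) {
  GENETIC_CODE_1 <- Biostrings::GENETIC_CODE
  aa <- GENETIC_CODE_1[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

aa_three <- function(aa) unname(AA3[aa])

`%||%` <- function(a, b) if (is.null(a)) b else a
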