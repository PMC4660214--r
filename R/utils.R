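# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Uniform random codons excluding stop codons (TAA, TAG, TGA).
random_codons <- function(n) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    cand <- paste0(sample(c("A", "C", "G", "T"), length(need), replace = TRUE),
                   sample(c("A", "C", "G", "T"), length(need), replace = TRUE),
                   sample(c("A", "C", "G", "T"), length(need), replace = TRUE))
    ok <- !(cand %in% stops)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

revcomp_dna <- function(x) {
  as.character(cpp_revcomp(x))
}

translate_dna <- function(x) {
  if (nchar(x) == 0) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
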