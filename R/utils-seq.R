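# Low-level sequence helpers. Sequences are plain upper-case character
# scalars (ACGT); coordinates 0-based half-open.

DNA_ALPHABET4 <- c("A", "C", "G", "T")

# i.i.d. background with a given GC fraction
random_dna <- function(n, gc = 0.4) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_ALPHABET4, n, replace = TRUE, prob = p), collapse = "")
}

random_dna_vec <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_ALPHABET4, n, replace = TRUE, prob = p)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substitution-only mutagenesis; returns the mutated sequence and the
# realized substitution count (mutated bases always change identity)
mutate_dna <- function(x, rate) {
  n <- nchar(x)
  if (rate <= 0 || n == 0) return(list(seq = x, n_sub = 0L))
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(n) < rate)
  for (i in hit) v[i] <- sample(DNA_ALPHABET4[DNA_ALPHABET4 != v[i]], 1L)
  list(seq = paste(v, collapse = ""), n_sub = length(hit))
}

# single-base indels at a given per-base rate (equal insertion/deletion odds)
indel_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit) == 0) return(x)
  out <- vector("list", length(v))
  for (i in seq_along(v)) out[[i]] <- v[i]
  for (i in hit) {
    if (runif(1) < 0.5) out[[i]] <- character(0)           # deletion
    else out[[i]] <- c(v[i], sample(DNA_ALPHABET4, 1L))    # insertion after
  }
  paste(unlist(out), collapse = "")
}

# all k-mers of a single sequence (forward strand)
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}

# mismatch count between equal-length strings
str_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

# fraction of positions matching between x[i] and x[i + p], x a raw vector
shift_match_fraction <- function(x, p) {
  n <- length(x)
  if (p >= n) return(NA_real_)
  mean(x[1:(n - p)] == x[(p + 1):n])
}

# deterministic derived RNG streams (kept < 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + 7919 * (i + 1)) %% 2147483629)
}

# boxcar smoothing with shrinking windows at the edges
boxcar_smooth <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
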