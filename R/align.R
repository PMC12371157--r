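# Alignment utilities. Percent identity is defined as matches / alignment
# columns (gap columns count against identity) under a fixed scoring scheme:
# match 1, mismatch -1, gap open 2, gap extend 0.5.

nt_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

align_nt <- function(a, b, type = "global", gap_open = 2,
                     gap_extend = 0.5) {
  Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type,
    substitutionMatrix = nt_submat(),
    gapOpening = gap_open, gapExtension = gap_extend)
}

# alignedPattern() keeps terminal gap columns, which pattern() drops for
# global alignments; identity must be computed over the full alignment
alignment_columns <- function(aln) {
  nchar(as.character(Biostrings::alignedPattern(aln)))
}

alignment_identity <- function(aln) {
  100 * Biostrings::nmatch(aln) / alignment_columns(aln)
}

# best global percent identity of a vs b, optionally over both strands
pct_identity <- function(a, b, both_strands = FALSE, type = "global") {
  id <- alignment_identity(align_nt(a, b, type))
  if (both_strands) {
    id2 <- alignment_identity(align_nt(a, revcomp(b), type))
    id <- max(id, id2)
  }
  id
}

# per-column comparison of a global alignment: raw divergence plus the
# transition (P) and transversion (Q) fractions over non-gap columns
alignment_divergence <- function(aln) {
  p <- charToRaw(as.character(Biostrings::alignedPattern(aln)))
  s <- charToRaw(as.character(Biostrings::alignedSubject(aln)))
  gap <- charToRaw("-")[1]
  keep <- p != gap & s != gap
  p <- rawToChar(p[keep], multiple = TRUE)
  s <- rawToChar(s[keep], multiple = TRUE)
  n <- length(p)
  mism <- p != s
  purine <- c("A", "G")
  ts <- mism & ((p %in% purine) == (s %in% purine))
  list(sites = n, d = sum(mism) / n, P = sum(ts) / n,
       Q = sum(mism & !ts) / n)
}

# best local alignment of a consensus against a target window (both
# strands); returns NULL when nothing clears the length/identity bar
best_local_hit <- function(consensus, target, min_identity = 80,
                           min_len = 30) {
  best <- NULL
  tl <- nchar(target)
  for (strand in c("+", "-")) {
    qry <- if (strand == "+") consensus else revcomp(consensus)
    aln <- align_nt(qry, target, type = "local")
    cols <- alignment_columns(aln)
    if (cols < min_len) next
    id <- 100 * Biostrings::nmatch(aln) / cols
    if (id < min_identity) next
    s0 <- BiocGenerics::start(Biostrings::subject(aln)) - 1  # 0-based
    e0 <- BiocGenerics::end(Biostrings::subject(aln))
    if (is.null(best) || Biostrings::score(aln) > best$score) {
      best <- list(start = s0, end = e0, identity = id,
                   strand = strand, columns = cols,
                   score = Biostrings::score(aln))
    }
  }
  best
}
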