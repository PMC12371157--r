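# Shared fixtures and independent oracles. Fixtures are generated in code
# under fixed seeds; oracles deliberately avoid the code paths they check.

rnd_dna <- function(n, gc = 0.4) centroscape:::random_dna(n, gc)

# brute-force read assignment oracle: best local-alignment identity against
# each consensus, ties to the lexicographically smaller id, unassigned when
# best identity < min_id
oracle_assign <- function(reads, library, min_id = 75) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  ids <- sort(library$id)
  seqs <- library$sequence[match(ids, library$id)]
  vapply(reads, function(r) {
    best_id <- NA_character_; best <- -Inf
    for (i in seq_along(ids)) {
      for (s in c(r, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r))))) {
        aln <- Biostrings::pairwiseAlignment(
          s, seqs[i], type = "local", substitutionMatrix = sm,
          gapOpening = 2, gapExtension = 0.5)
        cols <- nchar(as.character(Biostrings::pattern(aln)))
        idy <- 100 * Biostrings::nmatch(aln) / max(cols, 1)
        score <- Biostrings::score(aln)
        if (cols >= 0.5 * nchar(r) && idy >= min_id && score > best) {
          best <- score; best_id <- ids[i]
        }
      }
    }
    best_id
  }, character(1))
}

# a chromosome with n planted LTR elements of assorted geometry
make_element_cohort <- function(n = 20, seed = 77, max_divergence = 0.05,
                                pbs = "TGGTATCAGAGCCA") {
  set.seed(seed)
  tsds <- c("ACGT", "CATTG", "GGATCC", "TTAAC", "CGCGA")
  plants <- list(); pos <- 3000
  for (i in seq_len(n)) {
    ltr <- rnd_dna(sample(300:1500, 1))
    internal <- rnd_dna(sample(1500:4000, 1))
    dv <- stats::runif(1, 0, max_divergence)
    plants[[i]] <- element_plant(
      sprintf("e%02d", i), ltr, internal, start = pos,
      target_divergence = dv, tsd = sample(tsds, 1), pbs_motif = pbs)
    pos <- pos + centroscape:::plant_width(plants[[i]]) + sample(2000:4000, 1)
  }
  cs <- chrom_spec("cohort", pos + 3000, centromere_center = round(pos / 2),
                   element_plants = plants)
  simulate_genome(genome_spec(list(cs), seed = seed))
}

# a single-array chromosome for satellite tests
make_array_genome <- function(monomer, copies, mutation, seed = 3,
                              margin = 1000) {
  len <- copies * nchar(monomer) + 2 * margin
  ap <- array_plant("fam", monomer, copies, start = margin,
                    per_base_mutation = mutation)
  simulate_genome(genome_spec(list(
    chrom_spec("arr", len, centromere_center = round(len / 2),
               satellite_plants = list(ap))), seed = seed))
}

extract_truth_array <- function(genome) {
  a <- genome$truth$arrays[1, ]
  substring(genome$sequences[[a$chrom]], a$start + 1, a$end)
}
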