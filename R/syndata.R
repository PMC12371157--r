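#' Simulate a genome with planted centromeric features
#'
#' Generates i.i.d. background sequence at the specified GC content and
#' overwrites it with the planted satellite arrays and LTR retroelements of
#' each chromosome spec. One deterministic RNG stream is derived per
#' chromosome from the global seed, so the seed fully determines every
#' emitted base and the same spec always yields byte-identical output.
#'
#' Truth coordinates are 0-based half-open and name the emitted sequence
#' exactly: extracting a truth interval from the returned sequence
#' reproduces the planted (possibly mutated) feature byte-for-byte.
#'
#' @param spec a \code{\link{genome_spec}}.
#' @return An object of class \code{cen_genome}: a list with
#'   \item{sequences}{named character vector of chromosome sequences}
#'   \item{lengths}{named numeric vector of chromosome lengths}
#'   \item{truth}{list of data frames \code{arrays}, \code{elements} and
#'     \code{parts} (element substructure: TSDs, LTRs, PBS, internal and any
#'     planted protein-domain intervals)}
#'   \item{spec}{the input spec}
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  nchrom <- length(spec$chromosomes)
  seqs <- character(nchrom)
  arr_rows <- list(); el_rows <- list(); part_rows <- list()

  for (ci in seq_len(nchrom)) {
    cs <- spec$chromosomes[[ci]]
    set.seed(derive_seed(spec$seed, ci))
    v <- random_dna_vec(cs$length, spec$gc_background)

    for (ap in cs$satellite_plants) {
      ml <- nchar(ap$monomer)
      copies <- character(ap$copies)
      nsub <- 0L
      for (j in seq_len(ap$copies)) {
        m <- mutate_dna(ap$monomer, ap$per_base_mutation)
        cj <- m$seq
        if (ap$indel_rate > 0) cj <- indel_dna(cj, ap$indel_rate)
        copies[j] <- cj
        nsub <- nsub + m$n_sub
      }
      arr <- paste(copies, collapse = "")
      aw <- nchar(arr)
      v[(ap$start + 1):(ap$start + aw)] <- strsplit(arr, "", fixed = TRUE)[[1]]
      arr_rows[[length(arr_rows) + 1L]] <- data.frame(
        chrom = cs$name, start = ap$start, end = ap$start + aw,
        family_id = ap$family_id, copies = ap$copies, monomer_length = ml,
        n_substitutions = nsub,
        divergence = nsub / (ap$copies * ml),
        stringsAsFactors = FALSE)
    }

    for (ep in cs$element_plants) {
      m <- mutate_dna(ep$ltr_seq, ep$target_divergence)
      ltr3 <- m$seq
      Lltr <- nchar(ep$ltr_seq)
      pbs <- ep$pbs_motif %||% ""
      emit <- paste0(ep$tsd, ep$ltr_seq, pbs, ep$internal_seq, ltr3, ep$tsd)
      ew <- nchar(emit)
      v[(ep$start + 1):(ep$start + ew)] <- strsplit(emit, "", fixed = TRUE)[[1]]

      tl <- nchar(ep$tsd)
      s5 <- ep$start + tl                      # 5' LTR start (= element start)
      pbs_s <- s5 + Lltr
      int_s <- pbs_s + nchar(pbs)
      int_e <- int_s + nchar(ep$internal_seq)
      s3 <- int_e                              # 3' LTR start
      e3 <- s3 + Lltr                          # element end
      el_rows[[length(el_rows) + 1L]] <- data.frame(
        chrom = cs$name, element_id = ep$element_id,
        start = s5, end = e3,
        ltr5_start = s5, ltr5_end = s5 + Lltr,
        ltr3_start = s3, ltr3_end = e3,
        ltr_length = Lltr, tsd = ep$tsd,
        pbs_motif = if (nchar(pbs)) pbs else NA_character_,
        autonomy = ep$autonomy,
        target_divergence = ep$target_divergence,
        realized_divergence = m$n_sub / Lltr,
        n_substitutions = m$n_sub,
        stringsAsFactors = FALSE)

      add_part <- function(type, s, e) {
        part_rows[[length(part_rows) + 1L]] <<- data.frame(
          chrom = cs$name, element_id = ep$element_id, part = type,
          start = s, end = e, stringsAsFactors = FALSE)
      }
      add_part("target_site_duplication", ep$start, s5)
      add_part("long_terminal_repeat", s5, s5 + Lltr)
      if (nchar(pbs)) add_part("primer_binding_site", pbs_s, int_s)
      add_part("internal_region", int_s, int_e)
      add_part("long_terminal_repeat", s3, e3)
      add_part("target_site_duplication", e3, e3 + tl)
      if (!is.null(ep$domain_intervals)) {
        for (r in seq_len(nrow(ep$domain_intervals))) {
          di <- ep$domain_intervals[r, ]
          add_part(paste0("domain:", di$domain),
                   int_s + di$start, int_s + di$end)
        }
      }
    }
    seqs[ci] <- paste(v, collapse = "")
  }

  nm <- vapply(spec$chromosomes, function(x) x$name, character(1))
  names(seqs) <- nm
  empty_arr <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), family_id = character(0),
                          copies = integer(0), monomer_length = integer(0),
                          n_substitutions = integer(0), divergence = numeric(0),
                          stringsAsFactors = FALSE)
  structure(list(
    sequences = seqs,
    lengths = setNames(vapply(spec$chromosomes, function(x) x$length,
                              numeric(1)), nm),
    truth = list(
      arrays = if (length(arr_rows)) do.call(rbind, arr_rows) else empty_arr,
      elements = if (length(el_rows)) do.call(rbind, el_rows) else NULL,
      parts = if (length(part_rows)) do.call(rbind, part_rows) else NULL),
    spec = spec), class = "cen_genome")
}

#' @export
print.cen_genome <- function(x, ...) {
  cat("Simulated genome:", length(x$sequences), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  cat("  planted arrays:",
      if (is.null(x$truth$arrays)) 0 else nrow(x$truth$arrays),
      " planted elements:",
      if (is.null(x$truth$elements)) 0 else nrow(x$truth$elements), "\n")
  invisible(x)
}

# uniform draw of read starts over [0, npos) excluding [lo, hi] with prob
# weight `fold` on the inside; returns 0-based starts
draw_chip_starts <- function(n, npos, lo, hi, fold) {
  n_in <- max(hi - lo + 1, 0)
  n_out <- npos - n_in
  p_in <- fold * n_in / (fold * n_in + n_out)
  inside <- runif(n) < p_in
  starts <- numeric(n)
  k_in <- sum(inside)
  if (k_in) starts[inside] <- lo + sample.int(n_in, k_in, replace = TRUE) - 1
  k_out <- n - k_in
  if (k_out) {
    u <- sample.int(n_out, k_out, replace = TRUE) - 1
    starts[!inside] <- ifelse(u < lo, u, u + n_in)
  }
  starts
}

#' Simulate ChIP and input read sets
#'
#' Input read starts are uniform over each chromosome; ChIP read starts are
#' drawn with relative weight \code{spec$chip_fold} inside the interval
#' \code{centromere_center +/- chip_halfwidth} (taken from the genome spec)
#' and weight 1 elsewhere. Both channels receive
#' \code{round(input_depth * chrom_length / read_length)} reads per
#' chromosome; reads never extend past chromosome ends. Output is
#' seed-reproducible.
#'
#' @param genome a \code{\link{simulate_genome}} result.
#' @param spec a \code{\link{read_sim_spec}}.
#' @param sequences if \code{TRUE} (default) read sequences are extracted
#'   from the genome (reverse-complemented for minus-strand reads); with
#'   \code{FALSE} only positions are returned, which is sufficient for
#'   coverage-based stages and much lighter at high depth.
#' @return An object of class \code{read_sim}: list with data frames
#'   \code{chip} and \code{input} (columns \code{read_id}, \code{chrom},
#'   \code{start} (0-based), \code{strand} and optionally \code{seq}) plus
#'   the spec.
#' @export
simulate_reads <- function(genome, spec, sequences = TRUE) {
  stopifnot(inherits(genome, "cen_genome"), inherits(spec, "read_sim_spec"))
  if (spec$chip_fold < 1) stop("chip_fold must be >= 1")
  rl <- spec$read_length
  if (rl > min(genome$lengths))
    stop("read_length exceeds the shortest chromosome")

  one_channel <- function(channel, ci) {
    cs <- genome$spec$chromosomes[[ci]]
    len <- cs$length
    npos <- len - rl + 1
    n <- round(spec$input_depth * len / rl)
    set.seed(derive_seed(spec$seed, ci * 2L + (channel == "chip")))
    if (channel == "input" || is.na(cs$centromere_center) ||
        spec$chip_fold == 1) {
      starts <- sample.int(npos, n, replace = TRUE) - 1
    } else {
      lo <- max(0, cs$centromere_center - spec$chip_halfwidth)
      hi <- min(npos - 1, cs$centromere_center + spec$chip_halfwidth)
      starts <- draw_chip_starts(n, npos, lo, hi, spec$chip_fold)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    df <- data.frame(
      read_id = sprintf("%s_%s_%06d", channel, cs$name, seq_len(n)),
      chrom = cs$name, start = starts, strand = strand,
      stringsAsFactors = FALSE)
    if (sequences) {
      sq <- substring(genome$sequences[[ci]], starts + 1, starts + rl)
      neg <- strand == "-"
      if (any(neg)) sq[neg] <- revcomp(sq[neg])
      df$seq <- sq
    }
    df
  }

  nchrom <- length(genome$spec$chromosomes)
  chip <- do.call(rbind, lapply(seq_len(nchrom), one_channel, channel = "chip"))
  input <- do.call(rbind, lapply(seq_len(nchrom), one_channel, channel = "input"))
  structure(list(chip = chip, input = input, spec = spec),
            class = "read_sim")
}

DOMAIN_ORDER <- c("GAG", "PRO", "RT", "RH", "INT", "CHD")

# one deterministic codon per amino acid (reverse translation for planting
# protein domains into synthetic internal sequences)
REV_CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

reverse_translate <- function(aa) {
  v <- strsplit(toupper(aa), "", fixed = TRUE)[[1]]
  paste(REV_CODON[v], collapse = "")
}

#' Build a CRM-like internal sequence encoding selected protein domains
#'
#' Concatenates, in canonical chromovirus order (GAG, PRO, RT, RH, INT,
#' CHD), the reverse-translated amino-acid consensus of each requested
#' domain, separated by random spacer sequence. Used to plant autonomous
#' (all six domains) and nonautonomous (domain-deleted) retroelement
#' internals whose content is known exactly. Draws spacer bases from the
#' current RNG stream; seed beforehand for reproducibility.
#'
#' @param profiles named \code{AAStringSet} (or named character vector) of
#'   per-domain amino-acid consensi, e.g. from
#'   \code{\link{read_domain_profiles}}.
#' @param domains character vector of domains to include.
#' @param spacer_len spacer length in bp between consecutive parts.
#' @param gc spacer GC fraction.
#' @return list with \code{seq} and \code{domain_intervals} (data frame of
#'   0-based intervals relative to \code{seq}).
#' @export
make_crm_internal <- function(profiles, domains = DOMAIN_ORDER,
                              spacer_len = 150, gc = 0.4) {
  prof <- setNames(as.character(profiles), names(profiles))
  stopifnot(all(domains %in% names(prof)))
  domains <- DOMAIN_ORDER[DOMAIN_ORDER %in% domains]
  pieces <- character(0); rows <- list(); pos <- 0
  for (d in domains) {
    sp <- random_dna(spacer_len, gc)
    dna <- reverse_translate(prof[[d]])
    pieces <- c(pieces, sp, dna)
    rows[[d]] <- data.frame(domain = d, start = pos + spacer_len,
                            end = pos + spacer_len + nchar(dna),
                            stringsAsFactors = FALSE)
    pos <- pos + spacer_len + nchar(dna)
  }
  pieces <- c(pieces, random_dna(spacer_len, gc))
  list(seq = paste(pieces, collapse = ""),
       domain_intervals = do.call(rbind, rows))
}
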