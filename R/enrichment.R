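#' Construct or read a repeat consensus library
#'
#' A library is a data frame with one row per repeat consensus: \code{id},
#' \code{class} (\code{"satellite"} or \code{"TE"}), \code{monomer_length}
#' (integer as character, or \code{"variable"}) and \code{sequence}.
#'
#' @param id character vector of unique repeat ids.
#' @param class repeat class per entry.
#' @param sequence consensus nucleotide sequence per entry.
#' @param monomer_length nominal monomer length (bp) or \code{"variable"}.
#' @return data frame of class \code{repeat_library}.
#' @export
repeat_library <- function(id, class, sequence, monomer_length = "variable") {
  stopifnot(length(id) == length(sequence), all(nchar(sequence) > 0))
  if (length(id) == 0) monomer_length <- character(0)
  if (anyDuplicated(id)) stop("duplicate repeat ids in library")
  if (!all(class %in% c("satellite", "TE")))
    stop("repeat class must be 'satellite' or 'TE'")
  structure(data.frame(id = id, class = class,
                       monomer_length = as.character(monomer_length),
                       sequence = toupper(sequence),
                       stringsAsFactors = FALSE),
            class = c("repeat_library", "data.frame"))
}

#' Read a repeat library from FASTA
#'
#' Headers carry whitespace-separated tokens:
#' \code{>id class=satellite|TE monomer=<int|variable>}.
#'
#' @param path FASTA file path.
#' @return A \code{\link{repeat_library}} data frame.
#' @export
read_repeat_library <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  tok <- strsplit(hdr, "\\s+")
  id <- vapply(tok, `[`, character(1), 1)
  get_tok <- function(t, key, default) {
    hit <- grep(paste0("^", key, "="), t, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default
  }
  cls <- vapply(tok, get_tok, character(1), key = "class", default = "satellite")
  mono <- vapply(tok, get_tok, character(1), key = "monomer", default = "variable")
  repeat_library(id, cls, as.character(ss), mono)
}

# two-strand k-mer index over a library; repeats are kept in lexicographic
# id order so that "first" tie-breaking is the lexicographically smallest id
build_kmer_index <- function(library, k) {
  lib <- library[order(library$id), , drop = FALSE]
  km <- character(0); rp <- integer(0)
  for (i in seq_len(nrow(lib))) {
    ki <- unique(c(seq_kmers(lib$sequence[i], k),
                   seq_kmers(revcomp(lib$sequence[i]), k)))
    km <- c(km, ki)
    rp <- c(rp, rep.int(i, length(ki)))
  }
  reps <- split(rp, km)
  list(kmers = names(reps), reps = unname(reps),
       ids = lib$id, n = nrow(lib), k = k)
}

# vectorized chunked read -> repeat assignment; returns integer index into
# index$ids (NA = unassigned)
assign_reads <- function(seqs, index, min_fraction, chunk = 4000L) {
  k <- index$k; nrep <- index$n
  n <- length(seqs)
  out <- rep(NA_integer_, n)
  if (n == 0) return(out)
  L <- nchar(seqs)
  if (any(L < k)) stop("k exceeds read length")
  for (off in seq(1L, n, by = chunk)) {
    sel <- off:min(off + chunk - 1L, n)
    sq <- seqs[sel]; Ls <- L[sel]
    nk <- Ls - k + 1L
    starts <- sequence(nk)
    km <- substring(rep(sq, nk), starts, starts + k - 1L)
    ridx <- rep(seq_along(sq), nk)
    m <- match(km, index$kmers)
    keep <- !is.na(m)
    counts <- matrix(0L, nrow = nrep, ncol = length(sq))
    if (any(keep)) {
      hits <- index$reps[m[keep]]
      lens <- lengths(hits)
      rid <- rep(ridx[keep], lens)
      rrep <- unlist(hits, use.names = FALSE)
      counts <- matrix(tabulate((rid - 1L) * nrep + rrep,
                                nbins = length(sq) * nrep),
                       nrow = nrep)
    }
    best <- max.col(t(counts), ties.method = "first")
    bestcnt <- counts[cbind(best, seq_along(sq))]
    ok <- bestcnt > 0 & bestcnt >= min_fraction * nk
    out[sel[ok]] <- best[ok]
  }
  out
}

#' Count ChIP and input read hits against a repeat library
#'
#' Alignment-free assignment: a read is a hit to the repeat sharing the
#' largest number of canonical k-mers with it, provided that number is at
#' least \code{min_fraction * (read_length - k + 1)}. Ties are broken by the
#' lexicographically smallest repeat id; each read contributes to at most
#' one repeat. Strandedness is handled by indexing both strands of every
#' consensus, which is equivalent to canonical-k-mer matching.
#'
#' @param reads a \code{\link{simulate_reads}} result, or a list with
#'   elements \code{chip} and \code{input} that are character vectors of
#'   read sequences (or data frames with a \code{seq} column).
#' @param library a \code{\link{repeat_library}}.
#' @param k k-mer size (default 21).
#' @param min_fraction minimum shared-k-mer fraction for assignment.
#' @return data frame of class \code{hit_counts}: one row per repeat with
#'   \code{repeat_id}, \code{chip_hits}, \code{input_hits}, and the library
#'   sizes \code{chip_total}, \code{input_total} (reads examined per
#'   channel).
#' @export
count_hits <- function(reads, library, k = 21L, min_fraction = 0.5) {
  stopifnot(inherits(library, "repeat_library"), nrow(library) >= 1)
  get_seqs <- function(x) {
    if (is.data.frame(x)) {
      if (!"seq" %in% names(x))
        stop("reads were simulated without sequences; rerun with sequences = TRUE")
      x$seq
    } else as.character(x)
  }
  chip <- get_seqs(reads$chip)
  input <- get_seqs(reads$input)
  idx <- build_kmer_index(library, k)
  a_chip <- assign_reads(chip, idx, min_fraction)
  a_input <- assign_reads(input, idx, min_fraction)
  df <- data.frame(
    repeat_id = idx$ids,
    chip_hits = tabulate(a_chip, nbins = idx$n),
    input_hits = tabulate(a_input, nbins = idx$n),
    chip_total = length(chip),
    input_total = length(input),
    stringsAsFactors = FALSE)
  # index rows are in sorted-id order; restore the input library order
  df <- df[match(library$id, df$repeat_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hit_counts", "data.frame")
  df
}

#' Library-size-normalized ChIP/input ratio
#'
#' \code{(chip_hits / chip_total) / (input_hits / input_total)}, i.e. the
#' raw hit ratio corrected for the two channels' total read counts. Repeats
#' with zero input hits get \code{NA} (undefined) rather than infinity;
#' rounding is left to report time.
#'
#' @param chip_hits,input_hits per-repeat hit counts (vectorized).
#' @param chip_total,input_total total reads examined per channel (> 0).
#' @return numeric vector of normalized ratios (\code{NA} where undefined).
#' @export
normalized_ratio <- function(chip_hits, input_hits, chip_total, input_total) {
  stopifnot(all(chip_hits >= 0), all(input_hits >= 0),
            all(chip_total > 0), all(input_total > 0))
  out <- (chip_hits / chip_total) / (input_hits / input_total)
  out[input_hits == 0] <- NA_real_
  out
}

#' Attach normalized ratios to a hit-count table
#'
#' @param counts a \code{\link{count_hits}} result (or any data frame with
#'   the same columns).
#' @return the table with \code{normalized_ratio} and \code{note} columns
#'   (\code{"undefined (no input hits)"} where the ratio is undefined).
#' @export
hit_records <- function(counts) {
  counts$normalized_ratio <- normalized_ratio(
    counts$chip_hits, counts$input_hits,
    counts$chip_total, counts$input_total)
  counts$note <- ifelse(counts$input_hits == 0,
                        "undefined (no input hits)", "")
  counts
}

#' Rank repeats by normalized ratio and flag centromeric candidates
#'
#' Stable sort by descending normalized ratio; undefined ratios are listed
#' last. Repeats at or above \code{min_ratio} are flagged candidates.
#'
#' @param records output of \code{\link{hit_records}}.
#' @param min_ratio candidate threshold (default 10).
#' @return the reordered table with a logical \code{candidate} column.
#' @export
rank_candidates <- function(records, min_ratio = 10) {
  if (nrow(records) == 0) {
    records$candidate <- logical(0)
    return(records)
  }
  key <- records$normalized_ratio
  ord <- order(is.na(key), -ifelse(is.na(key), 0, key))
  out <- records[ord, , drop = FALSE]
  out$candidate <- !is.na(out$normalized_ratio) &
    out$normalized_ratio >= min_ratio
  rownames(out) <- NULL
  out
}

#' Recover the library-size constant from one published row
#'
#' When a repeat-survey table prints raw hit counts and the normalized
#' ratio but not the two library sizes, the implied constant
#' \code{input_total / chip_total} can be recovered from any single row as
#' printed ratio divided by raw ratio.
#'
#' @param printed_ratio the published normalized ratio of the row.
#' @param chip_hits,input_hits the row's raw hit counts.
#' @return the implied \code{input_total / chip_total} constant.
#' @seealso \code{\link{calibrated_ratio}}
#' @export
calibrate_library_ratio <- function(printed_ratio, chip_hits, input_hits) {
  stopifnot(printed_ratio > 0, chip_hits > 0, input_hits > 0)
  printed_ratio / (chip_hits / input_hits)
}

#' Normalized ratio from raw counts and a recovered library-size constant
#'
#' @param chip_hits,input_hits raw hit counts.
#' @param constant \code{input_total / chip_total}, e.g. from
#'   \code{\link{calibrate_library_ratio}}.
#' @return numeric vector (\code{NA} where \code{input_hits} is 0).
#' @export
calibrated_ratio <- function(chip_hits, input_hits, constant) {
  out <- constant * chip_hits / input_hits
  out[input_hits == 0] <- NA_real_
  out
}

#' Published hop centromeric repeat survey
#'
#' The printed per-repeat ChIP/input hit-count survey of the six hop
#' centromeric repeat families (satellites SaazCEN, Saaz293, Saaz85,
#' Saaz40, HuluTR120 and the CRM retrotransposon SaazCRM1), shipped as
#' package data and used as the reference input for normalization
#' arithmetic.
#'
#' @return data frame with columns \code{repeat}, \code{monomer_length},
#'   \code{chip_hits}, \code{input_hits}, \code{normalized_ratio},
#'   \code{annotation}.
#' @export
repeat_survey <- function() {
  read.delim(system.file("extdata", "hop_centromere_repeat_survey.tsv",
                         package = "centroscape"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
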