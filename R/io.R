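# Readers/writers for the standard interchange formats. Package-internal
# coordinates are 0-based half-open; BED output keeps that convention,
# GFF3 output is converted to 1-based closed by rtracklayer.

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write simulated reads to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality (the simulator has no
#' base-quality model).
#'
#' @param reads one channel of a \code{\link{simulate_reads}} result (a
#'   data frame with \code{read_id} and \code{seq}).
#' @param path output path.
#' @param format \code{"fasta"} (default) or \code{"fastq"}.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!"seq" %in% names(reads))
    stop("reads were simulated without sequences")
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(ss, path)
  } else {
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  }
  invisible(path)
}

#' Write planted-array truth as BED
#' @param genome a \code{\link{simulate_genome}} result.
#' @param path output BED path.
#' @export
write_truth_bed <- function(genome, path) {
  a <- genome$truth$arrays
  gr <- GenomicRanges::GRanges(
    a$chrom, IRanges::IRanges(a$start + 1, a$end),
    name = a$family_id, score = a$copies)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write planted-element truth (with substructure) as GFF3
#'
#' Elements are emitted as \code{LTR_retrotransposon} features with their
#' TSDs, LTRs, PBS, internal region and any planted protein domains as
#' \code{Parent}-linked children.
#'
#' @param genome a \code{\link{simulate_genome}} result.
#' @param path output GFF3 path.
#' @export
write_truth_gff3 <- function(genome, path) {
  el <- genome$truth$elements
  pt <- genome$truth$parts
  if (is.null(el)) stop("genome has no planted elements")
  part_type <- function(p) {
    ifelse(startsWith(p, "domain:"), "protein_match", p)
  }
  gr_el <- GenomicRanges::GRanges(
    el$chrom, IRanges::IRanges(el$start + 1, el$end),
    type = "LTR_retrotransposon", ID = el$element_id,
    Parent = NA_character_, Name = el$element_id)
  gr_pt <- GenomicRanges::GRanges(
    pt$chrom, IRanges::IRanges(pt$start + 1, pt$end),
    type = part_type(pt$part),
    ID = sprintf("%s_part%04d", pt$element_id, seq_len(nrow(pt))),
    Parent = pt$element_id,
    Name = sub("^domain:", "", pt$part))
  gr <- c(gr_el, gr_pt)
  S4Vectors::mcols(gr)$source <- "centroscape"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write annotated elements as GFF3
#' @param ann an \code{\link{annotate_elements}} result.
#' @param chrom chromosome name the elements live on.
#' @param path output GFF3 path.
#' @export
write_elements_gff3 <- function(ann, chrom, path) {
  el <- ann$elements
  grs <- list(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(el$start + 1, el$end),
    type = "LTR_retrotransposon", ID = el$element_id,
    Parent = NA_character_, Name = el$element_id))
  ltr_rows <- rbind(
    data.frame(id = el$element_id, s = el$ltr5_start, e = el$ltr5_end),
    data.frame(id = el$element_id, s = el$ltr3_start, e = el$ltr3_end))
  if (nrow(ltr_rows)) {
    grs[[2]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(ltr_rows$s + 1, ltr_rows$e),
      type = "long_terminal_repeat",
      ID = sprintf("%s_ltr%d", ltr_rows$id, seq_len(nrow(ltr_rows))),
      Parent = ltr_rows$id, Name = "LTR")
  }
  if (!is.null(ann$domain_hits) && nrow(ann$domain_hits)) {
    dh <- ann$domain_hits
    grs[[3]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(dh$start + 1, dh$end),
      type = "protein_match",
      ID = sprintf("%s_dom%d", dh$element_id, seq_len(nrow(dh))),
      Parent = dh$element_id, Name = dh$domain)
  }
  gr <- do.call(c, grs)
  S4Vectors::mcols(gr)$source <- "centroscape"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write a coverage track channel as bedGraph
#' @param track a \code{coverage_track}.
#' @param channel \code{"chip"} or \code{"input"}.
#' @param path output path.
#' @export
write_bedgraph <- function(track, channel = c("chip", "input"), path) {
  channel <- match.arg(channel)
  counts <- track[[paste0(channel, "_counts")]]
  nb <- length(counts)
  starts <- (seq_len(nb) - 1) * track$bin_size
  ends <- pmin(starts + track$bin_size, track$chrom_length)
  gr <- GenomicRanges::GRanges(track$chromosome,
                               IRanges::IRanges(starts + 1, ends),
                               score = counts)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
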