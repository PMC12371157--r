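#' Bin ChIP and input reads into fixed-width coverage tracks
#'
#' Each read is counted once, in the bin containing its start coordinate,
#' so bin counts sum to the number of reads per chromosome and channel.
#'
#' @param reads a \code{\link{simulate_reads}} result or a list with data
#'   frames \code{chip} and \code{input} (columns \code{chrom},
#'   \code{start}).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param bin_size bin width in bp (default 10 kb; must be at least the
#'   read length so a read cannot straddle more than two bins from its
#'   start bin).
#' @param read_length read length used for the end-of-chromosome check
#'   (taken from \code{reads$spec} when present).
#' @return named list of \code{coverage_track} objects (one per
#'   chromosome): \code{chromosome}, \code{chrom_length}, \code{bin_size},
#'   \code{chip_counts}, \code{input_counts}.
#' @export
bin_coverage <- function(reads, chrom_lengths, bin_size = 10000L,
                         read_length = NULL) {
  rl <- read_length %||% (if (!is.null(reads$spec)) reads$spec$read_length else 1L)
  if (bin_size < rl) stop("bin_size must be >= read length")
  channel_counts <- function(df, chrom, len, nb) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    if (nrow(d) == 0) return(integer(nb))
    if (any(d$start < 0 | d$start + rl > len))
      stop(sprintf("read beyond chromosome end on '%s'", chrom))
    tabulate(floor(d$start / bin_size) + 1L, nbins = nb)
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    nb <- ceiling(len / bin_size)
    structure(list(chromosome = ch, chrom_length = len,
                   bin_size = bin_size,
                   chip_counts = channel_counts(reads$chip, ch, len, nb),
                   input_counts = channel_counts(reads$input, ch, len, nb)),
              class = "coverage_track")
  })
  setNames(out, names(chrom_lengths))
}

#' Call the CENH3 summit of a chromosome from binned coverage
#'
#' Per-bin enrichment score
#' \code{log2(((chip + p) / chip_total) / ((input + p) / input_total))},
#' boxcar-smoothed over \code{smooth_bins} bins (shrinking windows at the
#' chromosome ends). The summit is the midpoint of the maximal-score bin;
#' exact ties resolve to the leftmost bin, with the remaining tied bins
#' recorded as secondary positions in the diagnostics.
#'
#' @param track a \code{coverage_track} from \code{\link{bin_coverage}}.
#' @param pseudocount count added to every bin in both channels.
#' @param smooth_bins boxcar window in bins (default 5).
#' @return object of class \code{summit_call}: \code{chromosome},
#'   \code{summit} (bp midpoint, \code{NA} if no enrichment),
#'   \code{summit_bin}, \code{enrichment_score} (smoothed log2 ratio at the
#'   summit), \code{flags} (may include \code{"no_enrichment"},
#'   \code{"flat_profile"}), \code{secondary} (tied summit positions) and
#'   the smoothed \code{score} track.
#' @export
call_summit <- function(track, pseudocount = 1, smooth_bins = 5L) {
  stopifnot(inherits(track, "coverage_track"))
  chip <- track$chip_counts; input <- track$input_counts
  stopifnot(length(chip) == length(input))
  flags <- character(0)
  if (sum(chip) == 0) {
    return(structure(list(chromosome = track$chromosome, summit = NA_real_,
                          summit_bin = NA_integer_,
                          enrichment_score = NA_real_,
                          flags = "no_enrichment",
                          secondary = numeric(0), score = NULL),
                     class = "summit_call"))
  }
  ct <- sum(chip); it <- sum(input)
  score <- log2(((chip + pseudocount) / ct) / ((input + pseudocount) / max(it, 1)))
  sm <- boxcar_smooth(score, smooth_bins)
  if (diff(range(sm)) < 1e-12) flags <- c(flags, "flat_profile")
  top <- which(sm == max(sm))
  bin <- top[1]
  mid <- function(b) min((b - 0.5) * track$bin_size, track$chrom_length)
  structure(list(chromosome = track$chromosome, summit = mid(bin),
                 summit_bin = bin, enrichment_score = sm[bin],
                 flags = flags,
                 secondary = if (length(top) > 1) vapply(top[-1], mid, numeric(1)) else numeric(0),
                 score = sm),
            class = "summit_call")
}

#' Extract the fixed-width centromeric domain around a summit
#'
#' The domain is \code{[summit - half_width, summit + half_width)}
#' intersected with the chromosome, i.e. 6 Mbp at the default half-width of
#' 3 Mbp whenever the summit is at least 3 Mbp from both chromosome ends,
#' and clipped (with a flag) otherwise.
#'
#' @param summit summit position in bp (0-based).
#' @param chrom_length chromosome length in bp.
#' @param half_width half-width in bp (default 3 Mb).
#' @param chromosome optional chromosome name carried through.
#' @return object of class \code{centromere_domain}: \code{domain_start},
#'   \code{domain_end}, \code{length}, \code{clipped}, \code{summit},
#'   \code{chromosome}.
#' @export
extract_domain <- function(summit, chrom_length, half_width = 3e6,
                           chromosome = NA_character_) {
  stopifnot(summit >= 0, summit <= chrom_length)
  s <- max(0, summit - half_width)
  e <- min(chrom_length, summit + half_width)
  structure(list(chromosome = chromosome, summit = summit,
                 domain_start = s, domain_end = e, length = e - s,
                 clipped = (e - s) < 2 * half_width),
            class = "centromere_domain")
}

#' Classify chromosome morphology from centromere position
#'
#' Levan-style arm-ratio classification: with \code{q >= p} the arm ratio
#' \code{q/p} maps to metacentric (< 1.7), submetacentric ([1.7, 3.0)) or
#' acrocentric (>= 3.0) under the default cut-offs.
#'
#' @param summit centromere position in bp.
#' @param chrom_length chromosome length in bp.
#' @param thresholds numeric cut-offs \code{c(submetacentric, acrocentric)}.
#' @return data frame row: \code{p_arm}, \code{q_arm}, \code{arm_ratio},
#'   \code{class}, \code{flag} (\code{"telocentric/undefined"} for a
#'   terminal summit).
#' @export
classify_morphology <- function(summit, chrom_length,
                                thresholds = c(1.7, 3.0)) {
  stopifnot(summit >= 0, summit <= chrom_length, length(thresholds) == 2)
  p <- min(summit, chrom_length - summit)
  q <- max(summit, chrom_length - summit)
  if (p == 0) {
    return(data.frame(p_arm = p, q_arm = q, arm_ratio = Inf,
                      class = "telocentric", flag = "telocentric/undefined",
                      stringsAsFactors = FALSE))
  }
  ratio <- q / p
  cls <- if (ratio < thresholds[1]) "metacentric"
         else if (ratio < thresholds[2]) "submetacentric"
         else "acrocentric"
  data.frame(p_arm = p, q_arm = q, arm_ratio = ratio, class = cls,
             flag = "", stringsAsFactors = FALSE)
}
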