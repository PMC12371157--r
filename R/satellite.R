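#' Estimate the monomer length of a tandem array by periodicity
#'
#' Computes the shifted-match profile: for each candidate period \code{p}
#' the fraction of positions where \code{sequence[i] == sequence[i + p]}.
#' A true tandem period produces a sharp peak (about
#' \code{(1 - e)^2 + e^2/3} for per-copy mutation rate \code{e}); the
#' estimator returns the smallest period whose match fraction is within
#' 0.02 of the global peak, so harmonics (2p, 3p, ...) are reported as
#' secondary rather than returned. Confidence is the robust z-score of the
#' peak against the profile background; below \code{min_confidence} the
#' result is \code{"no_period"}.
#'
#' The profile compares a sequence with a shifted copy of itself, so the
#' estimate is invariant under cyclic rotation of the array.
#'
#' @param sequence array sequence (>= 3x \code{max_period} long).
#' @param min_period,max_period candidate period range in bp
#'   (\code{max_period} defaults to \code{min(500, floor(n/3))}).
#' @param min_confidence robust z-score threshold (default 10).
#' @return object of class \code{monomer_estimate}: \code{period},
#'   \code{confidence}, \code{status} (\code{"ok"} or \code{"no_period"}),
#'   \code{harmonics}, \code{copy_estimate}
#'   (\code{floor(n / period)}) and the match \code{profile}.
#' @export
estimate_monomer_length <- function(sequence, min_period = 10L,
                                    max_period = NULL,
                                    min_confidence = 10) {
  n <- nchar(sequence)
  if (n < 3 * min_period) stop("sequence shorter than 3 * min_period")
  max_period <- as.integer(max_period %||% min(500L, floor(n / 3)))
  stopifnot(max_period >= min_period, n >= 3 * max_period)
  x <- charToRaw(toupper(sequence))
  periods <- min_period:max_period
  prof <- vapply(periods, function(p) shift_match_fraction(x, p), numeric(1))
  med <- median(prof)
  sc <- mad(prof)
  if (sc == 0) sc <- max(stats::sd(prof), 1e-6)
  z <- (prof - med) / sc
  peak <- max(prof)
  # a period is significant on a robust z-score against the profile
  # background, or outright when the match fraction is unreachable by
  # unstructured sequence (i.i.d. background peaks near 0.3)
  sig <- z >= min_confidence | prof >= 0.8
  cand <- periods[prof >= peak - 0.02 & sig]
  if (length(cand) == 0) {
    return(structure(list(period = NA_integer_, confidence = max(z),
                          status = "no_period", harmonics = integer(0),
                          copy_estimate = NA_integer_,
                          profile = setNames(prof, periods)),
                     class = "monomer_estimate"))
  }
  period <- min(cand)
  structure(list(period = period,
                 confidence = z[match(period, periods)],
                 status = "ok",
                 harmonics = setdiff(cand, period),
                 copy_estimate = as.integer(floor(n / period)),
                 profile = setNames(prof, periods)),
            class = "monomer_estimate")
}

#' Windowed pairwise-identity matrix of a region
#'
#' Tiles the sequence into windows and computes, for every window pair, the
#' global-alignment percent identity (matches / alignment columns, gaps
#' counting against identity), taking the better of the two strands. The
#' matrix is symmetric with a 100 diagonal.
#'
#' @param sequence region sequence.
#' @param window window width in bp (default 5 kb).
#' @param step tiling step in bp (default 2 kb); \code{step > window} is
#'   allowed (sparse tiling) but flagged.
#' @return object of class \code{identity_matrix}: \code{values} (percent
#'   identity matrix), \code{starts} (0-based window starts),
#'   \code{window}, \code{step}, \code{sparse}.
#' @export
identity_heatmap <- function(sequence, window = 5000L, step = 2000L) {
  n <- nchar(sequence)
  if (window > n) stop("window exceeds sequence length")
  starts <- seq(0L, n - window, by = step)
  w <- length(starts)
  vals <- matrix(100, w, w)
  if (w > 1) {
    wins <- substring(sequence, starts + 1, starts + window)
    for (i in 1:(w - 1)) {
      for (j in (i + 1):w) {
        id <- pct_identity(wins[i], wins[j], both_strands = TRUE)
        vals[i, j] <- vals[j, i] <- id
      }
    }
  }
  structure(list(values = vals, starts = starts, window = window,
                 step = step, sparse = step > window),
            class = "identity_matrix")
}

#' Detect internally repeated subunits within a satellite monomer
#'
#' Self-comparison by shifted matching: for each candidate shift the
#' monomer is compared with itself offset by that shift, and runs of at
#' least \code{min_len} bases with identity >= \code{min_identity} indicate
#' an internal repeat of period equal to the shift. The smallest qualifying
#' shift is reported as the subunit length, with copy count and 0-based
#' offsets of each copy. When the repeat structure spans (nearly) the whole
#' monomer the monomer is itself a tandem array of the subunit and is
#' flagged as such, with the shift reported as the candidate true monomer.
#'
#' @param monomer monomer consensus sequence (> 2x \code{min_len}).
#' @param min_len minimum subunit length (default 20).
#' @param max_len maximum subunit length (default half the monomer).
#' @param min_identity run identity threshold (default 0.8).
#' @return object of class \code{subunit_annotation}:
#'   \code{subunit_length}, \code{copies}, \code{positions} (0-based copy
#'   start offsets), \code{tandem_monomer}, \code{candidate_monomer}.
#'   Empty annotation (\code{copies = 0}) when nothing is found.
#' @export
detect_subunits <- function(monomer, min_len = 20L, max_len = NULL,
                            min_identity = 0.8) {
  n <- nchar(monomer)
  if (n <= 2 * min_len) stop("monomer too short for subunit detection")
  max_len <- as.integer(max_len %||% floor(n / 2))
  x <- charToRaw(toupper(monomer))
  empty <- structure(list(subunit_length = NA_integer_, copies = 0L,
                          positions = integer(0), tandem_monomer = FALSE,
                          candidate_monomer = NA_integer_),
                     class = "subunit_annotation")
  for (s in min_len:max_len) {
    v <- x[1:(n - s)] == x[(s + 1):n]
    if (length(v) < min_len) break
    rm_ <- boxcar_windowed_mean(v, min_len)
    ok <- which(rm_ >= min_identity)
    if (length(ok) == 0) next
    # first maximal block of qualifying window starts
    brk <- which(diff(ok) > 1)
    i0 <- ok[1]
    iend <- if (length(brk)) ok[brk[1]] else ok[length(ok)]
    run_len <- (iend + min_len - 1) - i0 + 1
    if (run_len < min_len) next
    copies <- as.integer(floor(run_len / s) + 1)
    tandem <- (run_len + s) >= 0.9 * n
    return(structure(list(
      subunit_length = as.integer(s), copies = copies,
      positions = as.integer(i0 - 1 + s * (0:(copies - 1))),
      tandem_monomer = tandem,
      candidate_monomer = if (tandem) as.integer(s) else NA_integer_),
      class = "subunit_annotation"))
  }
  empty
}

# mean of v over sliding windows of width w (window start positions)
boxcar_windowed_mean <- function(v, w) {
  n <- length(v)
  if (n < w) return(numeric(0))
  cs <- cumsum(c(0, v))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

#' Percent identity between two satellite consensi, phase-free
#'
#' Satellite monomers have arbitrary phase, so the comparison searches all
#' cyclic rotations of \code{b} (coarse stride then single-base refinement)
#' and both strands, reporting the best global-alignment identity
#' (matches / alignment columns).
#'
#' @param a,b consensus sequences (non-empty).
#' @param coarse coarse rotation stride (default 4).
#' @return list: \code{identity} (percent), \code{rotation} (best rotation
#'   of \code{b}), \code{strand}, \code{columns} (alignment span).
#' @export
consensus_similarity <- function(a, b, coarse = 4L) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  rot <- function(s, r) {
    nb <- nchar(s)
    r <- r %% nb
    if (r == 0) s else paste0(substring(s, r + 1, nb), substring(s, 1, r))
  }
  # stiffer gap penalties than the package default: the maximum over ~2n/4
  # rotations would otherwise favour wrong-phase alignments that fake
  # identity through cheap gaps
  eval_rot <- function(seqb, r, strand) {
    id <- alignment_identity(align_nt(a, rot(seqb, r), gap_open = 4,
                                      gap_extend = 1))
    list(identity = id, rotation = r, strand = strand)
  }
  best <- list(identity = -1)
  for (strand in c("+", "-")) {
    sb <- if (strand == "+") b else revcomp(b)
    offsets <- seq(0L, nchar(b) - 1L, by = coarse)
    res <- lapply(offsets, function(r) eval_rot(sb, r, strand))
    ids <- vapply(res, `[[`, numeric(1), "identity")
    top <- res[[which.max(ids)]]
    refine <- setdiff(unique((top$rotation + (-(coarse - 1)):(coarse - 1)) %% nchar(b)),
                      offsets)
    for (r in refine) {
      cand <- eval_rot(sb, r, strand)
      if (cand$identity > top$identity) top <- cand
    }
    if (top$identity > best$identity) best <- top
  }
  aln <- align_nt(a, rot(if (best$strand == "+") b else revcomp(b),
                         best$rotation), gap_open = 4, gap_extend = 1)
  best$columns <- alignment_columns(aln)
  best
}
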