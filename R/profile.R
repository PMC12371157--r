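#' Mask a domain sequence against a repeat consensus library
#'
#' Each consensus is split into ~100-bp tiles which are matched against the
#' domain on both strands with a mismatch budget derived from
#' \code{min_identity} (substitution-only matching). Per-family hits are
#' merged, then overlaps across families are resolved by greedy
#' score-ordered non-overlap tiling: the higher-scoring interval wins,
#' losers are trimmed to their non-overlapping remainder (kept if still >=
#' \code{min_len}); score ties go to the lexicographically smaller family
#' id. The procedure is idempotent: adjudicating an already non-overlapping
#' annotation changes nothing.
#'
#' @param domain_sequence the domain sequence.
#' @param library a \code{\link{repeat_library}}.
#' @param min_len minimum masked interval length (default 30 bp).
#' @param min_identity minimum tile identity (default 0.7).
#' @param tile consensus tile width (default 100 bp).
#' @return object of class \code{domain_mask}: \code{intervals} (data
#'   frame: \code{family}, 0-based \code{start}, \code{end},
#'   \code{score}), \code{bp_per_family} (named vector over all library
#'   families), \code{unassigned_bp}, \code{domain_length}.
#' @export
mask_domain <- function(domain_sequence, library, min_len = 30L,
                        min_identity = 0.7, tile = 100L) {
  n <- nchar(domain_sequence)
  fams <- if (nrow(library)) library$id else character(0)
  if (nrow(library) == 0) {
    return(structure(list(
      intervals = data.frame(family = character(0), start = numeric(0),
                             end = numeric(0), score = numeric(0),
                             stringsAsFactors = FALSE),
      bp_per_family = setNames(numeric(0), character(0)),
      unassigned_bp = n, domain_length = n), class = "domain_mask"))
  }
  subject <- Biostrings::DNAString(domain_sequence)
  rows <- list()
  for (i in seq_len(nrow(library))) {
    cons <- library$sequence[i]
    cl <- nchar(cons)
    starts <- seq(1L, cl, by = tile)
    ends <- pmin(starts + tile - 1L, cl)
    # fold a short trailing tile into the previous one
    if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1) < min_len) {
      starts <- starts[-length(starts)]
      ends[length(ends) - 1] <- cl
      ends <- ends[-length(ends)]
    }
    for (t in seq_along(starts)) {
      pat <- substring(cons, starts[t], ends[t])
      tw <- nchar(pat)
      if (tw < min_len) next
      mm <- floor((1 - min_identity) * tw)
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else revcomp(pat)
        hits <- Biostrings::matchPattern(p, subject, max.mismatch = mm,
                                         with.indels = FALSE)
        if (length(hits) == 0) next
        hs <- BiocGenerics::start(hits) - 1
        he <- BiocGenerics::end(hits)
        nmm <- vapply(as.character(hits), function(h) str_mismatches(h, p),
                      numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          family = library$id[i], start = hs, end = he,
          score = tw - nmm, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), start = numeric(0), end = numeric(0),
               score = numeric(0), stringsAsFactors = FALSE)
  # adjudicate at the individual tile-hit level (merging first would let a
  # long consensus that embeds another family's monomer swallow that
  # family's arrays), then merge the accepted pieces per family
  adj <- adjudicate_hits(hits, min_len)
  merged <- list()
  for (f in unique(adj$family)) {
    h <- adj[adj$family == f, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(h$start + 1, h$end),
                          min.gapwidth = 1L)
    ov <- IRanges::findOverlaps(IRanges::IRanges(h$start + 1, h$end), ir)
    agg <- tapply(h$score[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), sum)
    sc <- numeric(length(ir))
    sc[as.integer(names(agg))] <- agg
    merged[[f]] <- data.frame(family = f,
                              start = BiocGenerics::start(ir) - 1,
                              end = BiocGenerics::end(ir),
                              score = sc, stringsAsFactors = FALSE)
  }
  merged <- if (length(merged)) do.call(rbind, merged) else adj
  if (nrow(merged)) {
    merged <- merged[order(merged$start), , drop = FALSE]
    rownames(merged) <- NULL
  }
  bp <- setNames(numeric(length(fams)), fams)
  if (nrow(merged)) {
    agg <- tapply(merged$end - merged$start, merged$family, sum)
    bp[names(agg)] <- agg
  }
  structure(list(intervals = merged, bp_per_family = bp,
                 unassigned_bp = n - sum(bp), domain_length = n),
            class = "domain_mask")
}

# greedy score-ordered non-overlap adjudication with trimming; input/output
# 0-based half-open intervals with family + score
adjudicate_hits <- function(hits, min_len = 30L) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(-hits$score, hits$family, hits$start), , drop = FALSE]
  taken <- IRanges::IRanges()
  out <- list()
  for (i in seq_len(nrow(hits))) {
    cur <- IRanges::IRanges(hits$start[i] + 1, hits$end[i])
    free <- BiocGenerics::setdiff(cur, taken)
    free <- free[IRanges::width(free) >= min_len]
    if (length(free) == 0) next
    taken <- IRanges::reduce(c(taken, free))
    out[[length(out) + 1L]] <- data.frame(
      family = hits$family[i],
      start = BiocGenerics::start(free) - 1,
      end = BiocGenerics::end(free),
      score = hits$score[i], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else hits[0, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a centromeric domain into composition types
#'
#' Centromeres of the first type are composed essentially of the two major
#' repeats (the centromeric satellite and the centrophilic CRM
#' retrotransposon); the second type additionally carries chromosome-
#' specific accessory satellite arrays. The call is type 2 when any
#' accessory satellite family occupies at least \code{min_fraction} of the
#' domain (inclusive threshold).
#'
#' @param mask a \code{\link{mask_domain}} result.
#' @param library the \code{\link{repeat_library}} used for masking (for
#'   satellite/TE classes).
#' @param major_families ids of the two major families (non-accessory).
#' @param min_fraction accessory-fraction threshold (default 0.02).
#' @return list of class \code{centromere_type}: \code{type}
#'   (\code{"type1"}/\code{"type2"}), \code{accessory} (data frame of
#'   triggering families with fractions), \code{fractions} (all families).
#' @export
classify_centromere_type <- function(mask, library, major_families,
                                     min_fraction = 0.02) {
  stopifnot(inherits(mask, "domain_mask"))
  frac <- mask$bp_per_family / mask$domain_length
  sat <- library$id[library$class == "satellite"]
  accessory_ids <- setdiff(sat, major_families)
  acc <- frac[accessory_ids]
  trig <- acc[!is.na(acc) & acc >= min_fraction]
  structure(list(
    type = if (length(trig)) "type2" else "type1",
    accessory = data.frame(family = names(trig), fraction = as.numeric(trig),
                           stringsAsFactors = FALSE),
    fractions = frac, min_fraction = min_fraction),
    class = "centromere_type")
}

#' Assign CENH3 summits to retroelement substructure
#'
#' Each summit falls in exactly one category: inside a protein-coding
#' (domain) interval of an element -> \code{coding}; inside either LTR ->
#' \code{ltr}; inside an element but neither -> \code{spacer}; not inside
#' any element -> \code{outside_element}. Coding takes precedence over LTR
#' as a safety rule (by construction the two never overlap). Intervals are
#' half-open, so a summit at an element end is outside it.
#'
#' @param summits numeric vector of summit positions (bp, 0-based).
#' @param elements element table (needs \code{element_id}, \code{start},
#'   \code{end}, \code{ltr5_start/end}, \code{ltr3_start/end}).
#' @param domain_hits optional data frame of coding intervals
#'   (\code{element_id}, \code{start}, \code{end}), e.g. from
#'   \code{\link{annotate_elements}}.
#' @return list: \code{assignments} (data frame: \code{summit},
#'   \code{category}, \code{element_id}), \code{frequencies} (category
#'   counts over all four categories; sums to \code{length(summits)}).
#' @export
assign_summits <- function(summits, elements, domain_hits = NULL) {
  cats <- c("ltr", "coding", "spacer", "outside_element")
  assign_one <- function(s) {
    if (nrow(elements)) {
      inside <- which(s >= elements$start & s < elements$end)
    } else inside <- integer(0)
    if (length(inside) == 0)
      return(list(category = "outside_element", element_id = NA_character_))
    i <- inside[1]
    eid <- elements$element_id[i]
    if (!is.null(domain_hits) && nrow(domain_hits)) {
      dh <- domain_hits[domain_hits$element_id == eid, , drop = FALSE]
      if (any(s >= dh$start & s < dh$end))
        return(list(category = "coding", element_id = eid))
    }
    in_ltr <- (s >= elements$ltr5_start[i] & s < elements$ltr5_end[i]) ||
      (s >= elements$ltr3_start[i] & s < elements$ltr3_end[i])
    if (in_ltr) return(list(category = "ltr", element_id = eid))
    list(category = "spacer", element_id = eid)
  }
  res <- lapply(summits, assign_one)
  df <- data.frame(
    summit = summits,
    category = vapply(res, `[[`, character(1), "category"),
    element_id = vapply(res, `[[`, character(1), "element_id"),
    stringsAsFactors = FALSE)
  freq <- table(factor(df$category, levels = cats))
  list(assignments = df, frequencies = freq)
}
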