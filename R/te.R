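#' Detect intact LTR retroelements by structural self-comparison
#'
#' De novo structure-only detection: exact k-mer anchors shared between two
#' same-strand blocks at a separation of \code{min_sep}..\code{max_sep} bp
#' are grouped by diagonal (separation), clustered, and each cluster's LTR
#' pair is boundary-refined by extension along the diagonal. Candidates
#' must have LTR length within \code{[min_ltr, max_ltr]} and LTR-LTR
#' identity >= \code{min_identity}. Boundaries are then pinned by searching
#' a small jitter window for an exact 4-6 bp target-site duplication (TSD)
#' flanking the element; candidates without a TSD are kept but flagged.
#' Candidate "LTR" blocks that are themselves tandem-periodic (shifted-match
#' fraction >= 0.75 at any period up to 500 bp) are rejected, which
#' suppresses spurious pairs arising inside satellite arrays. Overlapping
#' candidates are resolved greedily (TSD-bearing first, then by
#' identity x length). Solo LTRs - isolated copies of a detected element's
#' LTR without a partner at plausible separation - are excluded from the
#' element list and reported separately.
#'
#' @param sequence the (domain) sequence to scan.
#' @param k anchor k-mer size (default 21).
#' @param min_ltr,max_ltr LTR length bounds in bp (defaults 100, 3000).
#' @param min_sep,max_sep separation bounds between LTR starts (defaults
#'   1 kb, 25 kb).
#' @param min_identity minimum LTR-LTR identity (default 0.85).
#' @param max_anchor_occ k-mers occurring more often than this are not used
#'   as anchors (they are almost surely satellite k-mers; default 25).
#' @param anchor_gap anchor runs split at gaps larger than this (default
#'   500 bp).
#' @param tsd_jitter boundary jitter (bp, each direction) searched for an
#'   exact TSD (default 10).
#' @return object of class \code{ltr_scan}: \code{elements} (data frame,
#'   0-based half-open: \code{element_id}, \code{start}, \code{end},
#'   \code{ltr5_start/end}, \code{ltr3_start/end}, \code{separation},
#'   \code{ltr_identity} (percent), \code{tsd}, \code{has_tsd}),
#'   \code{solo} (solo-LTR report) and \code{params}.
#' @export
find_ltr_elements <- function(sequence, k = 21L, min_ltr = 100L,
                              max_ltr = 3000L, min_sep = 1000L,
                              max_sep = 25000L, min_identity = 0.85,
                              max_anchor_occ = 25L, anchor_gap = 500L,
                              tsd_jitter = 10L) {
  n <- nchar(sequence)
  x <- charToRaw(toupper(sequence))
  empty_el <- data.frame(element_id = character(0), start = numeric(0),
                         end = numeric(0), ltr5_start = numeric(0),
                         ltr5_end = numeric(0), ltr3_start = numeric(0),
                         ltr3_end = numeric(0), separation = numeric(0),
                         ltr_identity = numeric(0), tsd = character(0),
                         has_tsd = logical(0), stringsAsFactors = FALSE)
  empty_solo <- data.frame(start = numeric(0), end = numeric(0),
                           partner = character(0), stringsAsFactors = FALSE)
  params <- list(k = k, min_ltr = min_ltr, max_ltr = max_ltr,
                 min_sep = min_sep, max_sep = max_sep,
                 min_identity = min_identity)
  done <- function(el, solo) structure(list(elements = el, solo = solo,
                                            params = params),
                                       class = "ltr_scan")
  if (n < min_sep + min_ltr) return(done(empty_el, empty_solo))

  km <- seq_kmers(sequence, k)
  pos <- split(seq_along(km), km)          # 1-based k-mer starts
  pos <- pos[lengths(pos) >= 2 & lengths(pos) <= max_anchor_occ]
  if (length(pos) == 0) return(done(empty_el, empty_solo))

  # anchor pairs with separation in range
  P1 <- integer(0); P2 <- integer(0)
  for (p in pos) {
    m <- length(p)
    i <- rep(seq_len(m - 1), times = (m - 1):1)
    j <- unlist(lapply(2:m, function(a) a:m))
    d <- p[j] - p[i]
    keep <- d >= min_sep & d <= max_sep
    P1 <- c(P1, p[i][keep]); P2 <- c(P2, p[j][keep])
  }
  if (length(P1) == 0) return(done(empty_el, empty_solo))
  D <- P2 - P1
  ord <- order(D, P1)
  P1 <- P1[ord]; D <- D[ord]

  # cluster anchors: same diagonal, nearby 5' positions
  grp <- cumsum(c(TRUE, diff(D) != 0 | diff(P1) > anchor_gap))
  cand <- list()
  for (g in split(seq_along(P1), grp)) {
    s0 <- min(P1[g]) - 1L            # 0-based candidate 5' LTR start
    e0 <- max(P1[g]) - 1L + k        # 0-based exclusive end
    d <- D[g][1]
    cand[[length(cand) + 1L]] <- refine_ltr_candidate(
      x, n, s0, e0, d, min_ltr, max_ltr, min_identity, tsd_jitter)
  }
  cand <- cand[!vapply(cand, is.null, logical(1))]
  if (length(cand) == 0) return(done(empty_el, empty_solo))

  el <- do.call(rbind, lapply(cand, as.data.frame,
                              stringsAsFactors = FALSE))
  # greedy non-overlap adjudication: TSD-bearing candidates first, then the
  # shortest consistent structure (elements sharing an LTR sequence spawn
  # cross-copy pairs at larger separation; the innermost pairing is the
  # real one), then identity
  el <- el[order(-el$has_tsd, el$separation, -el$ltr_identity), , drop = FALSE]
  accepted <- el[0, , drop = FALSE]
  for (i in seq_len(nrow(el))) {
    if (nrow(accepted) == 0 ||
        all(el$end[i] <= accepted$start | el$start[i] >= accepted$end)) {
      accepted <- rbind(accepted, el[i, , drop = FALSE])
    }
  }
  accepted <- accepted[order(accepted$start), , drop = FALSE]
  accepted$element_id <- sprintf("LTRE_%03d", seq_len(nrow(accepted)))
  accepted$score <- NULL
  rownames(accepted) <- NULL
  accepted <- accepted[, c("element_id", setdiff(names(accepted), "element_id"))]

  solo <- find_solo_ltrs(sequence, accepted, k, min_ltr, anchor_gap)
  done(accepted, solo)
}

# extend a candidate LTR pair along its exact diagonal, then pin boundaries
# with an exact-TSD jitter search; x is the raw sequence, coordinates
# 0-based half-open; returns NULL when the candidate fails the filters
refine_ltr_candidate <- function(x, n, s0, e0, d, min_ltr, max_ltr,
                                 min_identity, tsd_jitter) {
  # extension along the diagonal: compare x[i] with x[i + d] (0-based i),
  # stop after 4 consecutive mismatches, then trim back to the furthest
  # matching position whose trailing 10-window holds >= 8 matches. Random
  # sequence beyond the repeat boundary reaches that quality with
  # probability ~4e-4 per position, so chance matches rarely drag the edge
  # out; mildly diverged true edges that get trimmed a few bp short are
  # recovered by the TSD jitter search.
  extend <- function(from, step, bound) {
    i <- from; ms <- logical(0); run <- 0L
    while (i != bound) {
      m <- x[i + 1L] == x[i + d + 1L]
      ms <- c(ms, m)
      run <- if (m) 0L else run + 1L
      if (run >= 4L) break
      i <- i + step
    }
    good <- 0L
    for (j in seq_along(ms)) {
      w <- max(1L, j - 9L):j
      if (ms[j] && sum(ms[w]) >= ceiling(0.8 * length(w))) good <- j
    }
    if (good == 0L) from - step else from + step * (good - 1L)
  }
  lo_bound <- max(-1L, s0 - max_ltr)
  s <- max(extend(s0 - 1L, -1L, lo_bound), 0L)
  s <- min(s, s0)
  hi_bound <- min(n - d, s0 + max_ltr + 1L)
  e <- extend(e0, +1L, hi_bound) + 1L       # exclusive end
  e <- max(e, e0)
  # edge-quality trim: a rare long chance-match run beyond the repeat can
  # survive the extension stop; the giveaway is a low-identity outer edge
  mv <- x[(s + 1L):e] == x[(s + d + 1L):(e + d)]
  while (length(mv) > min_ltr && mean(mv[1:20]) < 0.7) {
    mv <- mv[-1L]; s <- s + 1L
  }
  while (length(mv) > min_ltr && mean(mv[(length(mv) - 19L):length(mv)]) < 0.7) {
    mv <- mv[-length(mv)]; e <- e - 1L
  }
  L <- e - s
  if (L < min_ltr || L > max_ltr || L >= d) return(NULL)
  ident <- mean(mv)
  if (ident < min_identity) return(NULL)
  # tandem-periodicity filter over the whole candidate span: a pair found
  # inside a satellite array leaves the span itself periodic at the
  # monomer length, which a genuine LTR element never is
  span <- x[(s + 1L):min(e + d, length(x))]
  if (length(span) >= 60L) {
    shifts <- seq(10L, min(500L, length(span) - 10L), by = 1L)
    for (sh in shifts) {
      if (shift_match_fraction(span, sh) >= 0.75) return(NULL)
    }
  }
  # exact-TSD jitter search: diverged edges make the extension stop early
  # (boundary inside the LTR) and chance matches make it overshoot, so the
  # search covers both directions.
  a0 <- s; ee0 <- s + d + L
  best <- NULL
  offs <- expand.grid(da = -tsd_jitter:tsd_jitter, de = -tsd_jitter:tsd_jitter)
  # joint score: a longer duplication is better, but not at the price of a
  # large boundary shift (chance duplications inside the LTR body would
  # otherwise beat the true TSD; sub-duplications of the true TSD at
  # shifted offsets would otherwise beat the full-length one)
  for (t in 6:4) {
    for (r in seq_len(nrow(offs))) {
      a <- a0 + offs$da[r]; ee <- ee0 + offs$de[r]
      if (ee - a - d < min_ltr || ee - a - d > max_ltr) next
      if (a - t < 0 || ee + t > n) next
      left <- x[(a - t + 1L):a]
      right <- x[(ee + 1L):(ee + t)]
      if (all(left == right)) {
        # inward shifts (shrinking the element) are cheap because the
        # extension overshoots far more often than it stops short;
        # outward shifts are expensive
        da <- offs$da[r]; de <- offs$de[r]
        inward <- max(da, 0) + max(-de, 0)
        outward <- max(-da, 0) + max(de, 0)
        sc <- t - 0.25 * inward - 1.0 * outward
        if (is.null(best) || sc > best$sc)
          best <- list(a = a, ee = ee, t = t, sc = sc)
      }
    }
  }
  if (!is.null(best)) {
    a <- best$a; ee <- best$ee
    Lf <- ee - a - d
    tsd <- rawToChar(x[(a - best$t + 1L):a])
    has_tsd <- TRUE
  } else {
    a <- a0; ee <- ee0; Lf <- L; tsd <- NA_character_; has_tsd <- FALSE
  }
  list(start = a, end = ee,
       ltr5_start = a, ltr5_end = a + Lf,
       ltr3_start = a + d, ltr3_end = ee,
       separation = d, ltr_identity = 100 * ident,
       tsd = tsd, has_tsd = has_tsd)
}

# isolated copies of detected element LTRs (no partner): k-mer footprint of
# each element's 5' LTR outside any accepted element span
find_solo_ltrs <- function(sequence, elements, k, min_ltr, anchor_gap) {
  solo <- data.frame(start = numeric(0), end = numeric(0),
                     partner = character(0), stringsAsFactors = FALSE)
  if (nrow(elements) == 0) return(solo)
  n <- nchar(sequence)
  km_all <- seq_kmers(sequence, k)
  for (i in seq_len(nrow(elements))) {
    ltr <- substring(sequence, elements$ltr5_start[i] + 1,
                     elements$ltr5_end[i])
    lk <- unique(c(seq_kmers(ltr, k), seq_kmers(revcomp(ltr), k)))
    hits <- which(km_all %in% lk)            # 1-based starts
    if (length(hits) == 0) next
    inside <- rep(FALSE, length(hits))
    for (j in seq_len(nrow(elements))) {
      inside <- inside | (hits - 1 >= elements$start[j] - k &
                          hits - 1 < elements$end[j])
    }
    hits <- hits[!inside]
    if (length(hits) == 0) next
    grp <- cumsum(c(TRUE, diff(hits) > anchor_gap))
    for (g in split(hits, grp)) {
      span_s <- min(g) - 1; span_e <- max(g) - 1 + k
      if (span_e - span_s >= 0.5 * min_ltr) {
        solo <- rbind(solo, data.frame(start = span_s, end = span_e,
                                       partner = elements$element_id[i],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(solo) > 1) {
    solo <- unique(solo)
    solo <- solo[order(solo$start), , drop = FALSE]
    rownames(solo) <- NULL
  }
  solo
}

#' Primer-binding-site motif catalog
#'
#' @param motifs named character vector (names are motif ids such as
#'   \code{"PBS4"}).
#' @param search_window bp scanned immediately 3' of the 5' LTR.
#' @return object of class \code{pbs_catalog}.
#' @export
pbs_catalog <- function(motifs, search_window = 30L) {
  stopifnot(length(motifs) > 0, !is.null(names(motifs)),
            !anyDuplicated(names(motifs)))
  structure(list(motifs = toupper(motifs),
                 search_window = as.integer(search_window)),
            class = "pbs_catalog")
}

#' Read a PBS motif catalog from a two-column text file
#'
#' Tab-separated \code{id<TAB>sequence}, \code{#} comments allowed. The
#' package ships a synthetic four-motif catalog (PBS1-PBS4) under
#' \code{inst/extdata/pbs_motifs_synthetic.txt}.
#'
#' @param path file path; defaults to the shipped catalog.
#' @param search_window see \code{\link{pbs_catalog}}.
#' @return a \code{pbs_catalog}.
#' @export
read_pbs_catalog <- function(path = system.file("extdata",
                                                "pbs_motifs_synthetic.txt",
                                                package = "centroscape"),
                             search_window = 30L) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  pbs_catalog(setNames(df[[2]], df[[1]]), search_window)
}

#' Detect the PBS motif of an element
#'
#' Scans the window immediately 3' of the 5' LTR for the best catalog
#' motif, allowing at most \code{max_mismatch} substitutions.
#'
#' @param element one row of an \code{ltr_scan} element table (or any list
#'   with \code{ltr5_end}).
#' @param sequence the sequence the element was annotated on.
#' @param catalog a \code{\link{pbs_catalog}}.
#' @param max_mismatch mismatch tolerance (default 1).
#' @param lead bp scanned before the called LTR end as well, absorbing
#'   small boundary jitter of de novo LTR calls (default 5).
#' @return the motif id, or \code{NA_character_} when nothing matches.
#' @export
detect_pbs <- function(element, sequence, catalog, max_mismatch = 1L,
                       lead = 5L) {
  stopifnot(inherits(catalog, "pbs_catalog"))
  if (is.null(element$ltr5_end) || is.na(element$ltr5_end))
    stop("element has no located 5' LTR")
  w <- catalog$search_window + lead
  maxlen <- max(nchar(catalog$motifs))
  region <- substring(sequence, max(1, element$ltr5_end + 1 - lead),
                      min(nchar(sequence), element$ltr5_end + w + maxlen))
  best <- NULL
  for (mi in seq_along(catalog$motifs)) {
    motif <- catalog$motifs[[mi]]
    ml <- nchar(motif)
    mraw <- charToRaw(motif)
    rraw <- charToRaw(region)
    nstart <- min(w, length(rraw) - ml + 1)
    if (nstart < 1) next
    for (s in seq_len(nstart)) {
      mm <- sum(rraw[s:(s + ml - 1)] != mraw)
      if (mm <= max_mismatch &&
          (is.null(best) || mm < best$mm)) {
        best <- list(id = names(catalog$motifs)[mi], mm = mm, pos = s)
      }
    }
  }
  if (is.null(best)) NA_character_ else best$id
}

#' Scan an internal sequence for retroelement protein domains
#'
#' Six-frame translation scored against short amino-acid consensus
#' profiles by local alignment (BLOSUM62, near-ungapped penalties). A
#' domain is called present when its best score reaches
#' \code{min_score_frac} of the profile self-score. Output is ordered by
#' genomic position; deviations from the canonical chromovirus order
#' (GAG, PRO, RT, RH, INT, CHD) are flagged.
#'
#' @param internal_sequence inter-LTR nucleotide sequence.
#' @param profiles named \code{AAStringSet} or character vector of domain
#'   consensi (see \code{\link{read_domain_profiles}}).
#' @param min_score_frac presence threshold as a fraction of self-score.
#' @return object of class \code{domain_scan}: \code{table} (per-domain
#'   best score, relative score, position, presence),
#'   \code{domains_present} (ordered by position), \code{order_ok},
#'   \code{flags} (includes \code{"too_short"} for inputs < 300 bp).
#' @export
scan_domains <- function(internal_sequence, profiles,
                         min_score_frac = 0.6) {
  prof <- setNames(as.character(profiles), names(profiles))
  stopifnot(length(prof) > 0, !is.null(names(prof)))
  doms <- names(prof)
  empty <- data.frame(domain = doms, present = FALSE, score = NA_real_,
                      rel_score = NA_real_, start = NA_real_,
                      end = NA_real_, strand = NA_character_,
                      stringsAsFactors = FALSE)
  n <- nchar(internal_sequence)
  if (n < 300) {
    return(structure(list(table = empty, domains_present = character(0),
                          order_ok = TRUE, flags = "too_short"),
                     class = "domain_scan"))
  }
  frames <- six_frame_translation(internal_sequence)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B62 <- get("BLOSUM62", envir = data_env)
  tab <- empty
  for (di in seq_along(prof)) {
    self <- Biostrings::score(Biostrings::pairwiseAlignment(
      prof[[di]], prof[[di]], type = "local", substitutionMatrix = B62,
      gapOpening = 12, gapExtension = 4))
    best <- NULL
    for (f in frames) {
      if (nchar(f$aa) < 5) next
      aln <- Biostrings::pairwiseAlignment(
        prof[[di]], f$aa, type = "local", substitutionMatrix = B62,
        gapOpening = 12, gapExtension = 4)
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$sc) {
        aa_s <- BiocGenerics::start(Biostrings::subject(aln)) - 1
        aa_e <- BiocGenerics::end(Biostrings::subject(aln))
        if (f$strand == "+") {
          g_s <- f$offset + 3 * aa_s
          g_e <- f$offset + 3 * aa_e
        } else {
          g_e <- n - (f$offset + 3 * aa_s)
          g_s <- n - (f$offset + 3 * aa_e)
        }
        best <- list(sc = sc, start = g_s, end = g_e, strand = f$strand)
      }
    }
    tab$score[di] <- best$sc
    tab$rel_score[di] <- best$sc / self
    tab$start[di] <- best$start
    tab$end[di] <- best$end
    tab$strand[di] <- best$strand
    tab$present[di] <- best$sc >= min_score_frac * self
  }
  pres <- tab[tab$present, , drop = FALSE]
  pres <- pres[order(pres$start), , drop = FALSE]
  canonical <- DOMAIN_ORDER[DOMAIN_ORDER %in% pres$domain]
  order_ok <- identical(pres$domain, canonical)
  structure(list(table = tab, domains_present = pres$domain,
                 order_ok = order_ok,
                 flags = if (order_ok) character(0) else "order_violation"),
            class = "domain_scan")
}

six_frame_translation <- function(sequence) {
  out <- list()
  for (strand in c("+", "-")) {
    sq <- if (strand == "+") sequence else revcomp(sequence)
    for (off in 0:2) {
      len <- nchar(sq) - off
      len <- len - (len %% 3)
      if (len < 3) next
      dna <- Biostrings::DNAString(substring(sq, off + 1, off + len))
      aa <- as.character(suppressWarnings(Biostrings::translate(dna)))
      out[[length(out) + 1L]] <- list(aa = aa, strand = strand, offset = off)
    }
  }
  out
}

#' Read retroelement protein-domain profiles
#'
#' The package ships synthetic amino-acid consensus profiles for the six
#' chromovirus domains (GAG, PRO, RT, RH, INT, CHD) as
#' \code{inst/extdata/crm_domain_profiles_synthetic.faa}; these are
#' fixtures for planted-truth testing, not biological consensi.
#'
#' @param path FASTA of amino-acid profiles (one per domain).
#' @return named character vector of profiles.
#' @export
read_domain_profiles <- function(path = system.file(
  "extdata", "crm_domain_profiles_synthetic.faa", package = "centroscape")) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Classify retroelement autonomy from domain content
#'
#' All six chromovirus domains present: autonomous. Missing exactly the
#' enzymatic core RT, RH and INT: dominant nonautonomous. Missing the core
#' plus at least one further domain: minor nonautonomous. Any other
#' pattern (e.g. missing INT only): unclassified.
#'
#' @param domains_present character vector, subset of
#'   \code{c("GAG", "PRO", "RT", "RH", "INT", "CHD")}.
#' @return one of \code{"autonomous"}, \code{"nonautonomous_dominant"},
#'   \code{"nonautonomous_minor"}, \code{"unclassified"}.
#' @export
classify_autonomy <- function(domains_present) {
  stopifnot(all(domains_present %in% DOMAIN_ORDER))
  missing <- setdiff(DOMAIN_ORDER, domains_present)
  core <- c("RT", "RH", "INT")
  if (length(missing) == 0) return("autonomous")
  if (setequal(missing, core)) return("nonautonomous_dominant")
  if (all(core %in% missing)) return("nonautonomous_minor")
  "unclassified"
}

#' Insertion-age model
#'
#' @param rate substitution rate per site per year (default
#'   \code{6.1e-9}, a synonymous rate appropriate for hop).
#' @param correction divergence correction: \code{"kimura2p"} (default),
#'   \code{"jukes_cantor"} or \code{"raw"}.
#' @return object of class \code{age_model}.
#' @export
age_model <- function(rate = 6.1e-9,
                      correction = c("kimura2p", "jukes_cantor", "raw")) {
  stopifnot(rate > 0)
  structure(list(rate = rate, correction = match.arg(correction)),
            class = "age_model")
}

#' Estimate retroelement insertion age from LTR divergence
#'
#' The two LTRs of an element are identical at insertion and diverge
#' neutrally afterwards, so the age is \code{K / (2 * rate)} where \code{K}
#' is the corrected substitutions/site between the aligned LTR copies.
#' Raw divergence is the mismatch fraction over aligned non-gap columns;
#' Jukes-Cantor and Kimura two-parameter corrections inflate it for
#' multiple hits. Pairs aligning below 60 percent identity are flagged
#' unreliable and the age is withheld.
#'
#' @param ltr5_seq,ltr3_seq the two LTR sequences (>= 50 bp each).
#' @param model an \code{\link{age_model}}.
#' @return list: \code{d_raw}, \code{K}, \code{age_years}, \code{age_ma},
#'   \code{identity} (alignment percent identity), \code{sites},
#'   \code{correction}, \code{flags}.
#' @export
estimate_insertion_age <- function(ltr5_seq, ltr3_seq,
                                   model = age_model()) {
  stopifnot(inherits(model, "age_model"),
            nchar(ltr5_seq) >= 50, nchar(ltr3_seq) >= 50)
  aln <- align_nt(ltr5_seq, ltr3_seq, type = "global")
  ident <- alignment_identity(aln)
  div <- alignment_divergence(aln)
  if (ident < 60) {
    return(list(d_raw = div$d, K = NA_real_, age_years = NA_real_,
                age_ma = NA_real_, identity = ident, sites = div$sites,
                correction = model$correction, flags = "unreliable_pair"))
  }
  K <- divergence_correct(div, model$correction)
  flags <- character(0)
  if (is.na(K)) flags <- "saturated"
  age <- K / (2 * model$rate)
  list(d_raw = div$d, K = K, age_years = age, age_ma = age / 1e6,
       identity = ident, sites = div$sites,
       correction = model$correction, flags = flags)
}

divergence_correct <- function(div, correction) {
  switch(correction,
    raw = div$d,
    jukes_cantor = {
      a <- 1 - 4 * div$d / 3
      if (a <= 0) NA_real_ else -0.75 * log(a)
    },
    kimura2p = {
      a <- 1 - 2 * div$P - div$Q
      b <- 1 - 2 * div$Q
      if (a <= 0 || b <= 0) NA_real_ else -0.5 * log(a * sqrt(b))
    })
}

#' Summarize PBS detection by autonomy class and motif
#'
#' Builds the autonomy x motif contingency table, the overall PBS
#' detection percentage (detected / total x 100, one decimal) and the
#' fraction of PBS-bearing elements that fall in the four most frequent
#' motif groups.
#'
#' @param elements data frame with columns \code{autonomy} and \code{pbs}
#'   (\code{NA} = no motif detected).
#' @return list: \code{table} (autonomy x motif counts, \code{"none"}
#'   column for undetected), \code{total}, \code{detected},
#'   \code{detected_pct}, \code{top4_motifs}, \code{top4_count},
#'   \code{top4_pct}.
#' @export
summarize_pbs_groups <- function(elements) {
  if (is.null(elements) || nrow(elements) == 0) {
    return(list(table = table(character(0), character(0)), total = 0L,
                detected = 0L, detected_pct = 0,
                top4_motifs = character(0), top4_count = 0L,
                top4_pct = NA_real_))
  }
  motif <- ifelse(is.na(elements$pbs), "none", elements$pbs)
  tab <- table(elements$autonomy, motif)
  total <- nrow(elements)
  detected <- sum(!is.na(elements$pbs))
  detected_pct <- round(100 * detected / total, 1)
  if (detected > 0) {
    mt <- sort(table(elements$pbs[!is.na(elements$pbs)]), decreasing = TRUE)
    top <- head(mt, 4)
    top4_pct <- round(100 * sum(top) / detected, 1)
    top4 <- names(top)
    top_count <- sum(top)
  } else {
    top4 <- character(0); top4_pct <- 0; top_count <- 0L
  }
  list(table = tab, total = total, detected = detected,
       detected_pct = detected_pct, top4_motifs = top4,
       top4_count = top_count, top4_pct = top4_pct)
}

#' Locate a repeat consensus within element LTRs
#'
#' Local alignment of the consensus (both strands) against each LTR of
#' each element; hits of at least \code{min_len} aligned columns at
#' \code{min_identity} percent identity are reported, along with the
#' fraction of elements carrying at least one hit (the statistic used to
#' ask whether a centromeric satellite is embedded in the LTRs of a
#' retroelement family).
#'
#' @param elements element table from \code{\link{find_ltr_elements}} (or
#'   a compatible data frame).
#' @param sequence the annotated sequence.
#' @param consensus repeat consensus to search for.
#' @param min_identity percent identity threshold (default 80).
#' @param min_len minimum aligned columns (default 30).
#' @return list: \code{hits} (data frame: \code{element_id}, \code{ltr},
#'   0-based \code{start}, \code{end} on the sequence, \code{identity},
#'   \code{strand}), \code{fraction_with_hit}.
#' @export
locate_repeat_in_ltr <- function(elements, sequence, consensus,
                                 min_identity = 80, min_len = 30) {
  if (inherits(elements, "ltr_scan")) elements <- elements$elements
  rows <- list(); carriers <- logical(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    for (side in c("ltr5", "ltr3")) {
      s <- elements[[paste0(side, "_start")]][i]
      e <- elements[[paste0(side, "_end")]][i]
      ltr <- substring(sequence, s + 1, e)
      hit <- best_local_hit(consensus, ltr, min_identity, min_len)
      if (!is.null(hit)) {
        carriers[i] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = elements$element_id[i], ltr = side,
          start = s + hit$start, end = s + hit$end,
          identity = hit$identity, strand = hit$strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(element_id = character(0), ltr = character(0),
               start = numeric(0), end = numeric(0),
               identity = numeric(0), strand = character(0),
               stringsAsFactors = FALSE)
  list(hits = hits,
       fraction_with_hit = if (nrow(elements)) mean(carriers) else NA_real_)
}

#' Annotate a scanned element set with PBS, domains, autonomy and age
#'
#' Convenience wrapper running \code{\link{detect_pbs}},
#' \code{\link{scan_domains}}, \code{\link{classify_autonomy}} and
#' \code{\link{estimate_insertion_age}} over every element of an
#' \code{ltr_scan}.
#'
#' @param scan an \code{\link{find_ltr_elements}} result.
#' @param sequence the scanned sequence.
#' @param catalog a \code{\link{pbs_catalog}}.
#' @param profiles domain profiles (see \code{\link{read_domain_profiles}}).
#' @param model an \code{\link{age_model}}.
#' @return list: \code{elements} (the element table extended with
#'   \code{pbs}, \code{domains}, \code{autonomy}, \code{ltr_divergence_K},
#'   \code{age_ma}), \code{domain_hits} (per-element coding intervals,
#'   0-based on \code{sequence}).
#' @export
annotate_elements <- function(scan, sequence, catalog, profiles,
                              model = age_model()) {
  el <- scan$elements
  el$pbs <- NA_character_
  el$domains <- ""
  el$autonomy <- NA_character_
  el$ltr_divergence_K <- NA_real_
  el$age_ma <- NA_real_
  dom_rows <- list()
  for (i in seq_len(nrow(el))) {
    el$pbs[i] <- detect_pbs(el[i, ], sequence, catalog)
    int_s <- el$ltr5_end[i]; int_e <- el$ltr3_start[i]
    internal <- substring(sequence, int_s + 1, int_e)
    ds <- scan_domains(internal, profiles)
    el$domains[i] <- paste(ds$domains_present, collapse = ",")
    el$autonomy[i] <- classify_autonomy(ds$domains_present)
    pres <- ds$table[ds$table$present, , drop = FALSE]
    if (nrow(pres)) {
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        element_id = el$element_id[i], domain = pres$domain,
        start = int_s + pres$start, end = int_s + pres$end,
        stringsAsFactors = FALSE)
    }
    age <- estimate_insertion_age(
      substring(sequence, el$ltr5_start[i] + 1, el$ltr5_end[i]),
      substring(sequence, el$ltr3_start[i] + 1, el$ltr3_end[i]),
      model)
    el$ltr_divergence_K[i] <- age$K
    el$age_ma[i] <- age$age_ma
  }
  list(elements = el,
       domain_hits = if (length(dom_rows)) do.call(rbind, dom_rows) else NULL)
}

#' Published CRM PBS survey expanded to element level
#'
#' Reads the shipped autonomy x PBS-motif count table (class marginals from
#' the published hop CRM survey; per-motif split synthetic but
#' marginal-consistent) and expands it to one row per element, the input
#' shape of \code{\link{summarize_pbs_groups}}.
#'
#' @return data frame with columns \code{autonomy} and \code{pbs}
#'   (\code{NA} where no motif was detected).
#' @export
crm_pbs_survey <- function() {
  df <- read.delim(system.file("extdata", "crm_pbs_survey_synthetic.tsv",
                               package = "centroscape"),
                   comment.char = "#", stringsAsFactors = FALSE)
  data.frame(
    autonomy = rep(df$autonomy, df$count),
    pbs = rep(ifelse(df$pbs == "none", NA_character_, df$pbs), df$count),
    stringsAsFactors = FALSE)
}
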