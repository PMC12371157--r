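#' Planted tandem satellite array
#'
#' Describes one satellite array to be planted into a simulated chromosome:
#' \code{copies} copies of \code{monomer}, each independently mutated at
#' \code{per_base_mutation} substitutions per base. With \code{indel_rate = 0}
#' (the default) the planted span is exactly \code{copies * nchar(monomer)}
#' bases long.
#'
#' @param family_id character label of the satellite family.
#' @param monomer monomer sequence (ACGT string).
#' @param copies number of tandem copies (>= 1).
#' @param start 0-based start offset of the array on the chromosome.
#' @param per_base_mutation substitution probability per base and copy.
#' @param indel_rate optional single-base indel probability (default 0;
#'   divergence bookkeeping assumes substitution-dominated decay).
#' @return An object of class \code{array_plant}.
#' @export
array_plant <- function(family_id, monomer, copies, start,
                        per_base_mutation = 0, indel_rate = 0) {
  stopifnot(is.character(family_id), nchar(monomer) > 0, copies >= 1,
            start >= 0, per_base_mutation >= 0, per_base_mutation < 1,
            indel_rate >= 0)
  structure(list(family_id = family_id, monomer = toupper(monomer),
                 copies = as.integer(copies), start = as.numeric(start),
                 per_base_mutation = per_base_mutation,
                 indel_rate = indel_rate),
            class = "array_plant")
}

#' Planted LTR retroelement
#'
#' Describes one LTR retroelement to be planted. The emitted structure is
#' \code{TSD + 5'LTR + PBS + internal + 3'LTR + TSD}; the 3' LTR copy is
#' mutated at \code{target_divergence} substitutions per site relative to the
#' 5' copy, emulating post-insertion decay. The realized divergence is
#' recorded in the truth output.
#'
#' @param element_id character label.
#' @param ltr_seq LTR sequence shared by both copies at insertion.
#' @param internal_seq internal (inter-LTR) sequence.
#' @param start 0-based start of the 5' TSD copy on the chromosome.
#' @param target_divergence substitutions/site applied between LTR copies.
#' @param tsd 4-6 bp target-site duplication sequence.
#' @param pbs_motif primer-binding-site motif placed immediately 3' of the
#'   5' LTR, or \code{NULL} for none.
#' @param autonomy one of \code{"autonomous"}, \code{"nonautonomous_dominant"},
#'   \code{"nonautonomous_minor"} (a truth label; the internal sequence
#'   content is the caller's responsibility, see \code{\link{make_crm_internal}}).
#' @param domain_intervals optional data frame (\code{domain}, \code{start},
#'   \code{end}; 0-based, relative to \code{internal_seq}) recording planted
#'   protein-domain positions.
#' @return An object of class \code{element_plant}.
#' @export
element_plant <- function(element_id, ltr_seq, internal_seq, start,
                          target_divergence = 0, tsd = "ACGTA",
                          pbs_motif = NULL,
                          autonomy = c("autonomous", "nonautonomous_dominant",
                                       "nonautonomous_minor"),
                          domain_intervals = NULL) {
  autonomy <- match.arg(autonomy)
  stopifnot(nchar(ltr_seq) > 0, nchar(internal_seq) > 0, start >= 0,
            target_divergence >= 0, target_divergence < 1,
            nchar(tsd) >= 4, nchar(tsd) <= 6)
  structure(list(element_id = element_id, ltr_seq = toupper(ltr_seq),
                 internal_seq = toupper(internal_seq),
                 start = as.numeric(start),
                 target_divergence = target_divergence,
                 tsd = toupper(tsd),
                 pbs_motif = if (is.null(pbs_motif)) NULL else toupper(pbs_motif),
                 autonomy = autonomy,
                 domain_intervals = domain_intervals),
            class = "element_plant")
}

plant_width <- function(p) {
  if (inherits(p, "array_plant")) return(p$copies * nchar(p$monomer))
  2 * nchar(p$tsd) + 2 * nchar(p$ltr_seq) +
    nchar(p$pbs_motif %||% "") + nchar(p$internal_seq)
}

plant_id <- function(p) if (inherits(p, "array_plant")) p$family_id else p$element_id

#' Chromosome specification for the genome simulator
#'
#' @param name chromosome name.
#' @param length chromosome length in bp.
#' @param centromere_center 0-based position of the (single) centromere
#'   midpoint, or \code{NA} for an acentric background chromosome.
#' @param satellite_plants list of \code{\link{array_plant}} objects.
#' @param element_plants list of \code{\link{element_plant}} objects.
#' @return An object of class \code{chrom_spec}.
#' @export
chrom_spec <- function(name, length, centromere_center = NA,
                       satellite_plants = list(), element_plants = list()) {
  stopifnot(is.character(name), length > 0)
  plants <- c(satellite_plants, element_plants)
  for (p in plants) {
    w <- plant_width(p)
    if (p$start < 0 || p$start + w > length)
      stop(sprintf("plant '%s' [%d, %d) lies outside chromosome '%s' (length %d)",
                   plant_id(p), p$start, p$start + w, name, length))
  }
  if (length(plants) > 1) {
    st <- vapply(plants, function(p) p$start, numeric(1))
    en <- st + vapply(plants, plant_width, numeric(1))
    o <- order(st)
    for (i in seq_len(length(plants) - 1)) {
      a <- o[i]; b <- o[i + 1]
      if (en[a] > st[b])
        stop(sprintf("planted features '%s' and '%s' overlap on chromosome '%s'",
                     plant_id(plants[[a]]), plant_id(plants[[b]]), name))
    }
  }
  structure(list(name = name, length = as.numeric(length),
                 centromere_center = centromere_center,
                 satellite_plants = satellite_plants,
                 element_plants = element_plants),
            class = "chrom_spec")
}

#' Genome specification
#'
#' @param chromosomes list of \code{\link{chrom_spec}} objects.
#' @param seed integer seed; fully determines all simulator output.
#' @param gc_background GC fraction of the i.i.d. background sequence.
#' @return An object of class \code{genome_spec}.
#' @export
genome_spec <- function(chromosomes, seed = 1L, gc_background = 0.4) {
  stopifnot(length(chromosomes) >= 1,
            all(vapply(chromosomes, inherits, logical(1), "chrom_spec")),
            gc_background >= 0, gc_background <= 1)
  nm <- vapply(chromosomes, function(x) x$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate chromosome names")
  structure(list(chromosomes = chromosomes, seed = as.integer(seed),
                 gc_background = gc_background),
            class = "genome_spec")
}

#' Read-simulation specification
#'
#' The input channel draws read start positions uniformly over each
#' chromosome; the ChIP channel draws them with relative weight
#' \code{chip_fold} inside \code{centromere_center +/- chip_halfwidth} and 1
#' elsewhere, emulating a CENH3 ChIP experiment against an input control.
#'
#' @param read_length read length in bp.
#' @param input_depth mean fold-coverage per channel.
#' @param chip_fold enrichment multiplier over the centromeric interval
#'   (>= 1).
#' @param chip_halfwidth half-width of the enriched interval in bp.
#' @param seed integer seed for the read simulator.
#' @return An object of class \code{read_sim_spec}.
#' @export
read_sim_spec <- function(read_length = 150L, input_depth = 20,
                          chip_fold = 20, chip_halfwidth = 50000,
                          seed = 1L) {
  if (chip_fold < 1) stop("chip_fold must be >= 1")
  stopifnot(read_length >= 1, input_depth > 0, chip_halfwidth >= 0)
  structure(list(read_length = as.integer(read_length),
                 input_depth = input_depth, chip_fold = chip_fold,
                 chip_halfwidth = as.numeric(chip_halfwidth),
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}
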