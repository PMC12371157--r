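# Bundled demo fixtures: a deterministic synthetic repeat library and a
# two-chromosome genome spec with one type-1 and one type-2 centromere.
# All sequences are synthetic stand-ins generated from the seed; monomer
# lengths (284, 323 bp) follow the published hop satellite survey.

#' Demo repeat consensus library
#'
#' Three families: \code{cen284} (the 284-bp major centromeric satellite
#' stand-in), \code{sat323} (a 323-bp accessory, chromosome-specific
#' satellite stand-in) and \code{crm} (a CRM-like Ty3/Gypsy retroelement
#' consensus whose LTR embeds one full \code{cen284} monomer, mirroring the
#' satellite-in-LTR architecture of centrophilic CRMs).
#'
#' @param seed integer seed; the same seed always yields the same library.
#' @return list: \code{library} (a \code{\link{repeat_library}}),
#'   \code{parts} (the building blocks: \code{cen_monomer},
#'   \code{acc_monomer}, \code{crm_ltr}, \code{crm_internal},
#'   \code{crm_domain_intervals}).
#' @export
demo_repeat_library <- function(seed = 100L) {
  profiles <- read_domain_profiles()
  set.seed(derive_seed(seed, 901))
  cen <- random_dna(284, gc = 0.42)
  acc <- random_dna(323, gc = 0.38)
  ltr <- paste0(random_dna(400, gc = 0.4), cen, random_dna(500, gc = 0.4))
  internal <- make_crm_internal(profiles, DOMAIN_ORDER, spacer_len = 150)
  crm <- paste0(ltr, internal$seq, ltr)
  lib <- repeat_library(
    id = c("cen284", "crm", "sat323"),
    class = c("satellite", "TE", "satellite"),
    sequence = c(cen, crm, acc),
    monomer_length = c("284", "variable", "323"))
  list(library = lib,
       parts = list(cen_monomer = cen, acc_monomer = acc, crm_ltr = ltr,
                    crm_internal = internal$seq,
                    crm_domain_intervals = internal$domain_intervals))
}

# one CRM-like element plant; autonomy decides which domains the internal
# sequence actually encodes
demo_crm_plant <- function(id, start, parts, profiles, autonomy, pbs,
                           divergence, tsd) {
  domains <- switch(autonomy,
                    autonomous = DOMAIN_ORDER,
                    nonautonomous_dominant = c("GAG", "PRO", "CHD"),
                    nonautonomous_minor = c("PRO", "CHD"))
  internal <- make_crm_internal(profiles, domains, spacer_len = 150)
  element_plant(id, ltr_seq = parts$crm_ltr, internal_seq = internal$seq,
                start = start, target_divergence = divergence, tsd = tsd,
                pbs_motif = pbs, autonomy = autonomy,
                domain_intervals = internal$domain_intervals)
}

#' Demo genome specification
#'
#' Two 400-kb chromosomes, each with a single centromere at 200 kb:
#' \code{chrA} is a type-1 centromere (major satellite array plus three
#' CRM-like elements), \code{chrB} a type-2 centromere that additionally
#' carries a large accessory \code{sat323} array (about 8 percent of the
#' chromosome). Element LTR divergences span 0.002-0.012
#' (insertion ages 0.16-0.98 Ma at the default rate); PBS4 is the most
#' frequent motif among the nonautonomous elements.
#'
#' @param seed integer seed.
#' @return list: \code{spec} (a \code{\link{genome_spec}}), \code{library}
#'   (the matching \code{\link{demo_repeat_library}} output).
#' @export
demo_genome_spec <- function(seed = 1L) {
  demo <- demo_repeat_library(seed)
  parts <- demo$parts
  profiles <- read_domain_profiles()
  catalog <- read_pbs_catalog()
  p1 <- catalog$motifs[["PBS1"]]; p2 <- catalog$motifs[["PBS2"]]
  p4 <- catalog$motifs[["PBS4"]]

  set.seed(derive_seed(seed, 902))
  chrA <- chrom_spec(
    "chrA", 400000, centromere_center = 200000,
    satellite_plants = list(
      array_plant("cen284", parts$cen_monomer, copies = 60, start = 180000,
                  per_base_mutation = 0.02)),
    element_plants = list(
      demo_crm_plant("crmA1", 200000, parts, profiles, "autonomous",
                     p1, 0.004, "ACGTA"),
      demo_crm_plant("crmA2", 208000, parts, profiles,
                     "nonautonomous_dominant", p4, 0.010, "TTAAC"),
      demo_crm_plant("crmA3", 216000, parts, profiles, "autonomous",
                     p2, 0.002, "GGATC")))
  chrB <- chrom_spec(
    "chrB", 400000, centromere_center = 200000,
    satellite_plants = list(
      array_plant("cen284", parts$cen_monomer, copies = 40, start = 176000,
                  per_base_mutation = 0.02),
      array_plant("sat323", parts$acc_monomer, copies = 100, start = 190000,
                  per_base_mutation = 0.02)),
    element_plants = list(
      demo_crm_plant("crmB1", 224000, parts, profiles,
                     "nonautonomous_dominant", p4, 0.012, "CATGG"),
      demo_crm_plant("crmB2", 232000, parts, profiles, "autonomous",
                     p1, 0.006, "ACGTA")))
  list(spec = genome_spec(list(chrA, chrB), seed = seed),
       library = demo$library, parts = parts)
}
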