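test_that("repeat-free background yields no elements across 20 seeds", {
  fp <- 0
  for (s in 1:20) {
    set.seed(s)
    fp <- fp + nrow(find_ltr_elements(rnd_dna(30000))$elements)
  }
  expect_equal(fp, 0)
})

test_that("a zero-divergence planted element is recovered at exact coordinates with its TSD and PBS", {
  set.seed(104)
  ltr <- rnd_dna(800); internal <- rnd_dna(3000)
  ep <- element_plant("e1", ltr, internal, start = 20000,
                      target_divergence = 0, tsd = "ACGTA",
                      pbs_motif = "TGGCACCAGTTCAA")
  g <- simulate_genome(genome_spec(list(
    chrom_spec("c1", 60000, 30000, element_plants = list(ep))), seed = 4))
  el <- find_ltr_elements(g$sequences[["c1"]])$elements
  tr <- g$truth$elements
  expect_equal(nrow(el), 1)
  expect_equal(el$start, tr$start)
  expect_equal(el$end, tr$end)
  expect_identical(el$tsd, "ACGTA")
  expect_true(el$has_tsd)
  expect_equal(el$ltr_identity, 100)
  expect_identical(detect_pbs(el[1, ], g$sequences[["c1"]],
                              read_pbs_catalog()), "PBS4")
})

test_that("a solo LTR is excluded from the element list but present in the solo report", {
  set.seed(31)
  ltr <- rnd_dna(600); internal <- rnd_dna(2500)
  emitted <- paste0("ACGTA", ltr, "TGGTATCAGAGCCA", internal, ltr, "ACGTA")
  sq <- paste0(rnd_dna(3000), emitted, rnd_dna(30000), ltr, rnd_dna(3000))
  scan <- find_ltr_elements(sq)
  expect_equal(nrow(scan$elements), 1)
  solo_start <- 3000 + nchar(emitted) + 30000
  expect_true(any(scan$solo$start >= solo_start - 50 &
                  scan$solo$end <= solo_start + 650))
  # the solo copy does not appear as an element
  expect_false(any(scan$elements$start > solo_start - 700))
})

test_that("a 20-element cohort is structurally recovered (>=95% within 5 bp, no false calls)", {
  g <- make_element_cohort(20, seed = 77)
  scan <- find_ltr_elements(g$sequences[["cohort"]])
  el <- scan$elements
  tt <- g$truth$elements
  expect_equal(nrow(el), 20)               # no false elements either
  hit <- vapply(seq_len(nrow(tt)), function(j)
    any(abs(el$start - tt$start[j]) <= 5 & abs(el$end - tt$end[j]) <= 5),
    logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("PBS detection allows one mismatch, reports none cleanly, and needs a located 5' LTR", {
  catalog <- read_pbs_catalog()
  set.seed(32)
  ltr_end <- 500
  motif <- catalog$motifs[["PBS2"]]
  mk <- function(m) paste0(rnd_dna(ltr_end), m, rnd_dna(100))
  el <- list(ltr5_end = ltr_end)
  expect_identical(detect_pbs(el, mk(motif), catalog), "PBS2")
  mut <- motif
  substr(mut, 7, 7) <- ifelse(substr(mut, 7, 7) == "A", "C", "A")
  expect_identical(detect_pbs(el, mk(mut), catalog), "PBS2")
  expect_true(is.na(detect_pbs(el, mk(rnd_dna(14)), catalog)))
  expect_error(detect_pbs(list(ltr5_end = NA), "ACGT", catalog), "5' LTR")
})

test_that("detected PBS fraction over a cohort equals the planted fraction", {
  g <- make_element_cohort(10, seed = 55, max_divergence = 0.01)
  # strip the motif from half the elements by planting a second cohort
  # without PBS on the same geometry
  g2 <- make_element_cohort(10, seed = 56, max_divergence = 0.01,
                            pbs = NULL)
  catalog <- read_pbs_catalog()
  frac_of <- function(g) {
    el <- find_ltr_elements(g$sequences[["cohort"]])$elements
    mean(vapply(seq_len(nrow(el)), function(i)
      !is.na(detect_pbs(el[i, ], g$sequences[["cohort"]], catalog)),
      logical(1)))
  }
  expect_equal(frac_of(g), 1)
  expect_equal(frac_of(g2), 0)
})

test_that("domain scanning recovers planted domain sets in canonical order and stays silent on noise", {
  prof <- read_domain_profiles()
  set.seed(3)
  full <- make_crm_internal(prof)
  ds <- scan_domains(full$seq, prof)
  expect_equal(ds$domains_present, c("GAG", "PRO", "RT", "RH", "INT", "CHD"))
  expect_true(ds$order_ok)
  part <- make_crm_internal(prof, c("GAG", "PRO", "CHD"))
  expect_equal(scan_domains(part$seq, prof)$domains_present,
               c("GAG", "PRO", "CHD"))
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    hits <- hits + length(scan_domains(rnd_dna(2000), prof)$domains_present)
  }
  expect_equal(hits, 0)
  short <- scan_domains(rnd_dna(100), prof)
  expect_true("too_short" %in% short$flags)
  expect_equal(length(short$domains_present), 0)
})

test_that("autonomy classification follows the domain-content rules and partitions all patterns", {
  expect_equal(classify_autonomy(c("GAG", "PRO", "RT", "RH", "INT", "CHD")),
               "autonomous")
  expect_equal(classify_autonomy(c("GAG", "PRO", "CHD")),
               "nonautonomous_dominant")
  expect_equal(classify_autonomy(c("PRO", "CHD")), "nonautonomous_minor")
  expect_equal(classify_autonomy(c("GAG", "PRO", "RT", "RH", "CHD")),
               "unclassified")
  # every one of the 64 domain subsets gets exactly one of the four labels
  doms <- c("GAG", "PRO", "RT", "RH", "INT", "CHD")
  labels <- vapply(0:63, function(m) {
    classify_autonomy(doms[bitwAnd(m, 2^(0:5)) > 0])
  }, character(1))
  expect_true(all(labels %in% c("autonomous", "nonautonomous_dominant",
                                "nonautonomous_minor", "unclassified")))
  expect_equal(sum(labels == "autonomous"), 1)
  expect_equal(sum(labels == "nonautonomous_dominant"), 1)
  expect_equal(sum(labels == "nonautonomous_minor"), 7)
})

test_that("insertion ages follow K/(2*rate): zero for identical LTRs, 1.0 Ma at K = 0.0122", {
  set.seed(33)
  a <- rnd_dna(500)
  z <- estimate_insertion_age(a, a)
  expect_equal(z$K, 0)
  expect_equal(z$age_years, 0)
  # plant exactly 61 substitutions in 5000 bp -> raw divergence 0.0122
  b <- rnd_dna(5000)
  v <- strsplit(b, "")[[1]]
  idx <- sample(5000, 61)
  for (i in idx) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  ag <- estimate_insertion_age(b, paste(v, collapse = ""),
                               age_model(correction = "raw"))
  expect_equal(ag$d_raw, 0.0122)
  expect_equal(ag$age_ma, 1.0)
  expect_equal(ag$age_years, 0.0122 / (2 * 6.1e-9))
})

test_that("planted LTR divergence is dated within 15 percent at 2-kb LTRs", {
  set.seed(35)
  ltr <- rnd_dna(2000)
  ep <- element_plant("e", ltr, rnd_dna(2500), start = 5000,
                      target_divergence = 0.006, tsd = "CATTG",
                      pbs_motif = "TGGTATCAGAGCCA")
  g <- simulate_genome(genome_spec(list(
    chrom_spec("c", 20000, element_plants = list(ep))), seed = 12))
  tr <- g$truth$elements
  sq <- g$sequences[["c"]]
  el <- find_ltr_elements(sq)$elements
  ag <- estimate_insertion_age(substring(sq, el$ltr5_start + 1, el$ltr5_end),
                               substring(sq, el$ltr3_start + 1, el$ltr3_end))
  target_age <- 0.006 / (2 * 6.1e-9) / 1e6
  expect_lt(abs(ag$age_ma - target_age) / target_age, 0.15)
  # the estimate always tracks the realized divergence closely
  expect_lt(abs(ag$d_raw - tr$realized_divergence), 0.002)
})

test_that("age is monotone in divergence, scales inversely with rate, and corrections order K2P >= JC >= raw", {
  set.seed(36)
  base <- rnd_dna(1000)
  ages <- vapply(c(5, 20, 60), function(k) {
    v <- strsplit(base, "")[[1]]
    for (i in sample(1000, k)) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
    estimate_insertion_age(base, paste(v, collapse = ""))$age_years
  }, numeric(1))
  expect_true(all(diff(ages) > 0))
  m <- centroscape:::mutate_dna(base, 0.02)$seq
  a1 <- estimate_insertion_age(base, m, age_model(rate = 6.1e-9))
  a2 <- estimate_insertion_age(base, m, age_model(rate = 6.1e-9 / 2))
  expect_equal(a2$age_years, 2 * a1$age_years)
  ok <- TRUE
  for (s in 1:100) {
    set.seed(s)
    a <- rnd_dna(300)
    b <- centroscape:::mutate_dna(a, stats::runif(1, 0.01, 0.3))$seq
    K <- vapply(c("raw", "jukes_cantor", "kimura2p"), function(cc)
      estimate_insertion_age(a, b, age_model(correction = cc))$K, numeric(1))
    if (is.unsorted(K + c(0, 1e-12, 2e-12))) ok <- FALSE
  }
  expect_true(ok)
  # dissimilar pairs are flagged and age is withheld
  u <- estimate_insertion_age(rnd_dna(200), rnd_dna(200))
  expect_true("unreliable_pair" %in% u$flags)
  expect_true(is.na(u$age_years))
})

test_that("PBS bookkeeping reproduces the published survey percentages", {
  sv <- crm_pbs_survey()
  s <- summarize_pbs_groups(sv)
  expect_equal(s$total, 671L)
  expect_equal(s$detected, 543L)
  expect_equal(s$detected_pct, 80.9)
  expect_equal(s$top4_count, 449L)
  expect_equal(s$top4_pct, 82.7)
  expect_true("PBS4" %in% s$top4_motifs)
  none <- summarize_pbs_groups(data.frame(autonomy = "autonomous",
                                          pbs = NA_character_))
  expect_equal(none$detected_pct, 0)
  empty <- summarize_pbs_groups(NULL)
  expect_equal(empty$total, 0L)
})

test_that("a repeat embedded in element LTRs is located and the carrier fraction recovered", {
  set.seed(40)
  mono <- rnd_dna(284)
  ltr_with <- paste0(rnd_dna(300), mono, rnd_dna(300))
  ltr_without <- rnd_dna(884)
  plants <- list(); pos <- 2000
  carries <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2)   # 8/10 carriers
  carries <- carries[1:10]
  for (i in 1:10) {
    plants[[i]] <- element_plant(
      sprintf("e%d", i), if (carries[i]) ltr_with else ltr_without,
      rnd_dna(2000), start = pos, target_divergence = 0.01,
      tsd = "ACGT", pbs_motif = "TGGTATCAGAGCCA")
    pos <- pos + centroscape:::plant_width(plants[[i]]) + 2500
  }
  g <- simulate_genome(genome_spec(list(
    chrom_spec("c", pos + 2000, element_plants = plants)), seed = 13))
  sq <- g$sequences[["c"]]
  el <- find_ltr_elements(sq)$elements
  res <- locate_repeat_in_ltr(el, sq, mono)
  expect_lte(abs(res$fraction_with_hit - mean(carries)), 0.02)
  # hits land at the planted offset inside both LTRs of a carrier
  first <- el[order(el$start), ][1, ]
  h <- res$hits[res$hits$element_id == first$element_id, ]
  expect_equal(nrow(h), 2)
  expect_lte(abs(h$start[1] - (first$ltr5_start + 300)), 5)
  # absent consensus -> no hits
  none <- locate_repeat_in_ltr(el, sq, rnd_dna(284))
  expect_equal(nrow(none$hits), 0)
})
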