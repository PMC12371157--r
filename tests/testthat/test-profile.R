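test_that("a pure planted array is masked almost completely as its own family", {
  set.seed(8)
  mono <- rnd_dna(284)
  g <- make_array_genome(mono, copies = 40, mutation = 0.02, seed = 4,
                         margin = 0)
  lib <- repeat_library("A", "satellite", mono, "284")
  mk <- mask_domain(g$sequences[["arr"]], lib)
  expect_gte(mk$bp_per_family[["A"]] / (284 * 40), 0.95)
  expect_equal(mk$domain_length, 284 * 40)
})

test_that("an empty library leaves everything unassigned", {
  lib <- repeat_library(character(0), character(0), character(0))
  mk <- mask_domain(rnd_dna(5000), lib)
  expect_equal(mk$unassigned_bp, 5000)
  expect_equal(length(mk$bp_per_family), 0)
})

test_that("overlap adjudication: higher score wins, ties go to the smaller family id, losers are trimmed, and the result is idempotent", {
  hits <- data.frame(family = c("zeta", "alpha"),
                     start = c(100, 150), end = c(300, 350),
                     score = c(180, 150), stringsAsFactors = FALSE)
  adj <- centroscape:::adjudicate_hits(hits, min_len = 30)
  expect_equal(adj$family, c("zeta", "alpha"))
  expect_equal(adj$start, c(100, 300))       # loser trimmed to remainder
  expect_equal(adj$end, c(300, 350))
  tie <- data.frame(family = c("zeta", "alpha"),
                    start = c(100, 100), end = c(300, 300),
                    score = c(100, 100), stringsAsFactors = FALSE)
  expect_equal(centroscape:::adjudicate_hits(tie, 30)$family, "alpha")
  # a trimmed remainder below min_len is dropped entirely
  small <- data.frame(family = c("a", "b"), start = c(100, 90),
                      end = c(300, 120), score = c(200, 50),
                      stringsAsFactors = FALSE)
  expect_equal(centroscape:::adjudicate_hits(small, 30)$family, "a")
  # idempotence on an already non-overlapping annotation
  again <- centroscape:::adjudicate_hits(adj, 30)
  expect_equal(again[order(again$start), c("family", "start", "end")],
               adj[order(adj$start), c("family", "start", "end")])
})

test_that("centromere typing: two-major composition is type 1, an accessory satellite at or above threshold makes type 2", {
  lib <- repeat_library(c("cen", "crm", "acc"),
                        c("satellite", "TE", "satellite"),
                        c(rnd_dna(100), rnd_dna(100), rnd_dna(100)))
  fake_mask <- function(bp) {
    structure(list(intervals = NULL, bp_per_family = bp,
                   unassigned_bp = 1e5 - sum(bp), domain_length = 1e5),
              class = "domain_mask")
  }
  t1 <- classify_centromere_type(fake_mask(c(cen = 10000, crm = 25000,
                                             acc = 0)),
                                 lib, c("cen", "crm"))
  expect_equal(t1$type, "type1")
  t2 <- classify_centromere_type(fake_mask(c(cen = 10000, crm = 25000,
                                             acc = 8000)),
                                 lib, c("cen", "crm"))
  expect_equal(t2$type, "type2")
  expect_equal(t2$accessory$family, "acc")
  # inclusive boundary: exactly 2 percent triggers type 2
  tb <- classify_centromere_type(fake_mask(c(cen = 10000, crm = 25000,
                                             acc = 2000)),
                                 lib, c("cen", "crm"))
  expect_equal(tb$type, "type2")
  tu <- classify_centromere_type(fake_mask(c(cen = 10000, crm = 25000,
                                             acc = 1999)),
                                 lib, c("cen", "crm"))
  expect_equal(tu$type, "type1")
})

test_that("type calls are correct across 10 seeds of planted type-1/type-2 domains", {
  set.seed(50)
  cen <- rnd_dna(284); acc <- rnd_dna(323)
  lib <- repeat_library(c("cen", "acc"), c("satellite", "satellite"),
                        c(cen, acc))
  ok <- TRUE
  for (s in 1:10) {
    g1 <- simulate_genome(genome_spec(list(chrom_spec(
      "t1", 50000, satellite_plants = list(
        array_plant("cen", cen, 30, start = 20000,
                    per_base_mutation = 0.02)))), seed = s))
    g2 <- simulate_genome(genome_spec(list(chrom_spec(
      "t2", 50000, satellite_plants = list(
        array_plant("cen", cen, 30, start = 20000,
                    per_base_mutation = 0.02),
        array_plant("acc", acc, 10, start = 30000,
                    per_base_mutation = 0.02)))), seed = s + 100))
    c1 <- classify_centromere_type(mask_domain(g1$sequences[["t1"]], lib),
                                   lib, "cen")
    c2 <- classify_centromere_type(mask_domain(g2$sequences[["t2"]], lib),
                                   lib, "cen")
    if (c1$type != "type1" || c2$type != "type2") ok <- FALSE
  }
  expect_true(ok)
})

test_that("summit assignment categories are exhaustive, half-open and coding-precedent", {
  elements <- data.frame(element_id = "e1", start = 1000, end = 6000,
                         ltr5_start = 1000, ltr5_end = 2000,
                         ltr3_start = 5000, ltr3_end = 6000,
                         stringsAsFactors = FALSE)
  domain_hits <- data.frame(element_id = "e1", start = 2500, end = 3000,
                            stringsAsFactors = FALSE)
  res <- assign_summits(c(1500, 2700, 4000, 6000, 500),
                        elements, domain_hits)
  expect_equal(res$assignments$category,
               c("ltr", "coding", "spacer", "outside_element",
                 "outside_element"))
  expect_equal(sum(res$frequencies), 5)
  expect_equal(as.integer(res$frequencies[["outside_element"]]), 2)
})

test_that("the full pipeline runs end-to-end on the bundled demo with planted truth recovered", {
  out1 <- file.path(tempdir(), "censcape_run1")
  res <- run_pipeline(list(library = "demo", seed = 1), out_dir = out1)
  # both centromere types called as planted
  expect_equal(res$types[["chrA"]]$type, "type1")
  expect_equal(res$types[["chrB"]]$type, "type2")
  # summits within two bins of the planted centers
  expect_true(all(abs(vapply(res$summits, `[[`, numeric(1), "summit") -
                        200000) <= 20000))
  # all five planted elements recovered with correct autonomy labels
  tr <- res$genome$truth$elements
  expect_equal(nrow(res$elements), nrow(tr))
  for (j in seq_len(nrow(tr))) {
    i <- which(res$elements$chromosome == tr$chrom[j] &
                 abs(res$elements$start - tr$start[j]) <= 5)
    expect_length(i, 1)
    expect_equal(res$elements$autonomy[i], tr$autonomy[j])
  }
  # satellite monomer lengths re-estimated from the masked arrays
  expect_true(all(abs(res$satellites$monomer_length[
    res$satellites$family == "cen284"] - 284) <= 1))
  # report files exist
  expect_true(all(file.exists(file.path(out1,
    c("enrichment_table.tsv", "domains.bed", "morphology.tsv",
      "composition.tsv", "element_summary.tsv", "age_histogram.tsv",
      "summit_assignment.tsv", "run_log.txt")))))
})

test_that("pipeline reruns with the same seed are byte-identical", {
  out1 <- file.path(tempdir(), "censcape_run1")   # written by the previous test
  out2 <- file.path(tempdir(), "censcape_run2")
  run_pipeline(list(library = "demo", seed = 1), out_dir = out2)
  for (f in c("enrichment_table.tsv", "element_summary.tsv",
              "composition.tsv", "summit_assignment.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("pipeline aborts naming the missing config key and the failing stage", {
  expect_error(run_pipeline(list(seed = 1)), "library")
  expect_error(run_pipeline(list(library = "no/such/file.fa")),
               "stage 'syndata'")
})
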