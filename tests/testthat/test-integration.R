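test_that("mapping filter honours the primary flag and MAPQ threshold", {
  m <- data.frame(read_id = c("r1", "r2", "r3", "r3"),
                  contig_id = c("c1", "c2", "c3", "c4"),
                  is_primary = c(TRUE, TRUE, FALSE, TRUE),
                  mapq = c(30L, 1L, 50L, 10L))
  a <- filter_and_assign_mappings(m, min_mapq = 2L, seed = 1)
  expect_identical(unname(a["r1"]), "c1")
  expect_false("r2" %in% names(a))          # below Phred 2
  expect_identical(unname(a["r3"]), "c4")   # secondary dropped first
  # boundary: mapq exactly at the threshold survives
  b <- filter_and_assign_mappings(
    data.frame(read_id = "r", contig_id = "c", is_primary = TRUE,
               mapq = 2L), min_mapq = 2L)
  expect_identical(unname(b["r"]), "c")
})

test_that("equal-MAPQ ties break by seeded draw, higher MAPQ wins outright", {
  m <- data.frame(read_id = "r1", contig_id = c("c1", "c2", "c3"),
                  is_primary = TRUE, mapq = c(40L, 40L, 40L))
  picks <- vapply(1:10, function(i)
    unname(filter_and_assign_mappings(m, seed = 99)["r1"]), "")
  expect_length(unique(picks), 1L)          # deterministic under seed
  shuffled <- m[c(3, 1, 2), ]
  expect_identical(unname(filter_and_assign_mappings(shuffled,
                                                     seed = 99)["r1"]),
                   picks[1])                # row order does not matter
  many <- vapply(1:30, function(s)
    unname(filter_and_assign_mappings(m, seed = s)["r1"]), "")
  expect_gt(length(unique(many)), 1L)       # the draw is actually random
  m2 <- data.frame(read_id = "r1", contig_id = c("c1", "c2"),
                   is_primary = TRUE, mapq = c(40L, 50L))
  expect_identical(unname(filter_and_assign_mappings(m2, seed = 1)["r1"]),
                   "c2")
})

test_that("priority cascade assigns the most reliable available signal", {
  assignment <- c(r1 = "c_binned", r2 = "c_unbinned", r3 = "c_plain")
  bin_map <- c(c_binned = "bin1")
  mag_ann <- c(bin1 = "g1")
  cat_ann <- c(c_binned = "sA", c_unbinned = "sB")
  dir_ann <- c(c_plain = "f1")
  read_ann <- c(r4 = "sC")
  reads <- c("r1", "r2", "r3", "r4", "r5")
  ann <- integrate_reads(assignment, bin_map, mag_ann, cat_ann, dir_ann,
                         read_ann, read_ids = reads, mode = "mcr")
  got <- setNames(ann$taxon, ann$read_id)
  src <- setNames(as.character(ann$source), ann$read_id)
  # MAG genus beats the contig's own species annotation
  expect_identical(unname(got["r1"]), "g1")
  expect_identical(unname(src["r1"]), "mag")
  expect_identical(unname(src["r2"]), "contig_cat")
  # unbinned contig without a voted annotation falls to its direct one
  expect_identical(unname(got["r3"]), "f1")
  expect_identical(unname(src["r3"]), "contig_direct")
  expect_identical(unname(src["r4"]), "read_direct")
  expect_identical(unname(src["r5"]), "unclassified")
  expect_true(is.na(got["r5"]))
})

test_that("modes restrict the admissible sources", {
  assignment <- c(r1 = "c1")
  bin_map <- c(c1 = "bin1")
  mag_ann <- c(bin1 = "g1")
  read_ann <- c(r1 = "sA", r2 = "sB")
  reads <- c("r1", "r2")
  mc <- integrate_reads(assignment, bin_map, mag_ann,
                        read_direct_annotations = read_ann,
                        read_ids = reads, mode = "mc")
  expect_identical(as.character(mc$source), c("mag", "unclassified"))
  cr <- integrate_reads(assignment, bin_map, mag_ann,
                        read_direct_annotations = read_ann,
                        read_ids = reads, mode = "cr")
  expect_identical(as.character(cr$source),
                   c("read_direct", "read_direct"))   # MAG ignored
  # a binned contig whose MAG is unannotated falls through to the contig
  mc2 <- integrate_reads(assignment, bin_map,
                         mag_annotations = c(bin1 = NA_character_),
                         contig_cat_annotations = c(c1 = "sA"),
                         read_ids = "r1", mode = "mc")
  expect_identical(as.character(mc2$source), "contig_cat")
  expect_error(integrate_reads(assignment, bin_map, read_ids = reads,
                               mode = "xyz"))
})

test_that("output partitions the read universe and mc classifies a subset of mcr", {
  sim <- simulate_dataset(simulation_config(seed = 8, n_species = 20,
                                            n_reads = 1500,
                                            assembled_fraction = 0.6,
                                            binned_fraction = 0.5))
  for (mode in c("mcr", "mc", "cr")) {
    res <- run_workflow(sim, mode = mode)
    expect_identical(sort(res$annotations$read_id),
                     sort(names(sim$truth_reads)))
    expect_equal(sum(table(res$annotations$source)),
                 length(sim$truth_reads))
  }
  mcr <- run_workflow(sim, mode = "mcr")$annotations
  mc <- run_workflow(sim, mode = "mc")$annotations
  classified <- function(a) a$read_id[!is.na(a$taxon)]
  expect_true(all(classified(mc) %in% classified(mcr)))
})

test_that("integration lifts species TPR above direct-read annotation on noisy data", {
  wins <- 0L
  for (s in 1:5) {
    sim <- simulate_dataset(simulation_config(
      seed = s + 100L, n_species = 30, n_reads = 2000,
      hit_noise = 0.3, assembled_fraction = 0.8))
    full <- run_workflow(sim, mode = "mcr")
    direct <- integrate_reads(
      setNames(character(0), character(0)), sim$bin_map,
      read_direct_annotations = full$read_direct,
      read_ids = names(sim$truth_reads), mode = "cr")
    tpr <- function(a) score_read_annotations(a, sim$truth_reads,
                                              sim$tree, "species")$tpr
    if (tpr(full$annotations) >= tpr(direct)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("SAM and TSV mapping dialects load equivalently", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("r1\tc1\t1\t60", "r2\tc2\t0\t60", "r3\tc1\t1\t1"), tsv)
  m <- read_mappings(tsv)
  expect_equal(nrow(m), 3L)
  expect_identical(m$is_primary, c(TRUE, FALSE, TRUE))

  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               "@SQ\tSN:c1\tLN:1000", "@SQ\tSN:c2\tLN:1000",
               "r1\t0\tc1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
               "r2\t256\tc2\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
               "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*"), sam)
  s <- read_mappings(sam)
  expect_equal(nrow(s), 2L)                 # unmapped record dropped
  expect_identical(s$is_primary[s$read_id == "r2"], FALSE)
  expect_identical(s$contig_id[s$read_id == "r1"], "c1")
})
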