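test_that("bit-score window keeps hits within r of the top, inclusive", {
  h <- hit_df("q", c("sA", "sB", "sC"), c(100, 95, 85))
  kept <- filter_hits_by_r(h, r = 0.10)   # threshold 90
  expect_setequal(kept$bit_score, c(100, 95))
  expect_equal(nrow(filter_hits_by_r(hit_df("q", "sA", 42), 0.1)), 1L)
  ties <- hit_df("q", c("sA", "sB"), c(70, 70))
  expect_equal(nrow(filter_hits_by_r(ties, 1e-9)), 2L)
  expect_error(filter_hits_by_r(h[0, ], 0.1), "nonempty")
})

test_that("query LCA annotation follows the retained hit set", {
  tree <- toy_tree()
  expect_identical(annotate_query_lca(hit_df("q", "sA", 100), tree), "sA")
  # two sibling species within r escalate to their genus
  sib <- hit_df("q", c("sA", "sB"), c(100, 96))
  expect_identical(annotate_query_lca(sib, tree), "g1")
  # out-of-window hit does not drag the LCA up
  far <- hit_df("q", c("sA", "sC"), c(100, 80))
  expect_identical(annotate_query_lca(far, tree), "sA")
  expect_true(is.na(annotate_query_lca(hit_df(character(0),
                                              character(0),
                                              numeric(0)), tree)))
  expect_error(annotate_query_lca(hit_df("q", "nope", 10), tree),
               "nope")
})

test_that("annotate_queries groups hits per query like the single-query rule", {
  tree <- toy_tree()
  h <- rbind(hit_df("q1", c("sA", "sB"), c(100, 96)),
             hit_df("q2", "sC", 50),
             hit_df("q3", c("sA", "sC"), c(100, 80)))
  ann <- annotate_queries(h, tree, r = 0.10)
  ann <- ann[order(ann$query_id), ]
  expect_identical(ann$taxon, c("g1", "sC", "sA"))
  expect_equal(ann$top_bit_score, c(100, 50, 100))
})

test_that("majority voting picks the deepest taxon above f", {
  tree <- toy_tree()
  # 3 ORFs, equal scores: A, A, B(sibling) -> species A at 2/3, genus at 1
  orfs <- data.frame(taxon = c("sA", "sA", "sB"),
                     top_bit_score = c(10, 10, 10))
  v <- vote_sequence(orfs, tree, f = 0.5, sequence_id = "ctg1")
  expect_identical(v$taxon, "sA")
  expect_equal(v$support, 2 / 3)
  expect_equal(unname(v$lineage_scores["g1"]), 1)
  expect_equal(unname(v$lineage_scores["1"]), 1)
  # exact 50/50 species tie escalates to the genus (strict > f)
  tie <- data.frame(taxon = c("sA", "sB"), top_bit_score = c(5, 5))
  vt <- vote_sequence(tie, tree, f = 0.5)
  expect_identical(vt$taxon, "g1")
  expect_equal(vt$support, 1)
  # single annotated ORF
  one <- data.frame(taxon = "sA", top_bit_score = 7)
  expect_identical(vote_sequence(one, tree)$taxon, "sA")
  expect_equal(vote_sequence(one, tree)$support, 1)
  # hitless ORFs leave the denominator; all-hitless is unclassified
  mix <- data.frame(taxon = c("sA", NA), top_bit_score = c(7, 99))
  expect_equal(vote_sequence(mix, tree)$support, 1)
  none <- data.frame(taxon = NA_character_, top_bit_score = 0)
  expect_true(is.na(vote_sequence(none, tree)$taxon))
  expect_identical(vote_sequence(none, tree)$source, "unclassified")
  expect_error(vote_sequence(orfs, tree, f = 0.4), "not supported")
})

test_that("lineage scores are non-increasing and sum to at most 1 per rank", {
  tree <- make_taxonomy(seed = 2, n_species = 20)
  set.seed(7)
  sp <- tree$ids[tree$rank %in% c("species", "genus", "family")]
  for (k in 1:30) {
    n <- sample(2:10, 1)
    orfs <- data.frame(taxon = sample(sp, n, replace = TRUE),
                       top_bit_score = stats::runif(n, 10, 200))
    v <- vote_sequence(orfs, tree, f = 0.5)
    expect_equal(unname(v$lineage_scores[1]), 1)   # root carries all mass
    expect_true(all(diff(v$lineage_scores) <= 1e-12))
    expect_equal(v$support, unname(v$lineage_scores[length(v$lineage_scores)]))
  }
})

test_that("voting matches the brute-force per-node evaluator", {
  set.seed(31)
  for (k in 1:40) {
    tree <- make_taxonomy(seed = k, n_species = sample(4:10, 1), fanout = 2)
    pool <- tree$ids[tree$rank %in% official_ranks()]
    n <- sample(1:12, 1)
    taxa <- sample(pool, n, replace = TRUE)
    w <- stats::runif(n, 1, 100)
    v <- vote_sequence(data.frame(taxon = taxa, top_bit_score = w), tree)
    expect_identical(v$taxon, brute_vote(taxa, w, 0.5, tree))
  }
})

test_that("increasing r or f never yields a deeper annotation", {
  set.seed(12)
  tree <- make_taxonomy(seed = 3, n_species = 15)
  sp <- tree$ids[tree$rank == "species"]
  is_anc <- function(a, b) a %in% lineage(tree, b)   # a ancestor-or-eq of b
  for (k in 1:60) {
    h <- hit_df("q", sample(sp, 5, replace = TRUE), stats::runif(5, 50, 100))
    rs <- sort(stats::runif(2, 0.01, 0.9))
    a1 <- annotate_query_lca(h, tree, rs[1])
    a2 <- annotate_query_lca(h, tree, rs[2])
    expect_true(is_anc(a2, a1))

    orfs <- data.frame(taxon = sample(sp, 6, replace = TRUE),
                       top_bit_score = stats::runif(6, 1, 50))
    fs <- sort(stats::runif(2, 0.5, 0.99))
    v1 <- vote_sequence(orfs, tree, fs[1])$taxon
    v2 <- vote_sequence(orfs, tree, fs[2])$taxon
    expect_true(is_anc(v2, v1))
    # uniform bit-score scaling leaves the vote unchanged
    v3 <- vote_sequence(transform(orfs, top_bit_score = top_bit_score * 37),
                        tree, fs[1])$taxon
    expect_identical(v3, v1)
  }
})

test_that("bin voting pools member-contig ORFs", {
  tree <- toy_tree()
  orfs <- data.frame(query_id = c("c1_1", "c1_2", "c2_1", "c2_2"),
                     taxon = c("sA", "sA", "sA", "sB"),
                     top_bit_score = c(10, 10, 10, 10))
  bins <- c(c1 = "bin1", c2 = "bin1")
  m <- annotate_mags(orfs, bins, tree)
  expect_identical(m$taxon, "sA")        # 3/4 majority across the pool
  expect_identical(m$source, "mag")
  # contig-level disagreement at species resolving at genus when pooled
  orfs2 <- data.frame(query_id = c("c1_1", "c2_1"),
                      taxon = c("sA", "sB"), top_bit_score = c(10, 10))
  expect_identical(annotate_mags(orfs2, bins, tree)$taxon, "g1")
  # a bin whose contigs have no hits is unclassified
  orfs3 <- data.frame(query_id = c("c1_1"), taxon = NA_character_,
                      top_bit_score = 0)
  expect_true(is.na(annotate_mags(orfs3, bins, tree)$taxon))
  expect_error(annotate_mag(orfs[0, ], tree), "at least one")
  expect_identical(annotate_mag(orfs, tree, bin_id = "b")$source, "mag")
})

test_that("hit tables parse with and without headers and comments", {
  f <- tempfile()
  writeLines(c("# comment", "query_id\tsubject_taxon_id\tbit_score",
               "q1\tsA\t100.5", "q2\tsB\t90"), f)
  h <- read_hits(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$bit_score, c(100.5, 90))
  f2 <- tempfile()
  writeLines(c("q1\tsA\t100.5"), f2)
  expect_equal(nrow(read_hits(f2)), 1L)
  expect_identical(orf_to_contig(c("ctg7_1", "ctg7_12")),
                   c("ctg7", "ctg7"))
  expect_identical(orf_to_contig("x", map = c(x = "c9")), "c9")
  expect_error(orf_to_contig("y", map = c(x = "c9")), "missing")
})
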