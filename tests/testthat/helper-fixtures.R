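# Shared fixtures: a small hand-built taxonomy and writers for the text
# dialects the loaders consume.

# root -> sk1 -> p1 -> c1 -> o1 -> f1 -> {g1 -> {sA, sB}, g2 -> sC}
toy_tree <- function() {
  taxonomy_tree(
    taxon_id  = c("1", "sk1", "p1", "c1", "o1", "f1", "g1", "g2",
                  "sA", "sB", "sC"),
    parent_id = c("1", "1", "sk1", "p1", "c1", "o1", "f1", "f1",
                  "g1", "g1", "g2"),
    rank = c("root", "superkingdom", "phylum", "class", "order", "family",
             "genus", "genus", "species", "species", "species"))
}

write_dmp_fixture <- function(dir, nodes, names_ = NULL, merged = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  if (!is.null(names_)) writeLines(names_, file.path(dir, "names.dmp"))
  if (!is.null(merged)) writeLines(merged, file.path(dir, "merged.dmp"))
  dir
}

dmp_line <- function(...) paste0(paste(..., sep = "\t|\t"), "\t|")

# independent parent-chasing lineage, used as oracle against lineage()
chase_lineage <- function(tree, id) {
  i <- match(id, tree$ids)
  path <- character(0)
  repeat {
    path <- c(tree$ids[i], path)
    if (i == tree$root) break
    i <- tree$parent[i]
  }
  path
}

# hit-table row builder
hit_df <- function(query, taxon, bit) {
  data.frame(query_id = query, subject_taxon = taxon, bit_score = bit)
}

# brute-force voting oracle: score every tree node independently as the
# normalised weight of ORFs whose annotation lineage contains it, then
# take the deepest node with score strictly above f.
brute_vote <- function(taxa, weights, f, tree) {
  keep <- !is.na(taxa)
  taxa <- taxa[keep]; weights <- weights[keep]
  if (!length(taxa)) return(NA_character_)
  total <- sum(weights)
  score <- vapply(tree$ids, function(node) {
    contrib <- vapply(taxa, function(t) node %in% lineage(tree, t),
                      logical(1))
    sum(weights[contrib]) / total
  }, numeric(1))
  cand <- tree$ids[score > f]
  cand[which.max(tree$depth[match(cand, tree$ids)])]
}

# random per-read annotation table over a tree's official-rank nodes
random_annotations <- function(tree, n, p_unclassified = 0.1) {
  pool <- tree$ids[tree$rank %in% official_ranks()]
  taxa <- sample(pool, n, replace = TRUE)
  taxa[stats::runif(n) < p_unclassified] <- NA
  data.frame(read_id = sprintf("r%05d", seq_len(n)), taxon = taxa)
}
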