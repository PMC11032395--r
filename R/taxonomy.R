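# Canonical rank slots, root-first. NCBI "superkingdom" and GTDB "domain"
# share the second slot.
.RANKS <- c("root", "superkingdom", "phylum", "class", "order", "family",
            "genus", "species")

#' Official rank vocabulary
#'
#' @param include_root keep the synthetic root slot.
#' @return Character vector of official rank labels, root-first.
#' @export
official_ranks <- function(include_root = FALSE) {
  if (include_root) .RANKS else .RANKS[-1]
}

# Map a raw rank label onto its canonical slot; non-official labels pass
# through unchanged (they are retained in the tree but skipped by
# rank projection).
.rank_slot <- function(rank) {
  ifelse(rank == "domain", "superkingdom", rank)
}

#' Construct a taxonomy tree
#'
#' Builds the rooted, rank-labelled taxonomy used by every downstream stage.
#' Exactly one node must be its own parent (the root); every other
#' \code{parent_id} must resolve to a node in the set.
#'
#' @param taxon_id character vector of unique node identifiers.
#' @param parent_id parent identifier per node (root points to itself).
#' @param rank rank label per node; anything outside the official vocabulary
#'   is kept as "no rank"-like filler and skipped during rank projection.
#' @param name display name per node (defaults to the identifier).
#' @param merged named character vector mapping retired identifiers to their
#'   current replacement; lookups remap through it transparently.
#' @return An object of class \code{taxonomy}.
#' @export
taxonomy_tree <- function(taxon_id, parent_id, rank,
                          name = taxon_id, merged = character(0)) {
  taxon_id <- as.character(taxon_id)
  parent_id <- as.character(parent_id)
  rank <- as.character(rank)
  name <- as.character(name)
  n <- length(taxon_id)
  stopifnot(length(parent_id) == n, length(rank) == n, length(name) == n)
  if (anyDuplicated(taxon_id))
    stop("duplicated taxon ids: ",
         paste(unique(taxon_id[duplicated(taxon_id)]), collapse = ", "))

  parent <- match(parent_id, taxon_id)
  if (anyNA(parent)) {
    bad <- taxon_id[is.na(parent)]
    stop("parent of node(s) ", paste(bad, collapse = ", "),
         " absent from taxonomy")
  }
  root <- which(parent == seq_len(n))
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root (node that is its own parent); ",
         "found ", length(root))

  # depth by parent-chasing with a cycle guard
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (j != root) {
      j <- parent[j]; d <- d + 1L
      if (d > n) stop("cycle detected in taxonomy at node ", taxon_id[i])
    }
    depth[i] <- d
  }

  # ancestor-or-self projection onto each official rank slot
  slot <- .rank_slot(rank)
  at_rank <- matrix(NA_character_, n, length(.RANKS),
                    dimnames = list(NULL, .RANKS))
  for (i in order(depth)) {
    if (i == root) {
      at_rank[i, "root"] <- taxon_id[i]
    } else {
      at_rank[i, ] <- at_rank[parent[i], ]
    }
    if (slot[i] %in% .RANKS) at_rank[i, slot[i]] <- taxon_id[i]
  }

  structure(list(ids = taxon_id, parent = parent, rank = rank, name = name,
                 merged = merged, root = root, depth = depth,
                 at_rank = at_rank, rank_order = .RANKS),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy: ", length(x$ids), " nodes, root '", x$ids[x$root],
      "', max depth ", max(x$depth), "\n", sep = "")
  tab <- table(.rank_slot(x$rank))
  keep <- intersect(.RANKS, names(tab))
  cat("  ranks:",
      paste(sprintf("%s=%d", keep, tab[keep]), collapse = " "), "\n")
  invisible(x)
}

# Resolve ids through the merged map, then to row indices. Unknown ids error.
.tx_index <- function(tree, ids) {
  ids <- as.character(ids)
  hit <- match(ids, names(tree$merged))
  ids[!is.na(hit)] <- tree$merged[hit[!is.na(hit)]]
  idx <- match(ids, tree$ids)
  if (anyNA(idx))
    stop("unknown taxon id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  idx
}

#' Root-to-node lineage
#'
#' @param tree a \code{taxonomy}.
#' @param taxon_id a single taxon identifier (retired ids are remapped).
#' @return Character vector of taxon ids from the root down to the node.
#' @export
lineage <- function(tree, taxon_id) {
  i <- .tx_index(tree, taxon_id)
  stopifnot(length(i) == 1L)
  path <- integer(tree$depth[i] + 1L)
  k <- length(path)
  while (TRUE) {
    path[k] <- i
    if (i == tree$root) break
    i <- tree$parent[i]; k <- k - 1L
  }
  tree$ids[path]
}

#' Lowest common ancestor of a taxon set
#'
#' @param tree a \code{taxonomy}.
#' @param taxa nonempty vector of taxon ids.
#' @return The id of the deepest node lying on every input lineage.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("lca() needs a nonempty taxon set")
  idx <- .tx_index(tree, taxa)
  if (length(idx) == 1L) return(tree$ids[idx])
  paths <- lapply(idx, function(i) {
    p <- integer(tree$depth[i] + 1L); k <- length(p)
    while (TRUE) {
      p[k] <- i
      if (i == tree$root) break
      i <- tree$parent[i]; k <- k - 1L
    }
    p
  })
  m <- min(lengths(paths))
  common <- 0L
  for (k in seq_len(m)) {
    v <- paths[[1L]][k]
    if (all(vapply(paths, function(p) p[k] == v, logical(1)))) common <- k
    else break
  }
  tree$ids[paths[[1L]][common]]
}

#' Project a taxon onto an official rank
#'
#' Returns the unique ancestor-or-self of \code{taxon_id} carrying the given
#' rank, or \code{NA} when the lineage does not reach that deep. Non-official
#' levels ("no rank", strain) are skipped.
#'
#' @param tree a \code{taxonomy}.
#' @param taxon_id taxon id(s); vectorised.
#' @param rank one official rank label ("domain" is accepted for
#'   "superkingdom").
#' @return Character vector of taxon ids (NA where absent).
#' @export
taxon_at_rank <- function(tree, taxon_id, rank) {
  slot <- .rank_slot(rank)
  if (length(slot) != 1L || !slot %in% .RANKS)
    stop("unknown rank label: ", rank)
  idx <- .tx_index(tree, taxon_id)
  unname(tree$at_rank[idx, slot])
}

#' Load an NCBI-style taxonomy dump
#'
#' Parses the \code{nodes.dmp}/\code{names.dmp}/\code{merged.dmp} dialect
#' (fields separated by \code{"\t|\t"}, records terminated by \code{"\t|"}).
#' When several name classes exist for a node the scientific name is
#' preferred.
#'
#' @param nodes_path path to nodes.dmp.
#' @param names_path optional path to names.dmp.
#' @param merged_path optional path to merged.dmp.
#' @return A \code{taxonomy}.
#' @export
load_ncbi_taxonomy <- function(nodes_path, names_path = NULL,
                               merged_path = NULL) {
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  rows <- parse_dmp(nodes_path)
  taxon_id <- vapply(rows, `[[`, "", 1L)
  parent_id <- vapply(rows, `[[`, "", 2L)
  rank <- vapply(rows, `[[`, "", 3L)

  name <- taxon_id
  if (!is.null(names_path)) {
    nrows <- parse_dmp(names_path)
    nid <- vapply(nrows, `[[`, "", 1L)
    nm <- vapply(nrows, `[[`, "", 2L)
    cls <- vapply(nrows, function(r) if (length(r) >= 4L) r[[4L]] else "", "")
    ord <- order(cls != "scientific name")  # scientific names first
    nid <- nid[ord]; nm <- nm[ord]
    keep <- !duplicated(nid)
    hit <- match(taxon_id, nid[keep])
    name[!is.na(hit)] <- nm[keep][hit[!is.na(hit)]]
  }

  merged <- character(0)
  if (!is.null(merged_path)) {
    mrows <- parse_dmp(merged_path)
    merged <- stats::setNames(vapply(mrows, `[[`, "", 2L),
                              vapply(mrows, `[[`, "", 1L))
  }
  if (!any(taxon_id == parent_id))
    stop("no root node (parent_id == taxon_id) found in ", nodes_path)
  taxonomy_tree(taxon_id, parent_id, rank, name, merged)
}

#' Load a GTDB-style taxonomy table
#'
#' Reads the two-column TSV of genome accession and seven-rank prefixed
#' lineage string (\code{d__;p__;c__;o__;f__;g__;s__}). One node is created
#' per distinct prefixed name per rank; both domains hang from a synthetic
#' root with id "1"; genomes attach as leaves below their species.
#'
#' @param tsv_path path to the taxonomy TSV.
#' @return A \code{taxonomy}.
#' @export
load_gtdb_taxonomy <- function(tsv_path) {
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(lines)]
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  gtdb_ranks <- c("domain", "phylum", "class", "order", "family", "genus",
                  "species")
  ids <- "1"; parents <- "1"; ranks <- "root"; names_ <- "root"
  seen <- new.env(parent = emptyenv())
  for (row in seq_along(lines)) {
    f <- strsplit(lines[row], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 2L)
      stop("row ", row, ": expected 2 tab-separated columns")
    parts <- strsplit(f[2L], ";", fixed = TRUE)[[1L]]
    if (length(parts) != 7L ||
        any(substr(parts, 1L, 3L) != prefixes))
      stop("row ", row, ": malformed 7-rank lineage string")
    prev <- "1"
    for (k in seq_len(7L)) {
      node <- parts[k]
      if (is.null(seen[[node]])) {
        seen[[node]] <- TRUE
        ids <- c(ids, node); parents <- c(parents, prev)
        ranks <- c(ranks, gtdb_ranks[k])
        names_ <- c(names_, substring(node, 4L))
      }
      prev <- node
    }
    ids <- c(ids, f[1L]); parents <- c(parents, prev)
    ranks <- c(ranks, "no rank"); names_ <- c(names_, f[1L])
  }
  taxonomy_tree(ids, parents, ranks, names_)
}

#' Write a taxonomy in the NCBI dump dialect
#'
#' Emits \code{nodes.dmp}, \code{names.dmp} and (when the tree carries a
#' merged map) \code{merged.dmp} so that a load/serialize/reload round trip
#' reproduces the node set.
#'
#' @param tree a \code{taxonomy}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ncbi_taxonomy <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- file.path(dir, "nodes.dmp")
  writeLines(paste0(tree$ids, "\t|\t", tree$ids[tree$parent], "\t|\t",
                    tree$rank, "\t|"), nodes)
  names_ <- file.path(dir, "names.dmp")
  writeLines(paste0(tree$ids, "\t|\t", tree$name, "\t|\t\t|\t",
                    "scientific name", "\t|"), names_)
  paths <- c(nodes, names_)
  if (length(tree$merged)) {
    merged <- file.path(dir, "merged.dmp")
    writeLines(paste0(names(tree$merged), "\t|\t", tree$merged, "\t|"),
               merged)
    paths <- c(paths, merged)
  }
  invisible(paths)
}
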