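# Homology-hit classification: r-window filtering, per-query LCA, and
# bit-score-weighted lineage voting for contigs and bins.

#' Read a tabular homology hit table
#'
#' Accepts DIAMOND-tabular-style TSV with at least three columns: query id,
#' subject taxon id, bit-score. A header line is detected by a non-numeric
#' third field; lines starting with "#" are ignored.
#'
#' @param path path to the TSV.
#' @return data.frame with columns \code{query_id}, \code{subject_taxon},
#'   \code{bit_score}.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(query_id = character(0), subject_taxon = character(0),
                      bit_score = numeric(0)))
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(first[3L])))
  dt <- data.table::fread(text = lines, header = has_header, sep = "\t")
  if (ncol(dt) < 3L) stop("hit table needs >= 3 columns: ", path)
  data.frame(query_id = as.character(dt[[1L]]),
             subject_taxon = as.character(dt[[2L]]),
             bit_score = as.numeric(dt[[3L]]))
}

#' Keep hits within the bit-score window below the top hit
#'
#' Retains, for a single query, every hit whose bit-score is at least
#' \code{(1 - r)} times the top bit-score. The boundary is inclusive, so
#' ties with the top hit are never dropped.
#'
#' @param hits data.frame of hits for one query (needs a \code{bit_score}
#'   column).
#' @param r window width as a fraction of the top bit-score (default 0.10).
#' @return The retained subset of \code{hits}.
#' @export
filter_hits_by_r <- function(hits, r = 0.10) {
  if (NROW(hits) == 0L) stop("filter_hits_by_r() needs a nonempty hit list")
  stopifnot(r > 0, r <= 1, all(hits$bit_score >= 0))
  hits[hits$bit_score >= (1 - r) * max(hits$bit_score), , drop = FALSE]
}

#' Annotate one query as the LCA of its retained hits
#'
#' @param hits data.frame of hits for one query (possibly empty).
#' @param tree a \code{taxonomy}.
#' @param r bit-score window fraction.
#' @return Taxon id, or \code{NA_character_} for an empty hit list.
#' @export
annotate_query_lca <- function(hits, tree, r = 0.10) {
  if (NROW(hits) == 0L) return(NA_character_)
  kept <- filter_hits_by_r(hits, r)
  lca(tree, unique(kept$subject_taxon))
}

#' Annotate every query in a hit table
#'
#' Applies the r-window LCA rule per query. Used for ORFs, for direct
#' (blastx-style) contig hits, and for direct read hits alike.
#'
#' @param hits data.frame as returned by \code{read_hits}.
#' @param tree a \code{taxonomy}.
#' @param r bit-score window fraction.
#' @return data.frame with \code{query_id}, \code{taxon},
#'   \code{top_bit_score}, one row per distinct query.
#' @export
annotate_queries <- function(hits, tree, r = 0.10) {
  if (NROW(hits) == 0L)
    return(data.frame(query_id = character(0), taxon = character(0),
                      top_bit_score = numeric(0)))
  dt <- data.table::as.data.table(hits)
  thr <- dt[, .(top = max(bit_score)), by = query_id]
  dt <- merge(dt, thr, by = "query_id")
  dt <- dt[bit_score >= (1 - r) * top]
  out <- dt[, .(taxon = lca(tree, unique(subject_taxon)),
                top_bit_score = top[1L]), by = query_id]
  as.data.frame(out)
}

# Core voting rule shared by contig- and bin-level annotation. Each
# annotated unit (ORF) deposits its weight on every node of its
# annotation's lineage; scores are normalised by the summed weight of
# annotated units, so the root always scores 1 and scores never increase
# towards the leaves. The winner is the deepest node with score
# strictly above f; with f >= 0.5 at most one node per rank can qualify,
# and exact 50/50 ties escalate to the competitors' LCA.
.vote_taxon <- function(taxa, weights, f, tree) {
  keep <- !is.na(taxa)
  taxa <- taxa[keep]; weights <- weights[keep]
  if (length(taxa) == 0L)
    return(list(taxon = NA_character_, support = NA_real_,
                lineage_scores = numeric(0)))
  total <- sum(weights)
  scores <- new.env(parent = emptyenv())
  for (k in seq_along(taxa)) {
    for (node in lineage(tree, taxa[k])) {
      prev <- scores[[node]]
      scores[[node]] <- (if (is.null(prev)) 0 else prev) + weights[k]
    }
  }
  ids <- ls(scores)
  sc <- vapply(ids, function(i) scores[[i]], numeric(1)) / total
  cand <- ids[sc > f]
  depths <- tree$depth[.tx_index(tree, cand)]
  pick <- cand[which.max(depths)]
  list(taxon = pick, support = unname(sc[match(pick, ids)]),
       lineage_scores = sc[match(lineage(tree, pick), ids)] |>
         stats::setNames(lineage(tree, pick)))
}

.check_f <- function(f) {
  if (f < 0.5) stop("f values below 0.5 are not supported")
  if (f >= 1) stop("f must be below 1")
}

#' Vote a sequence-level annotation from its ORF annotations
#'
#' Each annotated ORF contributes its top bit-score to every taxon on the
#' lineage of its LCA annotation; lineage scores are the contribution sums
#' divided by the total top bit-score of annotated ORFs. The sequence is
#' assigned the deepest taxon whose score strictly exceeds \code{f}
#' (majority voting at the default \code{f = 0.5}); ORFs without hits are
#' excluded from the denominator.
#'
#' @param orf_annotations data.frame with columns \code{taxon} (NA for
#'   hitless ORFs) and \code{top_bit_score}, as from
#'   \code{annotate_queries}.
#' @param tree a \code{taxonomy}.
#' @param f minimum lineage-support fraction in [0.5, 1).
#' @param sequence_id label recorded on the result.
#' @param source provenance label, e.g. "contig_cat" or "mag".
#' @return List of class \code{seq_annotation}: \code{sequence_id},
#'   \code{taxon} (NA when no ORF had hits), \code{support},
#'   \code{lineage_scores}, \code{source}.
#' @export
vote_sequence <- function(orf_annotations, tree, f = 0.5,
                          sequence_id = NA_character_,
                          source = "contig_cat") {
  .check_f(f)
  v <- .vote_taxon(orf_annotations$taxon, orf_annotations$top_bit_score,
                   f, tree)
  structure(c(list(sequence_id = sequence_id), v,
              list(source = if (is.na(v$taxon)) "unclassified" else source)),
            class = "seq_annotation")
}

#' @export
print.seq_annotation <- function(x, ...) {
  cat("Sequence ", x$sequence_id, ": ",
      if (is.na(x$taxon)) "unclassified"
      else sprintf("%s (support %.3f, source %s)", x$taxon, x$support,
                   x$source),
      "\n", sep = "")
  invisible(x)
}

#' Recover the parent contig of each ORF
#'
#' By convention ORF ids are \code{<contig>_<n>}; an explicit map overrides
#' the convention.
#'
#' @param orf_ids character vector of ORF ids.
#' @param map optional named character vector orf id -> contig id.
#' @return Character vector of contig ids.
#' @export
orf_to_contig <- function(orf_ids, map = NULL) {
  if (!is.null(map)) {
    out <- unname(map[orf_ids])
    if (anyNA(out))
      stop("ORF id(s) missing from orf-to-contig map: ",
           paste(orf_ids[is.na(out)][1:min(5, sum(is.na(out)))],
                 collapse = ", "))
    return(out)
  }
  sub("_[0-9]+$", "", orf_ids)
}

#' Vote annotations for all contigs
#'
#' @param orf_annotations data.frame with \code{query_id}, \code{taxon},
#'   \code{top_bit_score} (one row per ORF).
#' @param tree a \code{taxonomy}.
#' @param f minimum lineage-support fraction.
#' @param orf2contig optional explicit ORF-to-contig map.
#' @return data.frame with \code{sequence_id}, \code{taxon},
#'   \code{support}, \code{source}.
#' @export
annotate_contigs <- function(orf_annotations, tree, f = 0.5,
                             orf2contig = NULL) {
  .check_f(f)
  contig <- orf_to_contig(orf_annotations$query_id, orf2contig)
  groups <- split(seq_len(nrow(orf_annotations)), contig)
  res <- lapply(names(groups), function(cid) {
    idx <- groups[[cid]]
    v <- .vote_taxon(orf_annotations$taxon[idx],
                     orf_annotations$top_bit_score[idx], f, tree)
    data.frame(sequence_id = cid, taxon = v$taxon,
               support = v$support,
               source = if (is.na(v$taxon)) "unclassified" else "contig_cat")
  })
  do.call(rbind, res)
}

#' Vote annotations for all bins (MAGs)
#'
#' Pools the ORF annotations of every contig in a bin and applies the same
#' voting rule; a bin of contigs is a stronger taxonomic signal than any
#' single contig.
#'
#' @param orf_annotations data.frame with \code{query_id}, \code{taxon},
#'   \code{top_bit_score}.
#' @param bin_map named character vector contig id -> bin id.
#' @param tree a \code{taxonomy}.
#' @param f minimum lineage-support fraction.
#' @param orf2contig optional explicit ORF-to-contig map.
#' @return data.frame with \code{sequence_id} (bin id), \code{taxon},
#'   \code{support}, \code{source = "mag"}.
#' @export
annotate_mags <- function(orf_annotations, bin_map, tree, f = 0.5,
                          orf2contig = NULL) {
  .check_f(f)
  if (length(bin_map) == 0L)
    return(data.frame(sequence_id = character(0), taxon = character(0),
                      support = numeric(0), source = character(0)))
  contig <- orf_to_contig(orf_annotations$query_id, orf2contig)
  bin <- unname(bin_map[contig])
  groups <- split(seq_len(nrow(orf_annotations)), bin)
  bins_without_orfs <- setdiff(unique(bin_map), names(groups))
  res <- lapply(names(groups), function(bid) {
    idx <- groups[[bid]]
    v <- .vote_taxon(orf_annotations$taxon[idx],
                     orf_annotations$top_bit_score[idx], f, tree)
    data.frame(sequence_id = bid, taxon = v$taxon, support = v$support,
               source = if (is.na(v$taxon)) "unclassified" else "mag")
  })
  if (length(bins_without_orfs))
    res <- c(res, list(data.frame(sequence_id = bins_without_orfs,
                                  taxon = NA_character_, support = NA_real_,
                                  source = "unclassified")))
  do.call(rbind, res)
}

#' Vote the annotation of one bin
#'
#' Convenience wrapper around the pooled voting rule for a single bin.
#'
#' @param orf_annotations ORF annotations (\code{taxon},
#'   \code{top_bit_score}) of all member contigs of the bin.
#' @param tree a \code{taxonomy}.
#' @param f minimum lineage-support fraction.
#' @param bin_id label recorded on the result.
#' @return A \code{seq_annotation} with source "mag".
#' @export
annotate_mag <- function(orf_annotations, tree, f = 0.5,
                         bin_id = NA_character_) {
  if (NROW(orf_annotations) == 0L)
    stop("annotate_mag() needs a bin with at least one contig/ORF record")
  vote_sequence(orf_annotations, tree, f, sequence_id = bin_id,
                source = "mag")
}
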