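# Evaluation of read annotations and profiles: per-read scoring against
# ground truth, L1 distance, detection precision/sensitivity, weighted
# UniFrac as an earth-mover's distance on the taxonomy, and rarefaction.

# The six ranks at which annotations are scored.
.EVAL_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Ranks used for per-read scoring
#' @return Character vector phylum..species.
#' @export
evaluation_ranks <- function() .EVAL_RANKS

#' Score read annotations against per-read ground truth
#'
#' At each rank a read is correct when the projections of prediction and
#' truth agree, incorrect when the prediction projects to a different
#' taxon (or to one where the truth has none), and unannotated when the
#' prediction is unclassified or stops above the rank. TPR is the correct
#' fraction of annotated reads (0 when nothing is annotated at a rank);
#' overall accuracy (correct / total) is reported alongside.
#'
#' @param predicted data.frame with \code{read_id} and \code{taxon}.
#' @param truth named character vector read_id -> true taxon; must cover
#'   every predicted read.
#' @param tree a \code{taxonomy}.
#' @param ranks ranks to score.
#' @return data.frame with one row per rank: correct, incorrect,
#'   unannotated, tpr, accuracy.
#' @export
score_read_annotations <- function(predicted, truth, tree,
                                   ranks = evaluation_ranks()) {
  miss <- setdiff(predicted$read_id, names(truth))
  if (length(miss))
    stop("predicted read(s) missing from truth: ",
         paste(utils::head(miss, 5), collapse = ", "))
  tt <- unname(truth[predicted$read_id])
  pt <- predicted$taxon
  n <- nrow(predicted)
  pidx <- rep(NA_integer_, n); tidx <- rep(NA_integer_, n)
  pidx[!is.na(pt)] <- .tx_index(tree, pt[!is.na(pt)])
  tidx[!is.na(tt)] <- .tx_index(tree, tt[!is.na(tt)])
  out <- lapply(ranks, function(r) {
    slot <- .rank_slot(r)
    pr <- ifelse(is.na(pidx), NA_character_, tree$at_rank[pidx, slot])
    tr <- ifelse(is.na(tidx), NA_character_, tree$at_rank[tidx, slot])
    correct <- sum(!is.na(pr) & !is.na(tr) & pr == tr)
    incorrect <- sum(!is.na(pr) & (is.na(tr) | pr != tr))
    unannotated <- sum(is.na(pr))
    ann <- correct + incorrect
    data.frame(rank = r, correct = correct, incorrect = incorrect,
               unannotated = unannotated,
               tpr = if (ann > 0) correct / ann else 0,
               accuracy = correct / n)
  })
  do.call(rbind, out)
}

# Extract a rank's taxon->fraction vector from a profile or pass a plain
# named numeric through.
.rank_map <- function(p, rank) {
  if (inherits(p, "tax_profile")) {
    if (!rank %in% names(p$per_rank))
      stop("profile has no rank '", rank, "'")
    p$per_rank[[rank]]
  } else p
}

#' L1 distance between two profiles at one rank
#'
#' Sum over the union of taxa of the absolute abundance difference; ranges
#' from 0 (identical profiles) to 2 (two full-mass profiles sharing no
#' taxa).
#'
#' @param p1,p2 \code{tax_profile}s (or plain named fraction vectors).
#' @param rank rank at which to compare.
#' @return Numeric in [0, 2].
#' @export
l1_distance <- function(p1, p2, rank = "species") {
  a <- .rank_map(p1, rank); b <- .rank_map(p2, rank)
  taxa <- union(names(a), names(b))
  av <- ifelse(is.na(match(taxa, names(a))), 0, a[match(taxa, names(a))])
  bv <- ifelse(is.na(match(taxa, names(b))), 0, b[match(taxa, names(b))])
  sum(abs(av - bv))
}

#' Detection counts at one rank
#'
#' A taxon counts as detected when its relative abundance in the predicted
#' profile is at least the cut-off; detections are compared with the set of
#' taxa present in the reference profile at that rank.
#'
#' @param predicted,reference \code{tax_profile}s (or named fraction
#'   vectors).
#' @param rank rank at which to compare.
#' @param cutoff minimum detected abundance (default 1e-5, i.e. 0.001\%).
#' @return List with TP, FP, FN counts.
#' @export
detection_counts <- function(predicted, reference, rank = "species",
                             cutoff = 1e-5) {
  stopifnot(cutoff >= 0)
  p <- .rank_map(predicted, rank); r <- .rank_map(reference, rank)
  det <- names(p)[p >= cutoff & p > 0]
  ref <- names(r)[r > 0]
  list(TP = length(intersect(det, ref)),
       FP = length(setdiff(det, ref)),
       FN = length(setdiff(ref, det)))
}

.check_counts <- function(counts) {
  if (any(unlist(counts) < 0)) stop("detection counts must be nonnegative")
}

#' Detection precision, TP / (TP + FP)
#'
#' @param counts list with TP, FP, FN.
#' @return Numeric in [0, 1], or NA when nothing was detected.
#' @export
precision <- function(counts) {
  .check_counts(counts)
  d <- counts$TP + counts$FP
  if (d == 0) NA_real_ else counts$TP / d
}

#' Detection sensitivity, TP / (TP + FN)
#'
#' @param counts list with TP, FP, FN.
#' @return Numeric in [0, 1], or NA when the reference is empty.
#' @export
sensitivity <- function(counts) {
  .check_counts(counts)
  d <- counts$TP + counts$FN
  if (d == 0) NA_real_ else counts$TP / d
}

# Place a profile's mass on taxonomy nodes at the leaf-most level it is
# annotated to: a node keeps the part of its per-rank fraction that does
# not continue to a deeper profiled rank. Skipped-rank lineages subtract
# from the nearest shallower profiled ancestor. Tiny negative residues
# from renormalised profiles are clipped at zero.
.profile_node_mass <- function(profile, tree) {
  ranks <- names(profile$per_rank)
  ranks <- ranks[order(match(.rank_slot(ranks), .RANKS))]
  mass <- new.env(parent = emptyenv())
  for (r in ranks)
    for (tx in names(profile$per_rank[[r]]))
      mass[[tx]] <- profile$per_rank[[r]][[tx]]
  for (k in rev(seq_along(ranks))[-length(ranks)]) {  # deepest..2nd
    p <- profile$per_rank[[ranks[k]]]
    if (length(p) == 0L) next
    idx <- .tx_index(tree, names(p))
    for (j in seq_along(p)) {
      # nearest shallower profiled rank on this taxon's lineage
      for (k2 in rev(seq_len(k - 1L))) {
        anc <- tree$at_rank[idx[j], .rank_slot(ranks[k2])]
        if (!is.na(anc)) {
          if (!is.null(mass[[anc]])) mass[[anc]] <- mass[[anc]] - p[[j]]
          break
        }
      }
    }
  }
  ids <- ls(mass)
  v <- vapply(ids, function(i) mass[[i]], numeric(1))
  v[v < 0] <- 0
  v[v > 0]
}

#' Weighted UniFrac distance between two profiles
#'
#' Earth-mover's distance between the two abundance distributions placed on
#' the taxonomy, with the taxonomy as the relatedness measure and a
#' distance of 1 between consecutive official ranks. Mass annotated at an
#' internal rank sits on that node itself. Both distributions are
#' renormalised over their classified mass before transport (profiles with
#' different unclassified fractions remain comparable), and the distance is
#' accumulated by the bottom-up traversal that pushes each node's signed
#' surplus to its parent.
#'
#' @param p1,p2 \code{tax_profile}s on the same taxonomy.
#' @param tree a \code{taxonomy}.
#' @param edge_unit \code{"rank"} (default) counts one unit per official
#'   rank step between a node and its nearest official-rank ancestor;
#'   \code{"node"} counts every intervening taxonomy node.
#' @return Nonnegative distance (0 iff the classified distributions agree).
#' @export
weighted_unifrac <- function(p1, p2, tree, edge_unit = c("rank", "node")) {
  edge_unit <- match.arg(edge_unit)
  m1 <- .profile_node_mass(p1, tree)
  m2 <- .profile_node_mass(p2, tree)
  if (sum(m1) <= 0 || sum(m2) <= 0)
    stop("cannot compare a profile with zero classified mass")
  m1 <- m1 / sum(m1); m2 <- m2 / sum(m2)

  nodes <- union(names(m1), names(m2))
  res <- stats::setNames(rep(0, length(nodes)), nodes)
  res[names(m1)] <- m1
  res[names(m2)] <- res[names(m2)] - m2

  # close the node set over parents up to the root
  parent_of <- new.env(parent = emptyenv())
  edge_len <- new.env(parent = emptyenv())
  queue <- nodes
  root_id <- tree$ids[tree$root]
  while (length(queue)) {
    nxt <- character(0)
    for (node in queue) {
      if (node == root_id || !is.null(parent_of[[node]])) next
      i <- .tx_index(tree, node)
      k <- match(.rank_slot(tree$rank[i]), .RANKS)
      if (is.na(k)) stop("profile mass on non-official-rank node ", node)
      anc <- NA_character_; k2 <- k - 1L
      while (k2 >= 1L) {
        anc <- tree$at_rank[i, k2]
        if (!is.na(anc)) break
        k2 <- k2 - 1L
      }
      parent_of[[node]] <- anc
      edge_len[[node]] <- if (edge_unit == "rank") k - k2
        else tree$depth[i] - tree$depth[.tx_index(tree, anc)]
      if (!anc %in% names(res)) {
        res[anc] <- 0
        nxt <- c(nxt, anc)
      }
    }
    queue <- nxt
  }

  all_nodes <- names(res)
  slot_idx <- vapply(all_nodes, function(node) {
    match(.rank_slot(tree$rank[.tx_index(tree, node)]), .RANKS)
  }, integer(1))
  slot_idx[all_nodes == root_id] <- 1L
  dist <- 0
  for (node in all_nodes[order(-slot_idx)]) {
    if (node == root_id) next
    dist <- dist + abs(res[[node]]) * edge_len[[node]]
    res[[parent_of[[node]]]] <- res[[parent_of[[node]]]] + res[[node]]
  }
  if (abs(res[[root_id]]) > 1e-6)
    stop("mass mismatch after normalisation: ", res[[root_id]])
  dist
}

#' Rarefaction of detected taxa over subsampled read fractions
#'
#' Randomly subsamples the annotated reads without replacement at each
#' fraction, rebuilds the profile on the subsample's own denominator,
#' optionally applies the minimum-abundance cut-off, and counts detected
#' taxa at the given rank. Curves that keep climbing at full depth signal
#' spurious detections; levelling off signals robustness.
#'
#' @param annotations data.frame of per-read annotations (as from
#'   \code{integrate_reads}).
#' @param tree a \code{taxonomy}.
#' @param fractions percentages of reads to sample (in (0, 100]).
#' @param repeats subsamples per fraction.
#' @param rank rank at which taxa are counted.
#' @param cutoff optional minimum-abundance cut-off, evaluated on the
#'   subsample's own read total.
#' @param seed integer seed; fixed seeds give identical tables.
#' @return data.frame with fraction, repeat index, reads sampled and taxa
#'   detected.
#' @export
rarefaction <- function(annotations, tree,
                        fractions = c(1, 5, 10, 20, 30, 40, 50, 60, 70,
                                      80, 90, 100),
                        repeats = 10, rank = "species", cutoff = NULL,
                        seed = NULL) {
  if (any(fractions <= 0 | fractions > 100))
    stop("fractions must lie in (0, 100]")
  n <- nrow(annotations)
  with_seed(seed, {
    out <- list()
    for (f in fractions) {
      m <- max(1L, round(f / 100 * n))
      for (rep_i in seq_len(repeats)) {
        idx <- if (m == n) seq_len(n) else sample.int(n, m)
        prof <- build_profile(annotations[idx, , drop = FALSE], tree,
                              total_reads = m, ranks = rank)
        if (!is.null(cutoff)) prof <- apply_min_abundance(prof, cutoff)
        p <- prof$per_rank[[rank]]
        out[[length(out) + 1L]] <-
          data.frame(fraction = f, rep = rep_i, n_reads = m,
                     n_taxa = sum(p > 0))
      }
    }
    do.call(rbind, out)
  })
}

#' Plot rarefaction curves
#'
#' Mean detected-taxa count per sampled fraction with the min-max band
#' across repeats.
#'
#' @param tab data.frame from \code{rarefaction}.
#' @param ... passed to \code{plot}.
#' @export
plot_rarefaction <- function(tab, ...) {
  agg <- stats::aggregate(n_taxa ~ fraction, tab, mean)
  lo <- stats::aggregate(n_taxa ~ fraction, tab, min)
  hi <- stats::aggregate(n_taxa ~ fraction, tab, max)
  graphics::plot(agg$fraction, agg$n_taxa, type = "b", pch = 16,
                 xlab = "reads sampled (%)", ylab = "taxa detected",
                 ylim = range(c(lo$n_taxa, hi$n_taxa)), ...)
  nz <- hi$n_taxa > lo$n_taxa
  if (any(nz))
    graphics::arrows(agg$fraction[nz], lo$n_taxa[nz], agg$fraction[nz],
                     hi$n_taxa[nz], angle = 90, code = 3, length = 0.03,
                     col = "grey50")
  invisible(agg)
}
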