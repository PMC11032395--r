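# Per-rank relative-abundance profiles: construction from read
# annotations, the per-rank minimum-abundance cut-off, genome-size
# normalisation, and a lossless text serialisation.

#' Construct a taxonomic profile
#'
#' Low-level constructor; most users build profiles from read annotations
#' with \code{build_profile}. Validates that all fractions are in [0,1] and
#' that classified plus unclassified mass never exceeds 1 at any rank.
#'
#' @param per_rank named list, one element per official rank, each a named
#'   numeric vector taxon_id -> fraction of total reads.
#' @param total_reads total sequenced reads (the normalising denominator).
#' @param unclassified fraction of reads with no annotation at all.
#' @return Object of class \code{tax_profile}.
#' @export
tax_profile <- function(per_rank, total_reads, unclassified = 0) {
  ranks <- names(per_rank)
  bad <- setdiff(ranks, official_ranks())
  if (length(bad)) stop("unknown rank(s) in profile: ",
                        paste(bad, collapse = ", "))
  for (r in ranks) {
    p <- per_rank[[r]]
    if (length(p) && (any(p < 0) || any(p > 1)))
      stop("fractions at rank ", r, " outside [0, 1]")
    if (sum(p) + unclassified > 1 + 1e-9)
      stop("classified + unclassified mass exceeds 1 at rank ", r)
  }
  structure(list(per_rank = per_rank, total_reads = total_reads,
                 unclassified = unclassified),
            class = "tax_profile")
}

#' @export
print.tax_profile <- function(x, ...) {
  cat("Taxonomic profile: ", x$total_reads, " reads, ",
      sprintf("%.1f%%", 100 * x$unclassified), " unclassified\n", sep = "")
  for (r in names(x$per_rank)) {
    p <- x$per_rank[[r]]
    cat(sprintf("  %-13s %4d taxa, classified %.1f%%\n", r, length(p),
                100 * sum(p)))
  }
  invisible(x)
}

#' Build a per-rank profile from read annotations
#'
#' At each official rank a read contributes to the projection of its
#' annotation onto that rank; reads annotated above a rank contribute to
#' neither any taxon nor the unclassified pool at that rank. Abundances are
#' fractions of the total sequenced reads.
#'
#' @param annotations data.frame with \code{taxon} (NA for unclassified
#'   reads) and optionally \code{source}.
#' @param tree a \code{taxonomy}.
#' @param total_reads normalising denominator; defaults to the number of
#'   annotation records and must not be smaller than it.
#' @param ranks official ranks to profile.
#' @return A \code{tax_profile}.
#' @export
build_profile <- function(annotations, tree,
                          total_reads = nrow(annotations),
                          ranks = official_ranks()) {
  if (total_reads < nrow(annotations))
    stop("total_reads is smaller than the number of annotation records")
  taxa <- annotations$taxon
  classified <- !is.na(taxa)
  idx <- if (any(classified)) .tx_index(tree, taxa[classified]) else integer(0)
  per_rank <- stats::setNames(vector("list", length(ranks)), ranks)
  for (r in ranks) {
    proj <- tree$at_rank[idx, .rank_slot(r)]
    tab <- table(proj[!is.na(proj)])
    per_rank[[r]] <- stats::setNames(as.numeric(tab) / total_reads,
                                     names(tab))
  }
  uncl <- sum(!classified) / total_reads
  tax_profile(per_rank, total_reads, uncl)
}

#' Apply the per-rank minimum-abundance cut-off
#'
#' Removes, independently at every rank, taxa whose relative abundance is
#' strictly below the cut-off. Other ranks are untouched: reads of a
#' species removed at species rank still count towards its genus if the
#' genus itself clears the cut-off.
#'
#' @param profile a \code{tax_profile}.
#' @param cutoff minimum retained fraction (default 1e-5, i.e. 0.001\%).
#' @return The filtered \code{tax_profile}.
#' @export
apply_min_abundance <- function(profile, cutoff = 1e-5) {
  stopifnot(cutoff >= 0, cutoff < 1)
  profile$per_rank <- lapply(profile$per_rank,
                             function(p) p[p >= cutoff])
  profile
}

#' Convert sequence abundance to taxonomic abundance
#'
#' Read-fraction (sequence) abundances over-represent large genomes; this
#' divides each taxon's fraction by its mean genome size and renormalises
#' so the retained mass at each rank is unchanged. Taxa missing from the
#' size table fall back to the nearest ancestor with an entry.
#'
#' @param profile a \code{tax_profile}.
#' @param sizes named numeric vector taxon_id -> weighted mean genome size
#'   in bases (all positive).
#' @param tree optional \code{taxonomy}, required for the ancestor
#'   fallback.
#' @return The converted \code{tax_profile}.
#' @export
to_taxonomic_abundance <- function(profile, sizes, tree = NULL) {
  stopifnot(all(sizes > 0))
  size_of <- function(taxa) {
    s <- unname(sizes[taxa])
    miss <- is.na(s)
    if (any(miss)) {
      if (is.null(tree))
        stop("no genome size for taxa (and no tree for ancestor fallback): ",
             paste(taxa[miss], collapse = ", "))
      for (k in which(miss)) {
        anc <- rev(lineage(tree, taxa[k]))
        hit <- anc[!is.na(sizes[anc])][1L]
        if (is.na(hit))
          stop("no genome size on any ancestor of taxon ", taxa[k])
        s[k] <- sizes[[hit]]
      }
    }
    s
  }
  profile$per_rank <- lapply(profile$per_rank, function(p) {
    if (length(p) == 0L) return(p)
    q <- p / size_of(names(p))
    q * sum(p) / sum(q)
  })
  profile
}

#' Write a taxonomic profile to a text file
#'
#' Emits a CAMI-profiling-style table (taxon id, rank, lineage id path,
#' lineage name path, percentage) preceded by header lines carrying the
#' read total and unclassified fraction, so that
#' \code{read_profile} reproduces the object exactly.
#'
#' @param profile a \code{tax_profile}.
#' @param path output path.
#' @param tree optional \code{taxonomy}; when given, lineage id and name
#'   paths are filled in (cosmetic; not needed for the round trip).
#' @param sample_id sample label written in the header.
#' @export
write_profile <- function(profile, path, tree = NULL,
                          sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("@SampleID:", sample_id),
               paste0("@TotalReads:", format(profile$total_reads)),
               paste0("@Unclassified:",
                      sprintf("%.17g", profile$unclassified)),
               paste0("@Ranks:", paste(names(profile$per_rank),
                                       collapse = "|")),
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE"), con)
  for (r in names(profile$per_rank)) {
    p <- profile$per_rank[[r]]
    for (tx in names(p)) {
      if (!is.null(tree)) {
        lin <- lineage(tree, tx)
        path_ids <- paste(lin, collapse = "|")
        path_names <- paste(tree$name[.tx_index(tree, lin)], collapse = "|")
      } else {
        path_ids <- tx; path_names <- tx
      }
      writeLines(sprintf("%s\t%s\t%s\t%s\t%.17g", tx, r, path_ids,
                         path_names, 100 * p[[tx]]), con)
    }
  }
  invisible(path)
}

#' Read a taxonomic profile written by \code{write_profile}
#'
#' @param path path to the profile file.
#' @return A \code{tax_profile}; malformed rows or out-of-range
#'   percentages raise an error naming the line.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  total <- NA_real_; uncl <- 0; ranks <- character(0)
  body_start <- NA_integer_
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (startsWith(l, "@TotalReads:"))
      total <- as.numeric(sub("@TotalReads:", "", l))
    else if (startsWith(l, "@Unclassified:"))
      uncl <- as.numeric(sub("@Unclassified:", "", l))
    else if (startsWith(l, "@Ranks:"))
      ranks <- strsplit(sub("@Ranks:", "", l), "|", fixed = TRUE)[[1L]]
    else if (startsWith(l, "@@")) { body_start <- i + 1L; break }
  }
  if (is.na(body_start)) stop("no @@ column header found in ", path)
  per_rank <- stats::setNames(
    lapply(ranks, function(r) stats::setNames(numeric(0), character(0))),
    ranks)
  for (i in seq(body_start, length.out = length(lines) - body_start + 1L)) {
    l <- lines[i]
    if (!nzchar(l)) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 5L) stop("line ", i, ": expected 5 columns")
    pct <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(pct) || pct < 0 || pct > 100)
      stop("line ", i, ": percentage outside [0, 100]")
    if (!f[2L] %in% ranks) stop("line ", i, ": rank not declared in header")
    per_rank[[f[2L]]][f[1L]] <- pct / 100
  }
  tax_profile(per_rank, total, uncl)
}
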