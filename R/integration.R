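# Read-to-contig mapping intake, MAPQ filtering, and the priority cascade
# that gives every read its most reliable taxonomic signal:
# MAG > contig (voted) > contig (direct) > direct read annotation.

# Run code under a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards; a NULL seed leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Read read-to-contig mappings
#'
#' Accepts either SAM (parsed through Rsamtools; the primary flag and MAPQ
#' fields are honoured, unmapped records dropped) or a simplified 4-column
#' TSV dialect: read_id, contig_id, is_primary (0/1), mapq.
#'
#' @param path path to a .sam file or mapping TSV.
#' @return data.frame with \code{read_id}, \code{contig_id},
#'   \code{is_primary} (logical), \code{mapq} (integer).
#' @export
read_mappings <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("Rsamtools is required to read SAM input")
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
    res <- Rsamtools::scanBam(bam,
      param = Rsamtools::ScanBamParam(
        what = c("qname", "rname", "mapq", "flag")))[[1L]]
    mapped <- bitwAnd(res$flag, 4L) == 0L
    flag <- res$flag[mapped]
    primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
    return(data.frame(read_id = res$qname[mapped],
                      contig_id = as.character(res$rname[mapped]),
                      is_primary = primary,
                      mapq = as.integer(res$mapq[mapped])))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4L) stop("mapping TSV needs 4 columns: ", path)
  data.frame(read_id = as.character(dt[[1L]]),
             contig_id = as.character(dt[[2L]]),
             is_primary = as.integer(dt[[3L]]) == 1L,
             mapq = as.integer(dt[[4L]]))
}

#' Filter mappings and assign each read one contig
#'
#' Keeps only primary mappings with MAPQ at or above the threshold
#' (default Phred 2). A read left with several surviving mappings keeps the
#' highest-MAPQ one; exact MAPQ ties are broken by a seeded random draw, so
#' reruns with the same seed reproduce the same assignment.
#'
#' @param mappings data.frame as from \code{read_mappings}.
#' @param min_mapq minimum acceptable MAPQ (mappings strictly below are
#'   dropped).
#' @param seed integer seed for the tie-break draw.
#' @return Named character vector read_id -> contig_id (reads with no
#'   surviving mapping are absent).
#' @export
filter_and_assign_mappings <- function(mappings, min_mapq = 2L,
                                       seed = NULL) {
  m <- mappings[mappings$is_primary & mappings$mapq >= min_mapq, ,
                drop = FALSE]
  if (nrow(m) == 0L) return(stats::setNames(character(0), character(0)))
  # canonical order so the tie-break is independent of input row order
  m <- m[order(m$read_id, m$contig_id), , drop = FALSE]
  tie <- with_seed(seed, stats::runif(nrow(m)))
  ord <- order(m$read_id, -m$mapq, tie)
  m <- m[ord, , drop = FALSE]
  first <- !duplicated(m$read_id)
  stats::setNames(m$contig_id[first], m$read_id[first])
}

.SOURCES <- c("mag", "contig_cat", "contig_direct", "read_direct",
              "unclassified")

# Coerce an annotation data.frame (sequence_id/query_id + taxon) or an
# already-named vector into a named taxon vector; NA entries are dropped
# (unannotated sequences fall through the cascade).
.ann_map <- function(x) {
  if (is.null(x)) return(stats::setNames(character(0), character(0)))
  if (is.data.frame(x)) {
    key <- if ("sequence_id" %in% names(x)) x$sequence_id else x$query_id
    x <- stats::setNames(as.character(x$taxon), key)
  }
  x[!is.na(x)]
}

#' Integrate per-read taxonomic signals by priority
#'
#' Each read receives the first available annotation along the priority
#' order MAG > voted contig > direct contig > direct read; reads with no
#' applicable signal are unclassified. Mode \code{"mc"} uses only MAG and
#' voted-contig evidence (direct annotations are skipped); mode \code{"cr"}
#' ignores MAG annotations. A read on a binned contig whose MAG carries no
#' annotation falls through to the contig's own annotation.
#'
#' @param assignment named character vector read_id -> contig_id (from
#'   \code{filter_and_assign_mappings}); unmapped reads are simply absent.
#' @param bin_map named character vector contig_id -> bin_id.
#' @param mag_annotations,contig_cat_annotations,contig_direct_annotations
#'   annotation tables (data.frame with sequence_id/taxon) or named taxon
#'   vectors keyed by bin or contig id.
#' @param read_direct_annotations annotation table or named vector keyed by
#'   read id.
#' @param read_ids the full read universe; every id appears exactly once in
#'   the output.
#' @param mode one of \code{"mcr"}, \code{"mc"}, \code{"cr"}.
#' @return data.frame with \code{read_id}, \code{taxon} (NA iff
#'   unclassified), \code{source}.
#' @export
integrate_reads <- function(assignment, bin_map,
                            mag_annotations = NULL,
                            contig_cat_annotations = NULL,
                            contig_direct_annotations = NULL,
                            read_direct_annotations = NULL,
                            read_ids,
                            mode = c("mcr", "mc", "cr")) {
  mode <- match.arg(mode)
  mag_ann <- .ann_map(mag_annotations)
  cat_ann <- .ann_map(contig_cat_annotations)
  dir_ann <- .ann_map(contig_direct_annotations)
  read_ann <- .ann_map(read_direct_annotations)

  n <- length(read_ids)
  taxon <- rep(NA_character_, n)
  source <- rep("unclassified", n)

  contig <- unname(assignment[read_ids])
  bin <- unname(bin_map[contig])

  claim <- function(tx, src) {
    sel <- is.na(taxon) & !is.na(tx)
    taxon[sel] <<- tx[sel]
    source[sel] <<- src
  }
  if (mode != "cr") claim(unname(mag_ann[bin]), "mag")
  claim(unname(cat_ann[contig]), "contig_cat")
  if (mode != "mc") {
    claim(unname(dir_ann[contig]), "contig_direct")
    claim(unname(read_ann[read_ids]), "read_direct")
  }
  data.frame(read_id = read_ids, taxon = taxon,
             source = factor(source, levels = .SOURCES))
}

#' Write per-read annotations as TSV
#'
#' Columns: read id, source, taxon id, root-to-taxon lineage (ids joined by
#' ";"); unclassified reads carry "NA" in the last two columns.
#'
#' @param annotations data.frame from \code{integrate_reads}.
#' @param tree a \code{taxonomy}.
#' @param path output path.
#' @export
write_read_annotations <- function(annotations, tree, path) {
  lin <- rep(NA_character_, nrow(annotations))
  ok <- !is.na(annotations$taxon)
  if (any(ok)) {
    utax <- unique(annotations$taxon[ok])
    ulin <- vapply(utax, function(t) paste(lineage(tree, t), collapse = ";"),
                   "")
    lin[ok] <- ulin[match(annotations$taxon[ok], utax)]
  }
  utils::write.table(
    data.frame(read_id = annotations$read_id,
               source = as.character(annotations$source),
               taxon_id = annotations$taxon, lineage = lin),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
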