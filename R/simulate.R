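# Seeded synthetic-community simulator: random taxonomies, log-normal
# communities, read/contig/bin structures and noisy hit tables with full
# ground truth, emulating a CAMI-style evaluation setting without external
# aligners or reference databases.

#' Simulate a random taxonomy
#'
#' Builds a rooted tree with every official rank populated on every
#' root-to-species lineage. Species are grouped bottom-up: each level holds
#' roughly \code{1/fanout} as many nodes as the one below, and every parent
#' receives at least one child. Deterministic under the seed.
#'
#' @param seed integer seed.
#' @param n_species number of species leaves.
#' @param fanout mean number of children per internal node.
#' @return A \code{taxonomy}.
#' @export
make_taxonomy <- function(seed, n_species = 50, fanout = 3) {
  stopifnot(n_species >= 1, fanout >= 1)
  if (n_species > fanout^7)
    stop("n_species exceeds the capacity of the requested fanout")
  levels <- c("superkingdom", "phylum", "class", "order", "family",
              "genus", "species")
  prefix <- c("sk", "p", "c", "o", "f", "g", "s")
  with_seed(seed, {
    ids <- "1"; parents <- "1"; ranks <- "root"
    child_ids <- paste0("s", seq_len(n_species))
    counts <- n_species
    # nodes per level, species upward
    for (k in 6:1) counts <- c(max(1L, ceiling(counts[1L] / fanout)), counts)
    level_ids <- lapply(seq_along(levels),
                        function(k) paste0(prefix[k], seq_len(counts[k])))
    for (k in seq_along(levels)) {
      np <- if (k == 1L) 1L else counts[k - 1L]
      parent_pool <- if (k == 1L) "1" else level_ids[[k - 1L]]
      nch <- counts[k]
      # every parent gets one child, the rest are placed at random
      assign <- c(seq_len(min(np, nch)),
                  if (nch > np) sample.int(np, nch - np, replace = TRUE))
      ids <- c(ids, level_ids[[k]])
      parents <- c(parents, parent_pool[assign])
      ranks <- c(ranks, rep(levels[k], nch))
    }
    taxonomy_tree(ids, parents, ranks)
  })
}

#' Sample log-normal community abundances
#'
#' Species relative abundances are drawn from a log-normal distribution
#' (the standard model for microbial community structure) and normalised
#' to sum to 1; \code{sigma = 0} degenerates to a uniform community.
#'
#' @param tree a \code{taxonomy}.
#' @param mu,sigma log-normal parameters on the log scale.
#' @param seed integer seed.
#' @return Named numeric vector species id -> fraction, summing to 1.
#' @export
sample_community <- function(tree, mu = 1, sigma = 1.5, seed = NULL) {
  species <- tree$ids[tree$rank == "species"]
  if (length(species) == 0L) stop("taxonomy has no species nodes")
  with_seed(seed, {
    ab <- if (sigma == 0) rep(1, length(species))
          else stats::rlnorm(length(species), mu, sigma)
    stats::setNames(ab / sum(ab), species)
  })
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic dataset: community size and shape,
#' how much of the data assembles and bins, how novel the community is
#' relative to the reference, and how noisy direct read hits are.
#'
#' @param seed integer master seed; every artifact is deterministic
#'   under it.
#' @param n_species community size (species count).
#' @param mu,sigma log-normal abundance parameters.
#' @param n_reads total sequenced reads.
#' @param assembled_fraction share of reads that map to a contig.
#' @param binned_fraction share a contig is binned with, so the expected
#'   MAG-mapped read share is \code{assembled_fraction * binned_fraction}.
#' @param novel_fraction share of species without a reference
#'   representative; their hits scatter among sister taxa and their
#'   sequences can only be annotated at genus rank or above.
#' @param hit_noise probability that a direct read hit's subject is drawn
#'   from an unrelated clade (a species under a different genus).
#' @param orfs_per_contig inclusive range of ORFs called per contig.
#' @param contigs_per_species contigs assembled per species.
#' @param contamination probability a binned contig lands in another
#'   species' bin, for stress-testing the voting escalation.
#' @return List of class \code{sim_config}.
#' @export
simulation_config <- function(seed, n_species = 50, mu = 1, sigma = 1.5,
                              n_reads = 10000, assembled_fraction = 0.8,
                              binned_fraction = 0.6, novel_fraction = 0,
                              hit_noise = 0, orfs_per_contig = c(2L, 5L),
                              contigs_per_species = 3L,
                              contamination = 0) {
  fracs <- c(assembled_fraction, binned_fraction, novel_fraction,
             hit_noise, contamination)
  stopifnot(all(fracs >= 0), all(fracs <= 1), n_species >= 1, n_reads >= 1)
  structure(list(seed = as.integer(seed), n_species = n_species, mu = mu,
                 sigma = sigma, n_reads = n_reads,
                 assembled_fraction = assembled_fraction,
                 binned_fraction = binned_fraction,
                 novel_fraction = novel_fraction, hit_noise = hit_noise,
                 orfs_per_contig = orfs_per_contig,
                 contigs_per_species = contigs_per_species,
                 contamination = contamination),
            class = "sim_config")
}

# For a novel species, the hit subjects that stand in for its missing
# reference: at least two distinct relatives (nearest sisters first), so
# the LCA of any hit set lands at genus rank or above. With no relative at
# all the species' own genus is used as a subject, which pins the LCA at
# genus directly.
.novel_subjects <- function(tree, sp, species_ids) {
  g <- taxon_at_rank(tree, sp, "genus")
  sisters <- setdiff(
    species_ids[taxon_at_rank(tree, species_ids, "genus") == g], sp)
  if (length(sisters) >= 2L) return(sisters)
  fam <- taxon_at_rank(tree, sp, "family")
  cousins <- setdiff(
    species_ids[taxon_at_rank(tree, species_ids, "family") == fam], sp)
  subj <- unique(c(sisters, cousins))
  if (length(subj) >= 2L) return(subj)
  unique(c(subj, g))
}

#' Simulate a full dataset with ground truth
#'
#' Draws a community, assigns every read its true species, assembles a
#' configurable share of reads onto pure per-species contigs, bins a share
#' of contigs into per-species MAGs, and writes homology hit tables for
#' ORFs, contigs and reads. Novel species receive sister-scattered hits
#' (annotatable only at genus rank or above); direct read hits are
#' corrupted with the configured noise probability. Everything is
#' deterministic under the config seed.
#'
#' @param config a \code{sim_config}.
#' @return List with \code{tree}, \code{config}, \code{mappings} (read
#'   mapping records), \code{bin_map}, \code{orf_hits},
#'   \code{contig_hits}, \code{read_hits}, \code{truth_reads} (named
#'   read -> species), \code{truth_profile} (realised per-rank profile),
#'   \code{contig_truth}, \code{community}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- make_taxonomy(config$seed, config$n_species)
  community <- sample_community(tree, config$mu, config$sigma,
                                seed = config$seed + 1L)
  species <- names(community)
  with_seed(config$seed + 2L, {
    n <- config$n_reads
    read_ids <- sprintf("r%06d", seq_len(n))
    true_sp <- sample(species, n, replace = TRUE, prob = community)

    novel <- character(0)
    if (config$novel_fraction > 0) {
      k <- round(config$novel_fraction * length(species))
      novel <- sample(species, k)
    }

    contigs <- data.frame(
      contig_id = paste0(rep(species, each = config$contigs_per_species),
                         "_ctg", seq_len(config$contigs_per_species)),
      species = rep(species, each = config$contigs_per_species))

    # read -> contig mappings for the assembled share
    assembled <- stats::runif(n) < config$assembled_fraction
    map_contig <- rep(NA_character_, n)
    for (sp in species) {
      sel <- which(assembled & true_sp == sp)
      if (length(sel))
        map_contig[sel] <- sample(
          contigs$contig_id[contigs$species == sp], length(sel),
          replace = TRUE)
    }
    mappings <- data.frame(
      read_id = read_ids[assembled], contig_id = map_contig[assembled],
      is_primary = rep(TRUE, sum(assembled)),
      mapq = sample(30:60, sum(assembled), replace = TRUE))

    # bins: pure per-species MAGs, with an optional contamination knob
    binned <- stats::runif(nrow(contigs)) < config$binned_fraction
    bin_of <- paste0("bin_", contigs$species)
    if (config$contamination > 0) {
      flip <- binned & stats::runif(nrow(contigs)) < config$contamination
      if (any(flip))
        bin_of[flip] <- paste0("bin_",
                               sample(species, sum(flip), replace = TRUE))
    }
    bin_map <- stats::setNames(bin_of[binned], contigs$contig_id[binned])

    # ORF hit tables: true-species hits, or sister-scattered for novel
    orf_rows <- vector("list", nrow(contigs))
    subj_cache <- lapply(stats::setNames(nm = novel), .novel_subjects,
                         tree = tree, species_ids = species)
    orf_rng <- as.integer(config$orfs_per_contig)
    for (ci in seq_len(nrow(contigs))) {
      k <- orf_rng[1L] + sample.int(orf_rng[2L] - orf_rng[1L] + 1L, 1L) - 1L
      orf_ids <- paste0(contigs$contig_id[ci], "_", seq_len(k))
      sp <- contigs$species[ci]
      if (sp %in% novel) {
        subj <- subj_cache[[sp]]
        rows <- lapply(seq_len(k), function(i) {
          take <- if (length(subj) > 2L)
            sample(subj, 1L + sample.int(min(3L, length(subj)) - 1L, 1L))
          else subj
          data.frame(query_id = orf_ids[i], subject_taxon = take,
                     bit_score = stats::runif(length(take), 95, 100))
        })
        orf_rows[[ci]] <- do.call(rbind, rows)
      } else {
        orf_rows[[ci]] <- data.frame(
          query_id = orf_ids, subject_taxon = sp,
          bit_score = stats::runif(k, 90, 110))
      }
    }
    orf_hits <- do.call(rbind, orf_rows)

    # direct (blastx-style) contig hits: one hit set per contig
    contig_rows <- lapply(seq_len(nrow(contigs)), function(ci) {
      sp <- contigs$species[ci]
      if (sp %in% novel) {
        subj <- subj_cache[[sp]]
        data.frame(query_id = contigs$contig_id[ci], subject_taxon = subj,
                   bit_score = stats::runif(length(subj), 95, 100))
      } else {
        data.frame(query_id = contigs$contig_id[ci], subject_taxon = sp,
                   bit_score = stats::runif(1L, 90, 110))
      }
    })
    contig_hits <- do.call(rbind, contig_rows)

    # direct read hits: true species, corrupted with probability
    # hit_noise by a species under a different genus
    subject <- true_sp
    noisy <- stats::runif(n) < config$hit_noise
    if (any(noisy)) {
      genus <- taxon_at_rank(tree, true_sp[noisy], "genus")
      subject[noisy] <- vapply(genus, function(g) {
        pool <- species[taxon_at_rank(tree, species, "genus") != g]
        if (length(pool) == 0L) pool <- species
        pool[sample.int(length(pool), 1L)]
      }, "")
    }
    novel_read <- true_sp %in% novel & !noisy
    if (any(novel_read))
      subject[novel_read] <- vapply(true_sp[novel_read], function(sp) {
        s <- subj_cache[[sp]]
        s[sample.int(length(s), 1L)]
      }, "")
    read_hits <- data.frame(query_id = read_ids, subject_taxon = subject,
                            bit_score = stats::runif(n, 50, 100))

    truth_reads <- stats::setNames(true_sp, read_ids)
    truth_profile <- build_profile(
      data.frame(read_id = read_ids, taxon = true_sp), tree,
      total_reads = n)
    list(tree = tree, config = config, mappings = mappings,
         bin_map = bin_map, orf_hits = orf_hits,
         contig_hits = contig_hits, read_hits = read_hits,
         truth_reads = truth_reads, truth_profile = truth_profile,
         contig_truth = stats::setNames(contigs$species,
                                        contigs$contig_id),
         novel_species = novel, community = community)
  })
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits exactly the dialects the pipeline consumes: NCBI-style taxonomy
#' dumps, the 4-column mapping TSV, contig-to-bin TSV, hit-table TSVs for
#' ORFs/contigs/reads, the per-read truth TSV and the truth profile.
#'
#' @param sim result of \code{simulate_dataset}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_fixture_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ncbi_taxonomy(sim$tree, dir)
  p <- c(mappings = file.path(dir, "mappings.tsv"),
         bins = file.path(dir, "contig2bin.tsv"),
         orf = file.path(dir, "orf_hits.tsv"),
         contig = file.path(dir, "contig_hits.tsv"),
         read = file.path(dir, "read_hits.tsv"),
         truth_reads = file.path(dir, "truth_reads.tsv"),
         truth_profile = file.path(dir, "truth_profile.tsv"))
  utils::write.table(
    data.frame(sim$mappings$read_id, sim$mappings$contig_id,
               as.integer(sim$mappings$is_primary), sim$mappings$mapq),
    p[["mappings"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    data.frame(names(sim$bin_map), unname(sim$bin_map)), p[["bins"]],
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (nm in c("orf", "contig", "read")) {
    h <- sim[[paste0(nm, "_hits")]]
    utils::write.table(
      data.frame(h$query_id, h$subject_taxon,
                 sprintf("%.6f", h$bit_score)),
      p[[nm]], sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  utils::write.table(
    data.frame(names(sim$truth_reads), unname(sim$truth_reads)),
    p[["truth_reads"]], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_profile(sim$truth_profile, p[["truth_profile"]], sim$tree,
                sample_id = paste0("sim_seed", sim$config$seed))
  invisible(c(p, nodes = file.path(dir, "nodes.dmp"),
              names = file.path(dir, "names.dmp")))
}

#' Run the full annotation workflow on in-memory inputs
#'
#' Convenience wrapper chaining mapping assignment, per-query LCA
#' annotation, contig/MAG voting, priority integration and profiling.
#'
#' @param sim result of \code{simulate_dataset} (or a list with the same
#'   elements).
#' @param mode integration mode: \code{"mcr"}, \code{"mc"} or \code{"cr"}.
#' @param r bit-score window fraction.
#' @param f voting support threshold.
#' @param min_mapq minimum accepted MAPQ.
#' @param cutoff minimum-abundance cut-off applied to the final profile
#'   (NULL skips it).
#' @param seed seed for the mapping tie-break (defaults to the sim seed).
#' @return List with \code{annotations} (per read), \code{profile} (after
#'   cut-off), \code{raw_profile} (before cut-off) and the intermediate
#'   annotation tables.
#' @export
run_workflow <- function(sim, mode = "mcr", r = 0.10, f = 0.5,
                         min_mapq = 2L, cutoff = 1e-5, seed = NULL) {
  tree <- sim$tree
  if (is.null(seed)) seed <- sim$config$seed
  assignment <- filter_and_assign_mappings(sim$mappings, min_mapq, seed)
  orf_ann <- annotate_queries(sim$orf_hits, tree, r)
  contig_cat <- annotate_contigs(orf_ann, tree, f)
  mag_ann <- annotate_mags(orf_ann, sim$bin_map, tree, f)
  contig_direct <- annotate_queries(sim$contig_hits, tree, r)
  read_direct <- annotate_queries(sim$read_hits, tree, r)
  ann <- integrate_reads(assignment, sim$bin_map, mag_ann, contig_cat,
                         contig_direct, read_direct,
                         read_ids = names(sim$truth_reads), mode = mode)
  raw <- build_profile(ann, tree, total_reads = length(sim$truth_reads))
  profile <- if (is.null(cutoff)) raw else apply_min_abundance(raw, cutoff)
  list(annotations = ann, profile = profile, raw_profile = raw,
       assignment = assignment, orf_annotations = orf_ann,
       contig_cat = contig_cat, mag_annotations = mag_ann,
       contig_direct = contig_direct, read_direct = read_direct)
}
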