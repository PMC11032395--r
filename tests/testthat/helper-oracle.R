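# Independent reference computations for the weighted-UniFrac checks.

# Transportation-LP reference values, via one batched call to scipy's
# linprog (min-cost flow on the dense cost matrix).
lp_unifrac_oracle <- function(instances) {
  payload <- list(instances = lapply(instances, function(x) {
    list(cost = x$cost, a = as.numeric(x$a), b = as.numeric(x$b))
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = FALSE, digits = NA,
                       matrix = "rowmajor")
  status <- system2("python", c(test_path("emd-lp-oracle.py"), fin, fout))
  stopifnot(status == 0L)
  as.numeric(jsonlite::read_json(fout, simplifyVector = TRUE))
}

# Pairwise rank-step distances between taxa via shortest paths on the
# taxonomy's parent edges; independent of the bottom-up EMD traversal.
rank_step_dist <- function(tree, from, to) {
  g <- igraph::graph_from_edgelist(
    cbind(tree$ids[tree$parent], tree$ids)[-tree$root, , drop = FALSE],
    directed = FALSE)
  igraph::distances(g, v = from, to = to)
}

random_profile <- function(tree, n = 120) {
  build_profile(random_annotations(tree, n, p_unclassified = 0.15), tree)
}
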