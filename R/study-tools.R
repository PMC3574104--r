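# The MI-based associated-gene prediction program, edge-similarity metrics,
# the split/merge validation harness, and the MI-connectivity analysis.

#' Predict genes associated with a known pathway gene set
#'
#' For every (known gene g, candidate gene r) pair the mutual information
#' I(g; r) is computed; pairs exceeding `delta_mi` are reported, sorted by
#' MI descending. A candidate is reported once per known gene it clears the
#' threshold with.
#'
#' @param data A `discrete_dataset` containing all genes.
#' @param known Character vector of pathway genes (set G).
#' @param candidates Character vector of candidate genes (disjoint from
#'   `known`).
#' @param delta_mi MI threshold (nats).
#' @return data.frame with columns `known_gene`, `candidate_gene`, `mi`,
#'   sorted by `mi` descending.
#' @export
predict_associated_genes <- function(data, known, candidates,
                                     delta_mi = bn_thresholds()$delta_mi) {
  if (length(intersect(known, candidates)))
    stop("known and candidate gene sets must be disjoint")
  check_vars_present(data, c(known, candidates))
  res <- list()
  for (g in known) {
    for (r in candidates) {
      mi <- mutual_information(data, g, r)
      if (mi > delta_mi) {
        res[[length(res) + 1L]] <- data.frame(known_gene = g,
                                              candidate_gene = r, mi = mi)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(known_gene = character(0), candidate_gene = character(0),
                      mi = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(-out$mi, out$known_gene, out$candidate_gene), , drop = FALSE]
}

#' Directed-edge similarity of two DAGs
#'
#' Dice form: 2 |E_A intersect E_B| / (|E_A| + |E_B|) over directed edges
#' (the proportion of identical edges to the total edge count of the two
#' graphs). Two empty graphs have similarity 1. `method = "jaccard"` gives
#' |intersection| / |union| instead.
#'
#' @param dagA,dagB `bn_dag` objects over the same node set.
#' @param method "dice" (default) or "jaccard".
#' @return A value in [0, 1].
#' @export
edge_similarity <- function(dagA, dagB, method = c("dice", "jaccard")) {
  method <- match.arg(method)
  if (!setequal(dagA$nodes, dagB$nodes)) stop("node sets differ")
  ka <- edge_keys(dagA$edges)
  kb <- edge_keys(dagB$edges)
  if (!length(ka) && !length(kb)) return(1)
  inter <- length(intersect(ka, kb))
  if (method == "dice") 2 * inter / (length(ka) + length(kb))
  else inter / length(union(ka, kb))
}

#' Edge diff of a learned DAG against the truth
#'
#' @param true_dag,learned_dag `bn_dag` objects over the same node set.
#' @return Named vector: `n_edges` (learned edge count), `n_missing`
#'   (true edges absent), `n_extra` (learned edges not in the truth);
#'   directed comparison.
#' @export
edge_diff <- function(true_dag, learned_dag) {
  if (!setequal(true_dag$nodes, learned_dag$nodes)) stop("node sets differ")
  kt <- edge_keys(true_dag$edges)
  kl <- edge_keys(learned_dag$edges)
  c(n_edges = length(kl),
    n_missing = length(setdiff(kt, kl)),
    n_extra = length(setdiff(kl, kt)))
}

#' Split/merge validation experiment
#'
#' Per run: the dataset is split at random into D1 (`split_fraction`) and D2
#' (rest); networks B1 and B2 are learned from the parts and combined with
#' their sample counts as weights into B3; a reference B4 is learned from
#' the full dataset; the directed-edge similarity of B3 and B4 is recorded.
#'
#' @param data A `discrete_dataset`.
#' @param runs Number of runs (>= 1).
#' @param split_fraction Fraction put in D1, in (0, 1); default 0.25.
#' @param thresholds A [bn_thresholds()].
#' @param seed Integer seed; identical seeds give identical reports.
#' @param epsilon_var Variance threshold used in the combination.
#' @param keep_networks When TRUE the per-run consensus networks are
#'   returned too (used by recovery analyses).
#' @return An `experiment_report`: list with `per_run_similarity`, `mean`,
#'   `std`, `runs` (and `networks` when requested).
#' @export
split_merge_experiment <- function(data, runs = 100L, split_fraction = 0.25,
                                   thresholds = bn_thresholds(), seed = 1L,
                                   epsilon_var = thresholds$epsilon_var,
                                   keep_networks = FALSE) {
  stopifnot(runs >= 1L, split_fraction > 0, split_fraction < 1)
  n <- nrow(data)
  n1 <- round(n * split_fraction)
  if (n1 < 1L || n1 >= n) stop("split leaves an empty part")
  b4 <- learn_bn(data, thresholds) # reference: full data, runs share it
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  sims <- numeric(0)
  nets <- list()
  skipped <- 0L
  for (run in seq_len(runs)) {
    idx <- sample.int(n, n1)
    d1 <- data[idx, , drop = FALSE]
    d2 <- data[-idx, , drop = FALSE]
    if (nrow(d1) < ncol(data) || nrow(d2) < ncol(data)) {
      skipped <- skipped + 1L
      next
    }
    b1 <- learn_bn(d1, thresholds)
    b2 <- learn_bn(d2, thresholds)
    b3 <- combine(b1, b2,
                  aggregation_spec(c(nrow(d1), nrow(d2)), epsilon_var))
    sims <- c(sims, edge_similarity(b3$dag, b4$dag))
    if (keep_networks) nets[[length(nets) + 1L]] <- b3
  }
  if (skipped > 0L) message("split_merge_experiment: skipped ", skipped,
                            " run(s) with too few samples to learn")
  rep <- structure(list(per_run_similarity = sims,
                        mean = mean(sims),
                        std = stats::sd(sims),
                        runs = length(sims)),
                   class = "experiment_report")
  if (keep_networks) rep$networks <- nets
  rep
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d runs: similarity %.1f%% +/- %.1f%%\n",
              x$runs, 100 * x$mean,
              100 * ifelse(is.na(x$std), 0, x$std)))
  invisible(x)
}

#' MI-connectivity of a dataset
#'
#' Builds the undirected graph with an edge between every pair whose mutual
#' information exceeds `delta_mi` and reports the connected component sizes
#' and the fraction of variables in the largest component.
#'
#' @param data A `discrete_dataset` (>= 1 variable).
#' @param delta_mi MI threshold (nats).
#' @return List with `component_sizes` (decreasing) and `largest_fraction`.
#' @export
mi_connectivity <- function(data, delta_mi = bn_thresholds()$delta_mi) {
  vars <- names(data)
  stopifnot(length(vars) >= 1L)
  g <- ugraph(vars)
  if (length(vars) >= 2L) {
    pairs <- all_pairs_mi(data)
    pairs <- pairs[pairs$mi > delta_mi, , drop = FALSE]
    for (i in seq_len(nrow(pairs))) g <- ugraph_add(g, pairs$x[i], pairs$y[i])
  }
  left <- vars
  sizes <- integer(0)
  while (length(left)) {
    comp <- reachable_from(g$nodes, g$edges, left[[1L]], undirected = TRUE)
    comp <- union(comp, left[[1L]])
    sizes <- c(sizes, length(intersect(comp, left)))
    left <- setdiff(left, comp)
  }
  sizes <- sort(sizes, decreasing = TRUE)
  list(component_sizes = sizes, largest_fraction = sizes[1L] / length(vars))
}
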