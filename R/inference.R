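#' Topological ("prior") order of a DAG
#'
#' Every Bayesian network's DAG admits a topological order of its nodes,
#' called the prior order; parents always precede children.
#'
#' @param dag A `bn_dag`.
#' @return Character vector of node names; every edge (u, v) has u before v.
#'   Deterministic: among available nodes the lexicographically smallest is
#'   emitted first.
#' @export
topological_order <- function(dag) {
  ord <- topo_sort(dag$nodes, dag$edges)
  if (is.null(ord)) {
    cyc <- find_cycle(dag$nodes, dag$edges)
    stop("cycle detected: ", paste(cyc, collapse = " -> "))
  }
  ord
}

#' Are two DAGs' prior orders consistent?
#'
#' Two networks' variables' prior orders are consistent exactly when the
#' union graph (node union, edge union) is acyclic, i.e. one total order
#' tops both DAGs.
#'
#' @param dag1,dag2 `bn_dag` objects.
#' @return TRUE/FALSE.
#' @export
orders_consistent <- function(dag1, dag2) {
  nodes <- union(dag1$nodes, dag2$nodes)
  edges <- rbind(dag1$edges, dag2$edges)
  if (nrow(edges)) edges <- edges[!duplicated(edge_keys(edges)), , drop = FALSE]
  is_acyclic(nodes, edges)
}

#' Probability of a complete assignment
#'
#' Chain-rule product of the CPT entries selected by the assignment.
#'
#' @param bn A `bayesian_net`.
#' @param assignment Named character vector/list of states covering every node.
#' @return A probability.
#' @export
joint_probability <- function(bn, assignment) {
  assignment <- unlist(assignment)
  miss <- setdiff(bn$dag$nodes, names(assignment))
  if (length(miss)) stop("assignment missing variable(s): ",
                         paste(miss, collapse = ", "))
  p <- 1
  for (n in bn$dag$nodes) {
    cp <- bn$cpts[[n]]
    row <- cpt_row(cp, assignment)
    i <- match(assignment[[n]], cp$states[[n]])
    if (is.na(i)) stop("unknown state '", assignment[[n]], "' for '", n, "'")
    p <- p * row[i]
  }
  p
}

#' Forward-sample a dataset from a network
#'
#' Samples variables in topological order from their CPT rows; stands in for
#' external benchmark-database generators when building fixtures.
#'
#' @param bn A `bayesian_net`.
#' @param n Number of samples (>= 0).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `discrete_dataset` with `n` rows.
#' @export
forward_sample <- function(bn, n, seed) {
  stopifnot(n >= 0)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  ord <- topological_order(bn$dag)
  states <- bn_states(bn)
  out <- stats::setNames(vector("list", length(ord)), ord)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  {
    for (v in ord) {
      cp <- bn$cpts[[v]]
      r <- cpt_cardinality(cp)
      if (length(cp$parents) == 0L) {
        pv <- as.vector(cp$prob)
        check_sampling_row(pv, v)
        out[[v]] <- if (n > 0) sample.int(r, n, replace = TRUE, prob = pv) else integer(0)
      } else {
        # configuration index of each row, column-major over parent dims
        cards <- vapply(cp$parents, function(p) length(cp$states[[p]]), integer(1))
        mult <- cumprod(c(1L, cards[-length(cards)]))
        cfg <- rep(1L, n)
        for (j in seq_along(cp$parents)) {
          pj <- cp$parents[[j]]
          cfg <- cfg + (out[[pj]] - 1L) * mult[[j]]
        }
        pm <- matrix(cp$prob, nrow = r) # columns = configs
        draw <- integer(n)
        for (cfg_val in unique(cfg)) {
          rows <- which(cfg == cfg_val)
          pv <- pm[, cfg_val]
          check_sampling_row(pv, v)
          draw[rows] <- sample.int(r, length(rows), replace = TRUE, prob = pv)
        }
        out[[v]] <- draw
      }
    }
  }
  df <- as.data.frame(stats::setNames(lapply(ord, function(v) {
    factor(states[[v]][out[[v]]], levels = states[[v]])
  }), ord))
  if (n == 0L) { # keep 0-row frame with the right columns
    df <- as.data.frame(stats::setNames(lapply(ord, function(v)
      factor(character(0), levels = states[[v]])), ord))
  }
  discrete_dataset(df)
}

check_sampling_row <- function(pv, v) {
  if (any(!is.finite(pv)) || abs(sum(pv) - 1) > 1e-9 || any(pv < 0)) {
    stop("invalid CPT row for '", v, "': entries must be a distribution")
  }
}

## ---- factors for variable elimination -------------------------------------

cpt_factor <- function(cp) {
  list(vars = c(cp$child, cp$parents),
       states = cp$states,
       arr = cp$prob)
}

factor_reduce <- function(f, evidence) {
  keep <- intersect(names(evidence), f$vars)
  if (!length(keep)) return(f)
  idx <- lapply(f$vars, function(v) {
    if (v %in% keep) {
      i <- match(evidence[[v]], f$states[[v]])
      if (is.na(i)) stop("unknown state '", evidence[[v]], "' for '", v, "'")
      i
    } else TRUE
  })
  arr <- do.call(`[`, c(list(f$arr), idx, list(drop = FALSE)))
  rem <- !(f$vars %in% keep)
  if (!sum(rem)) { # all vars observed: scalar factor
    return(list(vars = character(0), states = list(), arr = as.vector(arr)))
  }
  dim(arr) <- dim(f$arr)[rem]
  list(vars = f$vars[rem], states = f$states[f$vars[rem]], arr = arr)
}

factor_product <- function(f1, f2) {
  if (!length(f1$vars)) return(list(vars = f2$vars, states = f2$states,
                                    arr = f2$arr * as.vector(f1$arr)))
  if (!length(f2$vars)) return(list(vars = f1$vars, states = f1$states,
                                    arr = f1$arr * as.vector(f2$arr)))
  uvars <- union(f1$vars, f2$vars)
  states <- c(f1$states, f2$states)[uvars]
  cards <- vapply(states, length, integer(1))
  expand <- function(f) {
    fdims <- vapply(f$states, length, integer(1))
    missing <- setdiff(uvars, f$vars)
    arr <- array(rep(as.vector(f$arr), prod(cards[missing])),
                 dim = c(fdims, cards[missing]))
    aperm(arr, match(uvars, c(f$vars, missing)))
  }
  a1 <- expand(f1)
  a2 <- expand(f2)
  list(vars = uvars, states = states, arr = array(a1 * a2, dim = cards))
}

factor_sum_out <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  if (length(f$vars) == 1L) {
    return(list(vars = character(0), states = list(), arr = sum(f$arr)))
  }
  perm <- c(seq_along(f$vars)[-i], i)
  arr <- aperm(f$arr, perm)
  d <- dim(arr)
  m <- matrix(arr, ncol = d[length(d)])
  arr2 <- array(rowSums(m), dim = d[-length(d)])
  list(vars = f$vars[-i], states = f$states[-i], arr = arr2)
}

# min-degree elimination order over the factor interaction graph
elimination_order <- function(factors, elim) {
  nbrs <- stats::setNames(lapply(elim, function(v) character(0)), elim)
  touch <- function(vs) {
    vs <- intersect(vs, elim)
    for (v in vs) nbrs[[v]] <<- union(nbrs[[v]], setdiff(vs, v))
  }
  for (f in factors) touch(f$vars)
  ord <- character(0)
  left <- elim
  while (length(left)) {
    deg <- vapply(left, function(v) length(intersect(nbrs[[v]], left)), integer(1))
    v <- sort(left[deg == min(deg)])[1L]
    nb <- intersect(nbrs[[v]], left)
    for (a in nb) nbrs[[a]] <- union(nbrs[[a]], setdiff(nb, a))
    ord <- c(ord, v)
    left <- setdiff(left, v)
  }
  ord
}

# Joint distribution over `targets` given evidence, by variable elimination.
infer_joint <- function(bn, targets, evidence = NULL) {
  evidence <- if (is.null(evidence)) character(0) else unlist(evidence)
  bad <- intersect(targets, names(evidence))
  if (length(bad)) stop("query variable(s) also in evidence: ",
                        paste(bad, collapse = ", "))
  factors <- lapply(bn$cpts, cpt_factor)
  if (length(evidence)) factors <- lapply(factors, factor_reduce, evidence = evidence)
  elim <- setdiff(bn$dag$nodes, c(targets, names(evidence)))
  for (v in elimination_order(factors, elim)) {
    involved <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(involved)) next
    prod_f <- Reduce(factor_product, factors[involved])
    factors <- c(factors[!involved], list(factor_sum_out(prod_f, v)))
  }
  res <- Reduce(factor_product, factors)
  # res may have vars in arbitrary order; put targets in requested order
  if (length(res$vars)) {
    res <- list(vars = res$vars, states = res$states,
                arr = aperm(array(res$arr,
                                  dim = vapply(res$states, length, integer(1))),
                            match(targets, res$vars)))
    res$vars <- targets
    res$states <- res$states[targets]
  }
  z <- sum(res$arr)
  if (length(targets) == 0L) return(z) # probability of the evidence itself
  if (!is.finite(z) || z <= 0) {
    stop("evidence has probability zero; conditional undefined")
  }
  arr <- res$arr / z
  arr <- array(arr, dim = vapply(res$states[targets], length, integer(1)),
               dimnames = res$states[targets])
  arr
}

#' Exact posterior distribution of one variable
#'
#' Variable elimination with a min-degree elimination order; exact, no
#' approximation. Zero-probability evidence raises an error rather than
#' returning NaN.
#'
#' @param bn A `bayesian_net`.
#' @param query Variable name (not in evidence).
#' @param evidence Named character vector/list of observed states (possibly
#'   empty/NULL).
#' @return Named probability vector over the query's states; sums to 1.
#' @export
infer_distribution <- function(bn, query, evidence = NULL) {
  stopifnot(length(query) == 1L, query %in% bn$dag$nodes)
  arr <- infer_joint(bn, query, evidence)
  stats::setNames(as.vector(arr), dimnames(arr)[[1L]])
}
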