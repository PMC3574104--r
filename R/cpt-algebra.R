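# CPT extension to a common form, weighted aggregation (linear opinion pool
# over conditionals), and variance-test simplification.

#' Aggregation specification
#'
#' @param weights Vector of positive integer beliefs, one per input network
#'   or CPT (an effective sample count; larger = more reliable).
#' @param epsilon_var Variance threshold for bogus-parent removal.
#' @param use_counts When TRUE (default) and every input CPT carries
#'   parent-configuration counts, aggregation weights each configuration by
#'   `w_i * count_i(pa) / N_i` — the exact merged-database rule; otherwise
#'   the scalar opinion-pool weights `w_i` are used for every configuration.
#' @return An `aggregation_spec`.
#' @export
aggregation_spec <- function(weights, epsilon_var = 1e-3, use_counts = TRUE) {
  weights <- as.numeric(weights)
  if (any(weights < 1 | weights != round(weights)))
    stop("weights must be positive integers")
  structure(list(weights = weights, epsilon_var = epsilon_var,
                 use_counts = isTRUE(use_counts)),
            class = "aggregation_spec")
}

# canonical ordering of a parent set: positions in `order` when supplied
# (the consensus prior order), lexicographic otherwise
canonical_parents <- function(parents, order = NULL) {
  if (is.null(order)) return(sort(parents))
  miss <- setdiff(parents, order)
  if (length(miss)) stop("parent(s) not in supplied order: ",
                         paste(miss, collapse = ", "))
  parents[order(match(parents, order), parents)]
}

bogus_tags <- function(cpt) {
  tg <- attr(cpt, "bogus", exact = TRUE)
  if (is.null(tg)) character(0) else tg
}

# re-shape a CPT's prob array so parents follow `target` order
reorder_cpt_parents <- function(cpt, target) {
  stopifnot(setequal(cpt$parents, target))
  if (identical(cpt$parents, target)) return(cpt)
  perm <- c(1L, 1L + match(target, cpt$parents))
  counts <- cpt_counts(cpt)
  if (!is.null(counts)) {
    counts <- if (length(target) > 1L) {
      aperm(array(counts, dim = dim(cpt$prob)[-1L]), match(target, cpt$parents))
    } else counts
  }
  out <- bn_cpt(cpt$child, target, cpt$states, aperm(cpt$prob, perm),
                counts = counts)
  attr(out, "bogus") <- bogus_tags(cpt)
  out
}

#' Extend a CPT with independent (bogus) parents
#'
#' If a variable B is independent of the child given the real parents,
#' P(x | pa, b) = P(x | pa): the table can be extended to include B by
#' replicating each conditional distribution unchanged across B's states.
#' Extended parents are tagged bogus (attribute `"bogus"`) so the variance
#' test can find and remove them later.
#'
#' @param cpt A `bn_cpt`.
#' @param extra_parents Character vector of new parent names, disjoint from
#'   the current parents and the child.
#' @param states Named list giving the state labels of each extra parent.
#' @param order Optional canonical node order (consensus prior order) used
#'   to fix the extended parent ordering; lexicographic when NULL.
#' @return A `bn_cpt` over `union(cpt$parents, extra_parents)`.
#' @export
extend_cpt <- function(cpt, extra_parents, states = NULL, order = NULL) {
  extra_parents <- as.character(extra_parents)
  if (!length(extra_parents)) return(cpt)
  clash <- intersect(extra_parents, c(cpt$parents, cpt$child))
  if (length(clash)) stop("extra parent overlaps CPT variables: ",
                          paste(clash, collapse = ", "))
  miss <- setdiff(extra_parents, names(states))
  if (length(miss)) stop("missing state space for extra parent(s): ",
                         paste(miss, collapse = ", "))
  all_states <- c(cpt$states, lapply(states[extra_parents], as.character))
  new_parents <- canonical_parents(c(cpt$parents, extra_parents), order)
  extra_cards <- vapply(extra_parents, function(p) length(all_states[[p]]),
                        integer(1))
  # replicate across the extra dims (appended last), then restore order
  arr <- array(rep(as.vector(cpt$prob), prod(extra_cards)),
               dim = c(dim(cpt$prob), extra_cards))
  seq_parents <- c(cpt$parents, extra_parents)
  perm <- c(1L, 1L + match(new_parents, seq_parents))
  arr <- aperm(arr, perm)
  counts <- cpt_counts(cpt)
  if (!is.null(counts)) {
    old_cards <- if (length(cpt$parents)) dim(cpt$prob)[-1L] else integer(0)
    cnt <- array(rep(as.vector(counts), prod(extra_cards)),
                 dim = c(old_cards, extra_cards))
    if (length(new_parents) > 1L) {
      cnt <- aperm(array(cnt, dim = c(old_cards, extra_cards)),
                   match(new_parents, seq_parents))
    }
    counts <- cnt
  }
  out <- bn_cpt(cpt$child, new_parents, all_states, arr, counts = counts)
  attr(out, "bogus") <- union(bogus_tags(cpt), extra_parents)
  out
}

#' Extend two CPTs of the same child into a common form
#'
#' Both tables are extended to the union parent set in one canonical order,
#' so that the same configuration tuple addresses corresponding entries in
#' the two tables and the aggregation function can be applied position-wise.
#'
#' @param cptA,cptB `bn_cpt` objects for the same child with identical child
#'   state spaces.
#' @param order Optional canonical node order (see [extend_cpt()]).
#' @return List of the two extended, index-aligned CPTs.
#' @export
common_form <- function(cptA, cptB, order = NULL) {
  if (cptA$child != cptB$child) stop("CPTs have different children")
  if (!identical(cptA$states[[cptA$child]], cptB$states[[cptB$child]]))
    stop("child state spaces differ")
  shared <- intersect(cptA$parents, cptB$parents)
  for (p in shared) {
    if (!identical(cptA$states[[p]], cptB$states[[p]]))
      stop("conflicting state spaces for shared parent '", p, "'")
  }
  target <- canonical_parents(union(cptA$parents, cptB$parents), order)
  a <- extend_cpt(cptA, setdiff(cptB$parents, cptA$parents),
                  states = cptB$states, order = order)
  b <- extend_cpt(cptB, setdiff(cptA$parents, cptB$parents),
                  states = cptA$states, order = order)
  list(reorder_cpt_parents(a, target), reorder_cpt_parents(b, target))
}

#' Aggregate CPTs in common form
#'
#' Position-wise weight-normalised convex combination
#' `sum_i w_i P_i / sum_i w_i`. When every input carries parent-configuration
#' counts and `spec$use_counts` is TRUE, the weight applied at configuration
#' pa is `w_i * count_i(pa) / N_i`; with `w_i` equal to the source sample
#' counts this reproduces, exactly, the maximum-likelihood estimate on the
#' merged database.
#'
#' @param cpts List of `bn_cpt` objects in identical form (same child, same
#'   parents in the same order, same state spaces).
#' @param spec An [aggregation_spec()] with one weight per CPT.
#' @return The aggregated `bn_cpt`.
#' @export
aggregate_cpts <- function(cpts, spec) {
  k <- length(cpts)
  stopifnot(k >= 1L, length(spec$weights) == k)
  ref <- cpts[[1L]]
  for (cp in cpts[-1L]) {
    if (cp$child != ref$child || !identical(cp$parents, ref$parents) ||
        !identical(dimnames(cp$prob), dimnames(ref$prob)))
      stop("CPTs are not in a common form")
  }
  r <- cpt_cardinality(ref)
  q <- prod(dim(ref$prob)) / r
  counts_list <- lapply(cpts, cpt_counts)
  use_counts <- spec$use_counts && !any(vapply(counts_list, is.null, logical(1)))
  wmat <- matrix(0, nrow = k, ncol = q) # per-config row weights
  for (i in seq_len(k)) {
    if (use_counts) {
      ci <- as.vector(counts_list[[i]])
      Ni <- sum(ci)
      wmat[i, ] <- if (Ni > 0) spec$weights[i] * ci / Ni else 0
    } else {
      wmat[i, ] <- spec$weights[i]
    }
  }
  num <- matrix(0, nrow = r, ncol = q)
  for (i in seq_len(k)) {
    num <- num + matrix(cpts[[i]]$prob, nrow = r) *
      rep(wmat[i, ], each = r)
  }
  wsum <- colSums(wmat)
  out <- num
  pos <- wsum > 0
  out[, pos] <- sweep(num[, pos, drop = FALSE], 2L, wsum[pos], "/")
  if (any(!pos)) { # nothing observed anywhere: plain opinion pool
    sw <- sum(spec$weights)
    for (i in seq_len(k)) {
      out[, !pos] <- out[, !pos, drop = FALSE] +
        matrix(cpts[[i]]$prob, nrow = r)[, !pos, drop = FALSE] *
        spec$weights[i] / sw
    }
  }
  out <- sweep(out, 2L, colSums(out), "/") # absorb float error only
  res <- bn_cpt(ref$child, ref$parents, ref$states,
                array(out, dim = dim(ref$prob)),
                counts = if (use_counts) array(wsum, dim = if (length(ref$parents))
                  dim(ref$prob)[-1L] else 1L) else NULL)
  attr(res, "bogus") <- Reduce(union, lapply(cpts, bogus_tags))
  res
}

#' Detect bogus parents by the variance test
#'
#' A parent is flagged when its average conditional-probability variance
#' ([parent_variance_profile()]) is at or below `epsilon_var`: the child's
#' conditional distribution (almost) does not change as the parent varies,
#' so child and parent are deemed independent given the other parents.
#'
#' @param cpt A `bn_cpt`.
#' @param epsilon_var Nonnegative variance threshold.
#' @return Character vector of flagged parent names (canonical order).
#' @export
detect_bogus_parents <- function(cpt, epsilon_var) {
  flagged <- vapply(cpt$parents,
                    function(p) parent_variance_profile(cpt, p) <= epsilon_var,
                    logical(1))
  cpt$parents[flagged]
}

# marginalise one parent out with uniform weights over its states
drop_parent <- function(cpt, parent) {
  i <- match(parent, cpt$parents)
  d <- dim(cpt$prob)
  pd <- i + 1L
  a <- aperm(cpt$prob, c(seq_along(d)[-pd], pd))
  m <- matrix(a, ncol = d[pd])
  arr <- array(rowMeans(m), dim = d[-pd])
  arr <- array(sweep(matrix(arr, nrow = d[1L]), 2L,
                     colSums(matrix(arr, nrow = d[1L])), "/"),
               dim = d[-pd])
  counts <- cpt_counts(cpt)
  if (!is.null(counts)) {
    if (length(cpt$parents) == 1L) {
      counts <- sum(counts)
    } else {
      ca <- aperm(array(counts, dim = d[-1L]),
                  c(seq_along(d[-1L])[-i], i))
      counts <- array(rowSums(matrix(ca, ncol = d[pd])), dim = d[-1L][-i])
    }
  }
  out <- bn_cpt(cpt$child, cpt$parents[-i], cpt$states[-pd], arr,
                counts = counts)
  attr(out, "bogus") <- setdiff(bogus_tags(cpt), parent)
  out
}

#' Simplify a CPT by removing bogus parents
#'
#' Greedy one-at-a-time removal: the parent with the smallest variance
#' profile at or below `epsilon_var` is marginalised out (uniform average
#' over its states), then all remaining parents are re-tested. One-at-a-time
#' removal avoids over-deletion when two parents are jointly informative.
#'
#' @param cpt A `bn_cpt`.
#' @param epsilon_var Variance threshold.
#' @return List with `cpt` (simplified) and `removed` (parent names, in
#'   removal order).
#' @export
simplify_cpt <- function(cpt, epsilon_var) {
  removed <- character(0)
  repeat {
    if (!length(cpt$parents)) break
    prof <- vapply(cpt$parents, function(p) parent_variance_profile(cpt, p),
                   numeric(1))
    cand <- which(prof <= epsilon_var)
    if (!length(cand)) break
    pick <- cpt$parents[cand[which.min(prof[cand])]]
    cpt <- drop_parent(cpt, pick)
    removed <- c(removed, pick)
  }
  list(cpt = cpt, removed = removed)
}
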