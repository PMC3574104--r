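# Whole-network combination: prior-order alignment by covered-edge reversal,
# same-variable combination (common form -> aggregate -> variance
# simplification), and extension of a network to a larger variable set.

#' Align one network's prior order to another's
#'
#' If the two networks' prior orders are already consistent (edge-set union
#' acyclic) `bn_adjust` is returned unchanged. Otherwise covered edges of
#' `bn_adjust` that take part in a union cycle are reversed one at a time.
#' An edge u -> v is covered when Pa(v) = Pa(u) + {u}; reversing such an
#' edge, with the two CPTs recomputed by Bayes' rule, leaves the represented
#' joint distribution unchanged.
#'
#' @param bn_fixed Reference network (untouched).
#' @param bn_adjust Network to be re-oriented; same variable set.
#' @param strict When TRUE (default), only exact covered-edge reversals are
#'   used and an error is raised when none applies — the two networks then
#'   sit in different Markov equivalence classes. When FALSE, a conflicting
#'   edge u -> v is first "covered" (both endpoint parent sets widened to
#'   their union, with conditionals recomputed exactly from the network's
#'   own joint) and then reversed; exact for covered edges, a logged
#'   approximation otherwise.
#' @return `bn_adjust`, possibly with reversed edges; errors when no
#'   equivalence-preserving reversal sequence exists (strict mode).
#' @export
align_prior_orders <- function(bn_fixed, bn_adjust, strict = TRUE) {
  if (!length(intersect(bn_fixed$dag$nodes, bn_adjust$dag$nodes)))
    stop("networks share no variable")
  for (iter in seq_len(200L)) {
    if (orders_consistent(bn_fixed$dag, bn_adjust$dag)) return(bn_adjust)
    nodes <- union(bn_fixed$dag$nodes, bn_adjust$dag$nodes)
    uedges <- rbind(bn_fixed$dag$edges, bn_adjust$dag$edges)
    uedges <- uedges[!duplicated(edge_keys(uedges)), , drop = FALSE]
    cyc <- find_cycle(nodes, uedges)
    cyc_edges <- cbind(from = cyc[-length(cyc)], to = cyc[-1L])
    in_adjust <- edge_keys(cyc_edges) %in% edge_keys(bn_adjust$dag$edges)
    cand <- cyc_edges[in_adjust, , drop = FALSE]
    reversed <- FALSE
    for (i in seq_len(nrow(cand))) {
      u <- cand[i, 1L]; v <- cand[i, 2L]
      if (setequal(dag_parents(bn_adjust$dag, v),
                   c(dag_parents(bn_adjust$dag, u), u))) {
        res <- reverse_edge_via_cover(bn_adjust, u, v)
        if (!is.null(res)) {
          bn_adjust <- res
          reversed <- TRUE
          break
        }
      }
    }
    if (!reversed && !strict) {
      for (i in seq_len(nrow(cand))) {
        res <- reverse_edge_via_cover(bn_adjust, cand[i, 1L], cand[i, 2L])
        if (!is.null(res)) {
          message("align_prior_orders: non-covered reversal of ",
                  cand[i, 1L], " -> ", cand[i, 2L],
                  " (joint preserved only on the local margin)")
          bn_adjust <- res
          reversed <- TRUE
          break
        }
      }
      if (!reversed && nrow(cand)) {
        # last resort: surrender the conflicting edge of the adjusted
        # (less-believed) network, marginalising the parent out of the CPT
        u <- cand[1L, 1L]; v <- cand[1L, 2L]
        message("align_prior_orders: dropping irreconcilable edge ",
                u, " -> ", v, " from the adjusted network")
        cpts <- bn_adjust$cpts
        cpts[[v]] <- drop_parent(cpts[[v]], u)
        e <- bn_adjust$dag$edges
        e <- e[edge_keys(e) != paste(u, v, sep = "\r"), , drop = FALSE]
        bn_adjust <- bayesian_net(bn_dag(bn_adjust$dag$nodes, e), cpts,
                                  bn_adjust$weight)
        reversed <- TRUE
      }
    }
    if (!reversed) {
      stop("prior orders inconsistent and no covered edge of the cycle ",
           paste(cyc, collapse = " -> "), " is reversible; conflicting ",
           "adjustable edges: ",
           paste(paste(cand[, 1L], cand[, 2L], sep = "->"), collapse = ", "))
    }
  }
  stop("edge reversal did not converge")
}

# Reverse u -> v after widening both parent sets to S = Pa(u) u Pa(v) \ {u}:
# new Pa(v) = S, new Pa(u) = S + {v}, with both conditionals computed
# exactly from the network's joint. Exact equivalence when the edge is
# covered (then S = Pa(u) already). Returns NULL when the rewired graph
# would be cyclic.
reverse_edge_via_cover <- function(bn, u, v) {
  dag <- bn$dag
  S <- setdiff(union(dag_parents(dag, u), dag_parents(dag, v)), c(u, v))
  e <- dag$edges
  drop <- e[, 2L] %in% c(u, v)
  new_e <- rbind(e[!drop, , drop = FALSE],
                 if (length(S)) cbind(from = S, to = v),
                 if (length(S)) cbind(from = S, to = u),
                 cbind(from = v, to = u))
  new_e <- new_e[!duplicated(edge_keys(new_e)), , drop = FALSE]
  if (!is_acyclic(dag$nodes, new_e)) return(NULL)
  states <- bn_states(bn)
  J <- infer_joint(bn, c(u, v, S)) # dims: u, v, S...
  ru <- dim(J)[1L]; rv <- dim(J)[2L]
  q <- prod(dim(J)) / (ru * rv)
  Jm <- array(J, dim = c(ru, rv, q))
  newV <- matrix(0, nrow = rv, ncol = q)
  newU <- matrix(0, nrow = ru, ncol = rv * q) # configs: v fastest, then S
  for (j in seq_len(q)) {
    slab <- Jm[, , j, drop = FALSE]
    dim(slab) <- c(ru, rv)
    ps <- sum(slab)
    pv <- colSums(slab)
    newV[, j] <- if (ps > 0) pv / ps else 1 / rv
    for (vi in seq_len(rv)) {
      col <- (j - 1L) * rv + vi
      newU[, col] <- if (pv[vi] > 0) slab[, vi] / pv[vi] else 1 / ru
    }
  }
  cardsS <- if (length(S)) vapply(states[S], length, integer(1)) else integer(0)
  cpV <- bn_cpt(v, S, states, array(newV, dim = c(rv, cardsS)))
  cpU <- bn_cpt(u, c(v, S), states, array(newU, dim = c(ru, rv, cardsS)))
  cpts <- bn$cpts
  cpts[[u]] <- cpU
  cpts[[v]] <- cpV
  bayesian_net(bn_dag(dag$nodes, new_e), cpts, bn$weight)
}

# write `values` into arr[ , sel...] (lead = number of leading free dims)
assign_slice <- function(arr, sel, values, lead = 1L) {
  idx <- c(rep(list(TRUE), lead), as.list(sel))
  do.call(`[<-`, c(list(arr), idx, list(value = values)))
}

#' Combine two networks over the same variable set
#'
#' Per node: the two CPTs are extended into a common form, aggregated with
#' the opinion-pool weights, and the aggregate's parents are submitted to
#' the variance test; bogus parents are removed and the consensus DAG is
#' rebuilt from the surviving parent sets. All parent sets respect the
#' shared prior order, so the result is acyclic by construction.
#'
#' @param bn1,bn2 `bayesian_net` objects over identical variable sets with
#'   consistent prior orders (call [align_prior_orders()] first otherwise).
#' @param spec An [aggregation_spec()] with two weights.
#' @return The consensus `bayesian_net`, weighted by the summed weights.
#' @export
combine_same_variables <- function(bn1, bn2, spec) {
  if (!setequal(bn1$dag$nodes, bn2$dag$nodes))
    stop("variable sets differ; use combine() for nested sets")
  if (!orders_consistent(bn1$dag, bn2$dag))
    stop("prior orders inconsistent: call align_prior_orders() first")
  nodes <- bn1$dag$nodes
  uedges <- rbind(bn1$dag$edges, bn2$dag$edges)
  uedges <- uedges[!duplicated(edge_keys(uedges)), , drop = FALSE]
  ord <- topo_sort(union(nodes, nodes), uedges) # consensus prior order
  edges <- empty_edges()
  cpts <- list()
  for (nd in nodes) {
    cf <- common_form(bn1$cpts[[nd]], bn2$cpts[[nd]], order = ord)
    agg <- aggregate_cpts(cf, spec)
    simp <- simplify_cpt(agg, spec$epsilon_var)
    cpts[[nd]] <- simp$cpt
    if (length(simp$cpt$parents)) {
      edges <- rbind(edges, cbind(from = simp$cpt$parents, to = nd))
    }
  }
  dag <- bn_dag(nodes, edges)
  bayesian_net(dag, cpts, weight = sum(spec$weights))
}

#' Extend a network to a larger variable set
#'
#' Enlarges `bn_small` to the variables of `bn_ref` (a superset). Every
#' `bn_ref` edge incident to a new variable is added and tagged "extended".
#' CPTs: old nodes without extended in-edges keep their CPT; new nodes take
#' their CPT from `bn_ref`; an old node that gains extended in-edges gets
#' each conditional row rebuilt from its original conditional and
#' conditionals inferred exactly in `bn_ref`, with the case picked by how
#' the old-parent block and the new-parent block connect in `bn_ref`
#' (edge either way: Bayes product with the block-conditional; disconnected
#' blocks, hence independent: marginal product form).
#'
#' @param bn_small Network over a strict subset of `bn_ref`'s variables.
#' @param bn_ref Reference network over the full variable set.
#' @return A `bayesian_net` over `bn_ref`'s variables.
#' @export
extend_bn <- function(bn_small, bn_ref) {
  small_vars <- bn_small$dag$nodes
  ref_vars <- bn_ref$dag$nodes
  if (setequal(small_vars, ref_vars)) return(bn_small)
  if (!all(small_vars %in% ref_vars))
    stop("bn_small's variables must be a subset of bn_ref's")
  if (!orders_consistent(bn_small$dag, bn_ref$dag))
    stop("prior orders inconsistent; align before extending")
  sm_states <- bn_states(bn_small)
  rf_states <- bn_states(bn_ref)
  for (v in small_vars) {
    if (!identical(sm_states[[v]], rf_states[[v]]))
      stop("state spaces differ for shared variable '", v, "'")
  }
  new_vars <- setdiff(ref_vars, small_vars)
  ref_e <- bn_ref$dag$edges
  ext_mask <- ref_e[, 1L] %in% new_vars | ref_e[, 2L] %in% new_vars
  ext_edges <- ref_e[ext_mask, , drop = FALSE]
  edges <- rbind(bn_small$dag$edges, ext_edges)
  tags <- c(rep("normal", nrow(bn_small$dag$edges)),
            rep("extended", nrow(ext_edges)))
  dag <- bn_dag(ref_vars, edges, tags)
  ord <- topological_order(dag)
  cpts <- list()
  for (nd in ref_vars) {
    if (nd %in% new_vars) {
      cpts[[nd]] <- bn_ref$cpts[[nd]]
      next
    }
    A <- dag_parents(bn_small$dag, nd) # old parents
    B <- intersect(dag_parents(bn_ref$dag, nd), new_vars) # extended parents
    if (!length(B)) {
      cpts[[nd]] <- bn_small$cpts[[nd]]
      next
    }
    cpts[[nd]] <- extended_node_cpt(bn_small, bn_ref, nd, A, B, ord)
  }
  bayesian_net(dag, cpts, bn_small$weight)
}

# CPT of an old node that gained extended in-edges (new-parent block B),
# combining the original conditional P1(x|a) with conditionals inferred in
# the reference network.
extended_node_cpt <- function(bn_small, bn_ref, nd, A, B, ord) {
  cp1 <- bn_small$cpts[[nd]]
  rf_states <- bn_states(bn_ref)
  states <- rf_states[c(nd, A, B)]
  r <- length(states[[nd]])
  # The three textbook situations (old-parent block and new-parent block
  # joined by an edge either way, or disconnected and hence independent)
  # share one exact Bayes composition: P(x | a, b) is proportional to
  # P_small(x | a) * P_ref(b | x, a), the latter inferred exactly; with no
  # old parents this reduces to the pure product form P_small(x) P_ref(b|x).
  J <- infer_joint(bn_ref, c(nd, A, B)) # dims: x, A..., B...
  parents <- canonical_parents(c(A, B), ord)
  cards <- vapply(states[parents], length, integer(1))
  arr <- array(0, dim = c(r, cards))
  grid <- expand.grid(lapply(states[parents], seq_along), KEEP.OUT.ATTRS = FALSE)
  n_fallback <- 0L
  for (gi in seq_len(nrow(grid))) {
    sel <- unlist(grid[gi, , drop = TRUE])
    cfg <- stats::setNames(mapply(function(p, ix) states[[p]][ix], parents, sel),
                           parents)
    p1 <- cpt_row(cp1, cfg) # P1(x | a); ignores B entries
    row <- numeric(r)
    for (xi in seq_len(r)) {
      jidx <- c(list(xi), lapply(c(A, B), function(p) match(cfg[[p]], states[[p]])))
      jxab <- do.call(`[`, c(list(J), jidx))
      # P2(b | x, a) = J(x, a, b) / J(x, a)
      jxa <- sum(do.call(`[`, c(list(J), c(jidx[seq_len(1L + length(A))],
                                           rep(list(TRUE), length(B))))))
      row[xi] <- if (jxa > 0) p1[xi] * jxab / jxa else 0
    }
    s <- sum(row)
    if (s <= 0) {
      # impossible context in the reference net: fall back to its conditional
      n_fallback <- n_fallback + 1L
      row <- tryCatch(
        as.vector(infer_joint(bn_ref, nd, cfg[c(A, B)])),
        error = function(e) rep(1 / r, r))
    } else {
      row <- row / s
    }
    arr <- assign_slice(arr, sel, row)
  }
  if (n_fallback > 0L) {
    message("extend_bn: ", n_fallback, " conditional row(s) of '", nd,
            "' taken from the reference network (zero-probability context)")
  }
  out <- bn_cpt(nd, parents, states, arr)
  attr(out, "bogus") <- character(0)
  out
}

#' Combine two Bayesian networks
#'
#' Equal variable sets are combined directly; nested sets are first brought
#' onto the larger set with [extend_bn()]. Inconsistent prior orders are
#' resolved by [align_prior_orders()] (second network adjusted). Non-nested,
#' non-equal variable sets are unsupported.
#'
#' @param bn1,bn2 `bayesian_net` objects.
#' @param spec An [aggregation_spec()]; weights follow the argument order.
#' @return The consensus `bayesian_net`.
#' @export
combine <- function(bn1, bn2, spec) {
  v1 <- bn1$dag$nodes; v2 <- bn2$dag$nodes
  if (setequal(v1, v2)) {
    if (!orders_consistent(bn1$dag, bn2$dag)) {
      # the less-believed network yields: adjust it to the other's order
      if (spec$weights[1L] >= spec$weights[2L]) {
        bn2 <- align_prior_orders(bn1, bn2, strict = FALSE)
      } else {
        bn1 <- align_prior_orders(bn2, bn1, strict = FALSE)
      }
    }
    return(combine_same_variables(bn1, bn2, spec))
  }
  if (all(v1 %in% v2)) {
    if (!orders_consistent(bn1$dag, bn2$dag))
      bn1 <- align_prior_orders(bn2, bn1, strict = FALSE)
    return(combine_same_variables(extend_bn(bn1, bn2), bn2, spec))
  }
  if (all(v2 %in% v1)) {
    if (!orders_consistent(bn1$dag, bn2$dag))
      bn2 <- align_prior_orders(bn1, bn2, strict = FALSE)
    return(combine_same_variables(bn1, extend_bn(bn2, bn1), spec))
  }
  stop("variable sets are neither equal nor nested; unsupported")
}

#' Fold several networks into one consensus network
#'
#' Left-to-right combination with accumulated weights, justified by the
#' associativity of the aggregation under weight accumulation.
#'
#' @param bns List of `bayesian_net` objects.
#' @param weights One positive integer per network.
#' @param epsilon_var Variance threshold for simplification.
#' @param use_counts See [aggregation_spec()].
#' @return The consensus `bayesian_net`.
#' @export
combine_networks <- function(bns, weights, epsilon_var = 1e-3,
                             use_counts = TRUE) {
  stopifnot(length(bns) >= 1L, length(weights) == length(bns))
  acc <- bns[[1L]]
  w <- weights[[1L]]
  for (i in seq_along(bns)[-1L]) {
    acc <- combine(acc, bns[[i]],
                   aggregation_spec(c(w, weights[[i]]), epsilon_var,
                                    use_counts))
    w <- w + weights[[i]]
  }
  acc
}
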