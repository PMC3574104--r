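# Independent brute-force oracles. Deliberately naive: plain loops and full
# enumeration, no shared code paths with the implementation they check.

enumerate_assignments <- function(states) {
  expand.grid(states, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# exact posterior by summing joint_probability over the full joint table
oracle_posterior <- function(bn, query, evidence = NULL) {
  grid <- enumerate_assignments(bn_states(bn))
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  probs <- vapply(which(keep), function(i) {
    joint_probability(bn, cfg_row(grid, i))
  }, numeric(1))
  agg <- tapply(probs, grid[[query]][keep], sum)
  agg <- agg[match(bn_states(bn)[[query]], names(agg))]
  agg[is.na(agg)] <- 0
  as.vector(agg) / sum(agg)
}

# contingency-table MI, explicit double loop
oracle_mi <- function(data, x, y) {
  n <- nrow(data)
  total <- 0
  for (a in levels(data[[x]])) {
    for (b in levels(data[[y]])) {
      pxy <- sum(data[[x]] == a & data[[y]] == b) / n
      if (pxy == 0) next
      px <- sum(data[[x]] == a) / n
      py <- sum(data[[y]] == b) / n
      total <- total + pxy * log(pxy / (px * py))
    }
  }
  total
}

# triple-sum conditional MI
oracle_cmi <- function(data, x, y, cond) {
  n <- nrow(data)
  cfgs <- unique(data[cond])
  total <- 0
  for (i in seq_len(nrow(cfgs))) {
    sel <- rep(TRUE, n)
    for (v in cond) sel <- sel & data[[v]] == cfgs[i, v]
    nc <- sum(sel)
    if (nc == 0) next
    sub <- data[sel, , drop = FALSE]
    total <- total + (nc / n) * oracle_mi(sub, x, y)
  }
  total
}

# naive variance profile: loop over child states and other-parent configs
oracle_variance_profile <- function(cpt, parent) {
  others <- setdiff(cpt$parents, parent)
  ostates <- cpt$states[others]
  ogrid <- if (length(others)) {
    enumerate_assignments(ostates)
  } else data.frame(row.names = 1L)
  vals <- c()
  for (xs in cpt$states[[cpt$child]]) {
    for (i in seq_len(max(1L, nrow(ogrid)))) {
      ps <- vapply(cpt$states[[parent]], function(pv) {
        cfg <- c(stats::setNames(pv, parent),
                 if (length(others)) cfg_row(ogrid, i))
        row <- cpt_row(cpt, cfg)
        row[match(xs, cpt$states[[cpt$child]])]
      }, numeric(1))
      vals <- c(vals, mean((ps - mean(ps))^2))
    }
  }
  mean(vals)
}

# acyclicity of an explicit union graph, simple DFS
oracle_union_acyclic <- function(dag1, dag2) {
  nodes <- union(dag1$nodes, dag2$nodes)
  edges <- unique(rbind(dag1$edges, dag2$edges))
  succ <- function(v) edges[edges[, 1] == v, 2]
  color <- stats::setNames(rep(0L, length(nodes)), nodes)
  ok <- TRUE
  visit <- function(v) {
    if (!ok) return()
    color[[v]] <<- 1L
    for (w in succ(v)) {
      if (color[[w]] == 1L) { ok <<- FALSE; return() }
      if (color[[w]] == 0L) visit(w)
    }
    color[[v]] <<- 2L
  }
  for (v in nodes) if (color[[v]] == 0L) visit(v)
  ok
}

# exhaustive pairwise/conditional CI map on 3 variables
oracle_ci_skeleton_3 <- function(data, delta) {
  vars <- names(data)
  stopifnot(length(vars) == 3L)
  edges <- c()
  for (p in utils::combn(vars, 2, simplify = FALSE)) {
    z <- setdiff(vars, p)
    dep_marginal <- oracle_mi(data, p[1], p[2]) > delta
    dep_cond <- oracle_cmi(data, p[1], p[2], z) > delta
    if (dep_marginal && dep_cond) edges <- c(edges, paste(sort(p), collapse = "-"))
  }
  sort(edges)
}

skeleton_keys <- function(dag_or_ugraph) {
  e <- dag_or_ugraph$edges
  if (!nrow(e)) return(character(0))
  sort(apply(t(apply(e, 1, sort)), 1, paste, collapse = "-"))
}

directed_keys <- function(dag) {
  e <- dag$edges
  if (!nrow(e)) return(character(0))
  sort(paste(e[, 1], e[, 2], sep = ">"))
}

# named configuration from row i of an expand.grid frame (robust to 1 column)
cfg_row <- function(grid, i) {
  vapply(grid, function(col) as.character(col[i]), character(1))
}
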