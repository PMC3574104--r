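#' Discrete variable with an ordered state space
#'
#' @param name Variable identifier.
#' @param states Ordered character vector of unique state labels.
#' @return An object of class `bn_variable` with fields `name`, `states`
#'   and `cardinality` (the number of states, the "number of expression
#'   values" of the variable).
#' @examples
#' bn_variable("smoke", c("no", "yes"))
#' @export
bn_variable <- function(name, states) {
  states <- as.character(states)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (anyDuplicated(states)) stop("duplicate state labels for '", name, "'")
  structure(list(name = name, states = states,
                 cardinality = length(states)),
            class = "bn_variable")
}

#' @export
print.bn_variable <- function(x, ...) {
  cat("<variable>", x$name, ": ", paste(x$states, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Discrete categorical dataset
#'
#' A validated data.frame of factors: one column per variable, one row per
#' sample. Factor levels are the per-variable state spaces.
#'
#' @param df data.frame whose columns are factors or coercible to factors.
#' @param states Optional named list of state-label vectors; when given,
#'   columns are coerced to factors with exactly these levels (unknown
#'   labels are an error).
#' @return A `discrete_dataset` (also a data.frame).
#' @export
discrete_dataset <- function(df, states = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate variable names")
  for (nm in names(df)) {
    col <- df[[nm]]
    if (!is.null(states)) {
      if (is.null(states[[nm]])) stop("no state space supplied for '", nm, "'")
      lev <- as.character(states[[nm]])
      col <- as.character(col)
      bad <- which(!col %in% lev)
      if (length(bad)) {
        stop("unknown state '", col[bad[1L]], "' for variable '", nm,
             "' (row ", bad[1L], ")")
      }
      df[[nm]] <- factor(col, levels = lev)
    } else if (!is.factor(col)) {
      df[[nm]] <- factor(as.character(col))
    }
  }
  class(df) <- c("discrete_dataset", "data.frame")
  df
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("<discrete_dataset> ", nrow(x), " samples x ", ncol(x), " variables\n",
      sep = "")
  NextMethod()
}

#' State spaces of a dataset
#' @param data A `discrete_dataset` (or data.frame of factors).
#' @return Named list of state-label vectors.
#' @export
dataset_states <- function(data) lapply(data, levels)

#' Variables of a dataset as `bn_variable` objects
#' @inheritParams dataset_states
#' @export
dataset_variables <- function(data) {
  mapply(bn_variable, names(data), dataset_states(data), SIMPLIFY = FALSE)
}

#' Directed acyclic graph
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column (from = parent, to = child) character matrix, or
#'   anything coercible; may be NULL for an edgeless graph.
#' @param tags Optional character vector (one per edge) with values in
#'   `"normal"`, `"bogus"`, `"extended"`. Defaults to `"normal"`.
#' @param validate Check acyclicity and simplicity (default TRUE).
#' @return A `bn_dag`.
#' @export
bn_dag <- function(nodes, edges = NULL, tags = NULL, validate = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- as_edge_matrix(edges)
  if (nrow(edges)) {
    miss <- setdiff(c(edges), nodes)
    if (length(miss)) stop("edge endpoint not in node set: ", miss[1L])
  }
  if (is.null(tags)) tags <- rep("normal", nrow(edges))
  stopifnot(length(tags) == nrow(edges),
            all(tags %in% c("normal", "bogus", "extended")))
  if (validate) {
    if (nrow(edges)) {
      if (any(edges[, 1L] == edges[, 2L])) stop("self-loop in edge set")
      if (anyDuplicated(edge_keys(edges))) stop("duplicate edge in edge set")
    }
    if (!is_acyclic(nodes, edges)) {
      cyc <- find_cycle(nodes, edges)
      stop("graph is cyclic: ", paste(cyc, collapse = " -> "))
    }
  }
  structure(list(nodes = nodes, edges = edges, tags = tags), class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("<dag> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges)) {
    lab <- paste0(x$edges[, 1L], " -> ", x$edges[, 2L],
                  ifelse(x$tags == "normal", "", paste0(" [", x$tags, "]")))
    cat(" ", paste(lab, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Parents of a node in a DAG
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @export
dag_parents <- function(dag, node) {
  e <- dag$edges
  sort(e[e[, 2L] == node, 1L])
}

#' Conditional probability table
#'
#' The table is an array whose first dimension indexes the child's states and
#' whose remaining dimensions index the parents' states, in the order of
#' `parents`. `dimnames` carry the state labels and are named by variable.
#'
#' @param child Child variable name.
#' @param parents Ordered character vector of parent names (may be empty).
#' @param states Named list of state labels covering child and all parents.
#' @param prob Array of conditional probabilities; each child-distribution
#'   (first margin) must sum to 1 within 1e-9. A plain vector is accepted for
#'   a parentless node, a matrix (child x parent) for a single parent.
#' @param counts Optional array of parent-configuration sample counts with
#'   the parent dimensions of `prob`; attached as attribute `"counts"` and
#'   used by count-weighted aggregation.
#' @return A `bn_cpt`.
#' @export
bn_cpt <- function(child, parents, states, prob, counts = NULL) {
  parents <- as.character(parents)
  if (child %in% parents) stop("child cannot be its own parent")
  if (anyDuplicated(parents)) stop("duplicate parent in CPT")
  need <- c(child, parents)
  miss <- setdiff(need, names(states))
  if (length(miss)) stop("missing state space for: ", paste(miss, collapse = ", "))
  cards <- vapply(states[need], length, integer(1))
  prob <- array(as.double(prob), dim = unname(cards),
                dimnames = stats::setNames(lapply(states[need], as.character), need))
  if (any(prob < -1e-12 | prob > 1 + 1e-12)) stop("probabilities outside [0, 1]")
  prob[prob < 0] <- 0
  prob[prob > 1] <- 1
  sums <- if (length(parents) == 0L) sum(prob) else {
    apply(prob, seq_along(dim(prob))[-1L], sum)
  }
  if (any(abs(sums - 1) > 1e-9)) {
    stop("CPT for '", child, "': a conditional distribution sums to ",
         format(sums[which.max(abs(sums - 1))], digits = 12), ", not 1")
  }
  obj <- structure(list(child = child, parents = parents,
                        states = stats::setNames(lapply(states[need], as.character), need),
                        prob = prob),
                   class = "bn_cpt")
  if (!is.null(counts)) {
    counts <- array(as.double(counts),
                    dim = if (length(parents)) unname(cards[-1L]) else 1L)
    attr(obj, "counts") <- counts
  }
  obj
}

cpt_counts <- function(cpt) attr(cpt, "counts", exact = TRUE)

#' Number of states of the CPT's child
#' @param cpt A `bn_cpt`.
#' @export
cpt_cardinality <- function(cpt) length(cpt$states[[cpt$child]])

#' @export
print.bn_cpt <- function(x, ...) {
  cat("<cpt> P(", x$child,
      if (length(x$parents)) paste0(" | ", paste(x$parents, collapse = ", ")),
      ")\n", sep = "")
  print(x$prob)
  invisible(x)
}

#' Look up one conditional distribution
#'
#' @param cpt A `bn_cpt`.
#' @param config Named character vector (or list) of parent states; extra
#'   names are ignored, missing parents are an error.
#' @return Numeric probability vector over the child's states.
#' @export
cpt_row <- function(cpt, config) {
  if (!length(cpt$parents)) return(as.vector(cpt$prob))
  config <- unlist(config)
  miss <- setdiff(cpt$parents, names(config))
  if (length(miss)) stop("missing parent state(s): ", paste(miss, collapse = ", "))
  idx <- c(list(TRUE), lapply(cpt$parents, function(p) {
    i <- match(config[[p]], cpt$states[[p]])
    if (is.na(i)) stop("unknown state '", config[[p]], "' for parent '", p, "'")
    i
  }))
  as.vector(do.call(`[`, c(list(cpt$prob), idx)))
}

#' Discrete Bayesian network
#'
#' @param dag A `bn_dag`.
#' @param cpts Named list of `bn_cpt`, one per node; each CPT's parent list
#'   must equal the node's parents in `dag` (as sets).
#' @param weight Positive integer belief weight (effective sample count).
#' @return A `bayesian_net`.
#' @export
bayesian_net <- function(dag, cpts, weight = 1L) {
  stopifnot(inherits(dag, "bn_dag"))
  weight <- as.integer(weight)
  if (is.na(weight) || weight < 1L) stop("weight must be a positive integer")
  miss <- setdiff(dag$nodes, names(cpts))
  if (length(miss)) stop("missing CPT for node(s): ", paste(miss, collapse = ", "))
  cpts <- cpts[dag$nodes]
  for (n in dag$nodes) {
    cp <- cpts[[n]]
    if (!inherits(cp, "bn_cpt") || cp$child != n)
      stop("CPT list entry '", n, "' is not a CPT for that node")
    if (!setequal(cp$parents, dag_parents(dag, n)))
      stop("CPT parents of '", n, "' disagree with DAG parents")
  }
  structure(list(dag = dag, cpts = cpts, weight = weight),
            class = "bayesian_net")
}

#' @export
print.bayesian_net <- function(x, ...) {
  cat("<bayesian_net> ", length(x$dag$nodes), " nodes, ", nrow(x$dag$edges),
      " edges, weight ", x$weight, "\n", sep = "")
  invisible(x)
}

#' State spaces of a network's variables
#' @param bn A `bayesian_net`.
#' @return Named list of state-label vectors.
#' @export
bn_states <- function(bn) {
  stats::setNames(lapply(bn$dag$nodes, function(n) bn$cpts[[n]]$states[[n]]),
                  bn$dag$nodes)
}
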