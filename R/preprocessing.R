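# Discretization of continuous expression matrices and the policy layer for
# literature-derived structures.

#' Tertile (q3) discretization of an expression matrix
#'
#' Per gene (row), values are split at the empirical 1/3 and 2/3 cut points
#' into three states: underexpressed / normal / overexpressed — the
#' maximum-entropy three-bin quantization. Cut points sit at order
#' statistics ceiling(n/3) and ceiling(2n/3); ties go to the lower bin, so
#' the binning is deterministic and the bins are as equal as ties permit.
#'
#' @param mat Numeric matrix (genes x samples) with rownames; a data.frame
#'   is accepted.
#' @return A `discrete_dataset`: one variable per gene, one row per sample
#'   (the matrix transposed), states `underexpressed`/`normal`/
#'   `overexpressed`. Constant genes are excluded with a warning.
#' @export
q3_discretize <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("expression matrix needs gene rownames")
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite expression value(s) at: ",
         paste(sprintf("[%s, %s]", rownames(mat)[bad[, 1L]], bad[, 2L]),
               collapse = ", "))
  }
  states <- c("underexpressed", "normal", "overexpressed")
  n <- ncol(mat)
  cols <- list()
  dropped <- character(0)
  for (g in rownames(mat)) {
    x <- mat[g, ]
    if (length(unique(x)) < 3L) {
      dropped <- c(dropped, g)
      next
    }
    s <- sort(x)
    c1 <- s[ceiling(n / 3)]
    c2 <- s[ceiling(2 * n / 3)]
    lab <- ifelse(x <= c1, states[1L], ifelse(x <= c2, states[2L], states[3L]))
    cols[[g]] <- factor(lab, levels = states)
  }
  if (length(dropped)) {
    warning("excluded gene(s) with fewer than 3 distinct values: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(cols)) stop("no gene with at least 3 distinct values")
  discrete_dataset(as.data.frame(cols, check.names = FALSE))
}

#' Attach parameters to a literature-derived structure
#'
#' Networks taken from the literature usually come as a bare structure;
#' parameters are obtained either by re-estimating from a dataset
#' (maximum-likelihood rule) or from explicitly supplied (expert-elicited or
#' program-output) CPTs.
#'
#' @param structure A `bn_dag`.
#' @param data Optional `discrete_dataset`; when given, parameters are
#'   learned on the structure and the other arguments are ignored.
#' @param cpts Optional named list of `bn_cpt` covering every node.
#' @param weight Belief weight of the resulting network (defaults to the
#'   sample count when learning from data, else 1).
#' @return A `bayesian_net`.
#' @export
attach_literature_parameters <- function(structure, data = NULL, cpts = NULL,
                                         weight = NULL) {
  stopifnot(inherits(structure, "bn_dag"))
  if (!is.null(data)) {
    bn <- learn_parameters(data, structure)
    if (!is.null(weight)) bn$weight <- as.integer(weight)
    return(bn)
  }
  if (is.null(cpts)) stop("supply either data or a complete CPT list")
  miss <- setdiff(structure$nodes, names(cpts))
  if (length(miss)) {
    stop("no CPT supplied for node(s): ", paste(miss, collapse = ", "))
  }
  bayesian_net(structure, cpts, weight = if (is.null(weight)) 1L else weight)
}
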