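#' Threshold bundle for learning and combination
#'
#' @param delta_mi Mutual-information relatedness threshold (nats). Two
#'   variables are treated as related when their (conditional) MI exceeds
#'   this. Default 0.01 nats; see [calibrate_delta_mi()] for a data-driven
#'   choice.
#' @param delta_orient Collider-orientation ratio threshold: an unshielded
#'   triple X-Z-Y is oriented X->Z<-Y when
#'   I(X;Y|Z) > delta_orient * I(X;Y) + delta_mi. Default 1.
#' @param epsilon_var Variance threshold for bogus-parent detection; a parent
#'   whose average conditional-probability variance falls at or below this is
#'   deemed independent of the child. Default 1e-3; see
#'   [calibrate_epsilon_var()].
#' @return A `bn_thresholds` list.
#' @export
bn_thresholds <- function(delta_mi = 0.01, delta_orient = 1, epsilon_var = 1e-3) {
  stopifnot(delta_mi >= 0, delta_orient >= 0, epsilon_var >= 0)
  structure(list(delta_mi = delta_mi, delta_orient = delta_orient,
                 epsilon_var = epsilon_var),
            class = "bn_thresholds")
}

check_vars_present <- function(data, vars) {
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variable(s) not in dataset: ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("empty dataset")
}

mi_from_counts <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

#' Empirical mutual information (natural log)
#'
#' I(X;Y) = sum p(x,y) log p(x,y) / (p(x) p(y)) over the observed joint
#' frequencies; 0 log 0 := 0. Maximum-likelihood frequencies, no smoothing.
#'
#' @param data A `discrete_dataset` (or data.frame of factors).
#' @param x,y Distinct variable names.
#' @return Nonnegative scalar in nats (clamped at 0 against float error).
#' @export
mutual_information <- function(data, x, y) {
  if (x == y) stop("x and y must differ")
  check_vars_present(data, c(x, y))
  tab <- table(data[[x]], data[[y]])
  max(0, mi_from_counts(tab))
}

#' Empirical conditional mutual information (natural log)
#'
#' I(X;Y|C) = sum_c p(c) I(X;Y | C = c); an empty conditioning set reduces to
#' [mutual_information()]. Unobserved configurations contribute zero.
#'
#' @inheritParams mutual_information
#' @param cond Character vector of conditioning variables (may be empty).
#' @param min_stratum Conditioning strata with fewer samples than this
#'   contribute 0 (the learner's small-count guard); default 0 gives the
#'   plain empirical definition.
#' @return Nonnegative scalar in nats.
#' @export
conditional_mutual_information <- function(data, x, y, cond = character(0),
                                           min_stratum = 0L) {
  cond <- setdiff(as.character(cond), character(0))
  if (x %in% cond || y %in% cond) stop("x/y must not be in the conditioning set")
  if (!length(cond)) return(mutual_information(data, x, y))
  check_vars_present(data, c(x, y, cond))
  n <- nrow(data)
  strat <- interaction(data[cond], drop = TRUE, lex.order = TRUE)
  xs <- data[[x]]
  ys <- data[[y]]
  total <- 0
  for (idx in split(seq_len(n), strat)) {
    if (length(idx) == 0L || length(idx) < min_stratum) next
    tab <- table(xs[idx], ys[idx])
    total <- total + (length(idx) / n) * mi_from_counts(tab)
  }
  max(0, total)
}

#' Average conditional-probability variance along one parent
#'
#' For every child state and every configuration of the other parents, takes
#' the variance (population form, divisor r) of the conditional probability
#' as only `parent` varies, and returns the mean of these variances. Zero
#' exactly when the parent can be marginalized out without changing any
#' conditional — the variance test for bogus parents.
#'
#' @param cpt A `bn_cpt`.
#' @param parent A member of `cpt$parents`.
#' @return Nonnegative scalar.
#' @export
parent_variance_profile <- function(cpt, parent) {
  i <- match(parent, cpt$parents)
  if (is.na(i)) stop("'", parent, "' is not a parent in this CPT")
  d <- dim(cpt$prob)
  pd <- i + 1L # parent dims sit after the child dim
  a <- aperm(cpt$prob, c(seq_along(d)[-pd], pd))
  m <- matrix(a, ncol = d[pd])
  v <- rowMeans(m^2) - rowMeans(m)^2
  mean(pmax(v, 0))
}

#' Permutation calibration of the MI threshold
#'
#' Shuffles one column of a random pair `B` times to build a null MI sample
#' and returns its upper quantile: a data-driven delta_mi with an
#' approximately `1 - probs` pairwise false-positive rate.
#'
#' @param data A `discrete_dataset`.
#' @param B Number of permutation replicates.
#' @param probs Quantile of the null distribution to return (default 0.99).
#' @param seed Integer seed.
#' @return Scalar threshold in nats.
#' @export
calibrate_delta_mi <- function(data, B = 200L, probs = 0.99, seed = 1L) {
  stopifnot(ncol(data) >= 2L, nrow(data) >= 2L)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  nulls <- vapply(seq_len(B), function(b) {
    pair <- sample(names(data), 2L)
    shuffled <- data
    shuffled[[pair[1L]]] <- sample(shuffled[[pair[1L]]])
    mutual_information(shuffled, pair[1L], pair[2L])
  }, numeric(1))
  as.numeric(stats::quantile(nulls, probs, names = FALSE))
}

#' Calibrate the bogus-parent variance threshold
#'
#' Repeatedly appends a known-independent (permuted) parent to a node,
#' re-estimates the CPT, and records the bogus parent's variance profile.
#' The returned quantile is an epsilon_var that would flag such parents.
#'
#' @param data A `discrete_dataset`.
#' @param child Node name.
#' @param parents Character vector of real parents (may be empty).
#' @param B Number of replicates.
#' @param probs Quantile to return (default 0.99).
#' @param seed Integer seed.
#' @return Scalar variance threshold.
#' @export
calibrate_epsilon_var <- function(data, child, parents = character(0),
                                  B = 50L, probs = 0.99, seed = 1L) {
  check_vars_present(data, c(child, parents))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pool <- setdiff(names(data), c(child, parents))
  if (!length(pool)) pool <- child
  profiles <- vapply(seq_len(B), function(b) {
    bogus <- data[[sample(pool, 1L)]][sample.int(nrow(data))]
    aug <- data
    aug[[".bogus"]] <- bogus
    dag <- bn_dag(c(child, parents, ".bogus"),
                  cbind(from = c(parents, ".bogus"),
                        to = rep(child, length(parents) + 1L)))
    bn <- learn_parameters(aug[, c(child, parents, ".bogus"), drop = FALSE], dag)
    parent_variance_profile(bn$cpts[[child]], ".bogus")
  }, numeric(1))
  as.numeric(stats::quantile(profiles, probs, names = FALSE))
}

## seed plumbing: run seeded code without disturbing the caller's RNG stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
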