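# Small hand-built networks and datasets used across the suite.

bin_states <- function(...) {
  nms <- c(...)
  stats::setNames(rep(list(c("0", "1")), length(nms)), nms)
}

# A -> B -> C chain with strong, monotone CPTs.
chain_net <- function(pa = 0.5, flip = 0.1) {
  st <- bin_states("A", "B", "C")
  bayesian_net(
    bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"))),
    list(A = bn_cpt("A", character(0), st, c(pa, 1 - pa)),
         B = bn_cpt("B", "A", st,
                    matrix(c(1 - flip, flip, flip, 1 - flip), 2)),
         C = bn_cpt("C", "B", st,
                    matrix(c(1 - flip, flip, flip, 1 - flip), 2))))
}

# A -> C <- B collider with marginally independent, monotone parents
# (not XOR: an MI-based learner can only see monotone colliders).
collider_net <- function() {
  st <- bin_states("A", "B", "C")
  bayesian_net(
    bn_dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C"))),
    list(A = bn_cpt("A", character(0), st, c(0.5, 0.5)),
         B = bn_cpt("B", character(0), st, c(0.5, 0.5)),
         C = bn_cpt("C", c("A", "B"), st,
                    array(c(0.9, 0.1, 0.5, 0.5, 0.5, 0.5, 0.1, 0.9),
                          c(2, 2, 2)))))
}

random_dataset <- function(n, vars, cards, seed) {
  set.seed(seed)
  df <- as.data.frame(stats::setNames(lapply(seq_along(vars), function(i) {
    factor(sample(paste0("s", seq_len(cards[[i]])), n, replace = TRUE),
           levels = paste0("s", seq_len(cards[[i]])))
  }), vars))
  discrete_dataset(df)
}
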