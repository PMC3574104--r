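# Benchmark fixtures: the canonical 8-node Chest-clinic network, a
# synthetic-parameter stand-in for the 37-node ALARM network, and seeded
# random networks. These replace the external benchmark-database generator
# in all tests and experiments.

#' The canonical Chest-clinic (Asia) network
#'
#' 8 binary nodes, 8 directed edges, with the classic conditional
#' probabilities (Lauritzen & Spiegelhalter's chest-clinic example).
#'
#' @return A `bayesian_net` with weight 1.
#' @export
fixture_chest_clinic <- function() {
  yn <- c("yes", "no")
  nodes <- c("asia", "tub", "smoke", "lung", "bronc", "either", "xray", "dysp")
  states <- stats::setNames(rep(list(yn), length(nodes)), nodes)
  edges <- rbind(
    c("asia", "tub"), c("smoke", "lung"), c("smoke", "bronc"),
    c("tub", "either"), c("lung", "either"), c("either", "xray"),
    c("either", "dysp"), c("bronc", "dysp"))
  colnames(edges) <- c("from", "to")
  cpts <- list(
    asia = bn_cpt("asia", character(0), states, c(0.01, 0.99)),
    smoke = bn_cpt("smoke", character(0), states, c(0.5, 0.5)),
    # columns follow parent-state order: first parent varies fastest
    tub = bn_cpt("tub", "asia", states,
                 matrix(c(0.05, 0.95, 0.01, 0.99), nrow = 2L)),
    lung = bn_cpt("lung", "smoke", states,
                  matrix(c(0.1, 0.9, 0.01, 0.99), nrow = 2L)),
    bronc = bn_cpt("bronc", "smoke", states,
                   matrix(c(0.6, 0.4, 0.3, 0.7), nrow = 2L)),
    either = bn_cpt("either", c("tub", "lung"), states,
                    array(c(1, 0, 1, 0, 1, 0, 0, 1), dim = c(2L, 2L, 2L))),
    xray = bn_cpt("xray", "either", states,
                  matrix(c(0.98, 0.02, 0.05, 0.95), nrow = 2L)),
    dysp = bn_cpt("dysp", c("bronc", "either"), states,
                  array(c(0.9, 0.1, 0.7, 0.3, 0.8, 0.2, 0.1, 0.9),
                        dim = c(2L, 2L, 2L))))
  bayesian_net(bn_dag(nodes, edges), cpts, 1L)
}

# canonical ALARM structure: 37 nodes, 46 directed edges, standard
# cardinalities. CPT entries are NOT the published ones (unavailable
# offline): they are sampled from a symmetric Dirichlet, so the fixture is
# a synthetic-parameter stand-in with the true graph.
alarm_structure <- function() {
  card3 <- c("low", "normal", "high")
  card4 <- c("zero", "low", "normal", "high")
  tf <- c("true", "false")
  states <- list(
    CVP = card3, PCWP = card3, HIST = tf, TPR = card3, BP = card3, CO = card3,
    HRBP = card3, HREKG = card3, HRSAT = card3, PAP = card3, SAO2 = card3,
    FIO2 = c("low", "normal"), PRESS = card4, EXPCO2 = card4, MINVOL = card4,
    MINVOLSET = card3, HYPOVOLEMIA = tf, LVFAILURE = tf, ANAPHYLAXIS = tf,
    INSUFFANESTH = tf, PULMEMBOLUS = tf,
    INTUBATION = c("normal", "esophageal", "onesided"), KINKEDTUBE = tf,
    DISCONNECT = tf, LVEDVOLUME = card3, STROKEVOLUME = card3,
    CATECHOL = c("normal", "high"), ERRLOWOUTPUT = tf, HR = card3,
    ERRCAUTER = tf, SHUNT = c("normal", "high"), PVSAT = card3,
    ARTCO2 = card3, VENTALV = card4, VENTLUNG = card4, VENTTUBE = card4,
    VENTMACH = card4)
  spec <- c(
    "LVFAILURE>HIST", "LVEDVOLUME>CVP", "LVEDVOLUME>PCWP",
    "HYPOVOLEMIA>LVEDVOLUME", "LVFAILURE>LVEDVOLUME",
    "HYPOVOLEMIA>STROKEVOLUME", "LVFAILURE>STROKEVOLUME",
    "ERRLOWOUTPUT>HRBP", "HR>HRBP", "ERRCAUTER>HREKG", "HR>HREKG",
    "ERRCAUTER>HRSAT", "HR>HRSAT", "ANAPHYLAXIS>TPR",
    "ARTCO2>EXPCO2", "VENTLUNG>EXPCO2", "INTUBATION>MINVOL",
    "VENTLUNG>MINVOL", "FIO2>PVSAT", "VENTALV>PVSAT", "PVSAT>SAO2",
    "SHUNT>SAO2", "PULMEMBOLUS>PAP", "INTUBATION>SHUNT",
    "PULMEMBOLUS>SHUNT", "INTUBATION>PRESS", "KINKEDTUBE>PRESS",
    "VENTTUBE>PRESS", "MINVOLSET>VENTMACH", "DISCONNECT>VENTTUBE",
    "VENTMACH>VENTTUBE", "INTUBATION>VENTLUNG", "KINKEDTUBE>VENTLUNG",
    "VENTTUBE>VENTLUNG", "INTUBATION>VENTALV", "VENTLUNG>VENTALV",
    "VENTALV>ARTCO2", "ARTCO2>CATECHOL", "INSUFFANESTH>CATECHOL",
    "SAO2>CATECHOL", "TPR>CATECHOL", "CATECHOL>HR", "HR>CO",
    "STROKEVOLUME>CO", "CO>BP", "TPR>BP")
  parts <- strsplit(spec, ">")
  edges <- cbind(from = vapply(parts, `[`, "", 1L),
                 to = vapply(parts, `[`, "", 2L))
  list(states = states, edges = edges)
}

rdirichlet_rows <- function(n, r, concentration) {
  g <- matrix(stats::rgamma(n * r, shape = concentration), nrow = r)
  sweep(g, 2L, colSums(g), "/")
}

#' ALARM-structure network with synthetic parameters
#'
#' The canonical 37-node, 46-edge ALARM monitoring-network structure with
#' synthetic CPTs drawn from a symmetric Dirichlet (the published parameters
#' are not shipped). Suitable for structure-recovery experiments, not for
#' reproducing the original network's distributions.
#'
#' @param seed Integer seed for the synthetic CPTs.
#' @param concentration Dirichlet concentration per row (default 0.5:
#'   fairly peaked rows, giving strong, learnable dependencies).
#' @return A `bayesian_net` with weight 1.
#' @export
fixture_alarm_synthetic <- function(seed = 42L, concentration = 0.5) {
  st <- alarm_structure()
  dag <- bn_dag(names(st$states), st$edges)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  cpts <- list()
  for (v in dag$nodes) {
    parents <- dag_parents(dag, v)
    r <- length(st$states[[v]])
    q <- if (length(parents)) {
      prod(vapply(st$states[parents], length, integer(1)))
    } else 1L
    rows <- rdirichlet_rows(q, r, concentration)
    cards <- vapply(st$states[parents], length, integer(1))
    cpts[[v]] <- bn_cpt(v, parents, st$states, array(rows, dim = c(r, cards)))
  }
  bayesian_net(dag, cpts, 1L)
}

#' Random Bayesian network
#'
#' DAG sampled under a random topological order (each node draws up to
#' `max_parents` parents uniformly from its predecessors); CPT rows drawn
#' from a symmetric Dirichlet.
#'
#' @param n_nodes Number of nodes (named V1..Vn).
#' @param max_parents Maximum in-degree.
#' @param cardinality States per variable (single integer or vector).
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (default 0.5).
#' @return A `bayesian_net` with weight 1.
#' @export
fixture_random_bn <- function(n_nodes, max_parents = 2L, cardinality = 2L,
                              seed = 1L, concentration = 0.5) {
  stopifnot(n_nodes >= 1L, max_parents >= 0L, all(cardinality >= 2L))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  nodes <- paste0("V", seq_len(n_nodes))
  cards <- rep(cardinality, length.out = n_nodes)
  states <- stats::setNames(
    lapply(cards, function(k) paste0("s", seq_len(k))), nodes)
  ord <- sample(nodes)
  edges <- empty_edges()
  for (i in seq_along(ord)[-1L]) {
    k <- sample.int(min(max_parents, i - 1L) + 1L, 1L) - 1L
    if (k > 0L) {
      pa <- sample(ord[seq_len(i - 1L)], k)
      edges <- rbind(edges, cbind(from = pa, to = ord[i]))
    }
  }
  dag <- bn_dag(nodes, edges)
  cpts <- list()
  for (v in nodes) {
    parents <- dag_parents(dag, v)
    r <- length(states[[v]])
    pc <- vapply(states[parents], length, integer(1))
    q <- if (length(parents)) prod(pc) else 1L
    rows <- rdirichlet_rows(q, r, concentration)
    cpts[[v]] <- bn_cpt(v, parents, states, array(rows, dim = c(r, pc)))
  }
  bayesian_net(dag, cpts, 1L)
}
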