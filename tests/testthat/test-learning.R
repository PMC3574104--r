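test_that("draft phase builds the MI spanning tree", {
  # two dependent variables -> single edge
  z <- sample(c("0", "1"), 400, replace = TRUE)
  d2 <- discrete_dataset(data.frame(x = z, y = z))
  res <- draft_mwst(d2)
  expect_identical(skeleton_keys(res$graph), "x-y")
  # chain data: tree must match the exhaustive best spanning tree on 3 nodes
  d <- forward_sample(chain_net(), 5000, seed = 31)
  res <- draft_mwst(d)
  trees <- list(c("A-B", "B-C"), c("A-B", "A-C"), c("A-C", "B-C"))
  scores <- vapply(trees, function(tr) {
    sum(vapply(strsplit(tr, "-"), function(p) mutual_information(d, p[1], p[2]),
               numeric(1)))
  }, numeric(1))
  expect_identical(skeleton_keys(res$graph), sort(trees[[which.max(scores)]]))
  expect_identical(skeleton_keys(res$graph), c("A-B", "B-C"))
})

test_that("draft with calibrated threshold leaves independent data empty", {
  d <- random_dataset(400, c("a", "b", "c", "e"), c(2, 2, 2, 2), seed = 17)
  delta <- calibrate_delta_mi(d, B = 200, probs = 0.999, seed = 5)
  res <- draft_mwst(d, bn_thresholds(delta_mi = delta))
  expect_lte(nrow(res$graph$edges), 3)
  # a generous threshold removes everything
  res2 <- draft_mwst(d, bn_thresholds(delta_mi = 0.2))
  expect_identical(nrow(res2$graph$edges), 0L)
  expect_identical(nrow(res2$remaining), 0L)
})

test_that("thickening adds truly dependent pairs and only those", {
  # empty remaining list: unchanged graph
  d <- forward_sample(chain_net(), 2000, seed = 1)
  res <- draft_mwst(d)
  g <- thicken(res$graph, res$remaining[0, ], d)
  expect_identical(skeleton_keys(g), skeleton_keys(res$graph))
  # collider data: marginally independent parents must not be joined
  dc <- forward_sample(collider_net(), 5000, seed = 8)
  resc <- draft_mwst(dc)
  gc <- thicken(resc$graph, resc$remaining, dc)
  expect_false("A-B" %in% skeleton_keys(gc))
  expect_true(all(c("A-C", "B-C") %in% skeleton_keys(gc)))
})

test_that("thinning removes shortcut edges and keeps strong trees", {
  expect_identical(nrow(thin(ugraph(c("A", "B")),
                             random_dataset(50, c("A", "B"), c(2, 2), 1))$edges),
                   0L)
  d <- forward_sample(chain_net(), 5000, seed = 13)
  tri <- ugraph(c("A", "B", "C"),
                rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  thinned <- thin(tri, d)
  expect_identical(skeleton_keys(thinned), c("A-B", "B-C"))
  # strong tree untouched
  tree <- ugraph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  expect_identical(skeleton_keys(thin(tree, d)), c("A-B", "B-C"))
})

test_that("orientation recovers monotone v-structures in most replicates", {
  hits <- 0L
  reps <- 20L
  for (s in seq_len(reps)) {
    d <- forward_sample(collider_net(), 5000, seed = 1000 + s)
    bn <- learn_bn(d)
    keys <- directed_keys(bn$dag)
    if (identical(sort(keys), sort(c("A>C", "B>C")))) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("single covered edge is oriented by the lexicographic tie-break", {
  z <- sample(c("0", "1"), 2000, replace = TRUE, prob = c(0.3, 0.7))
  w <- ifelse(stats::runif(2000) < 0.85, z, sample(c("0", "1"), 2000, TRUE))
  d <- discrete_dataset(data.frame(q = z, m = w))
  bn <- learn_bn(d)
  expect_identical(directed_keys(bn$dag), "m>q") # parent = smaller name
})

test_that("learner output is always a simple acyclic digraph", {
  for (s in 1:40) {
    gen <- fixture_random_bn(5, 2, 2, seed = s, concentration = 0.4)
    d <- forward_sample(gen, 400, seed = s + 500)
    dag <- learn_bn(d)$dag
    expect_true(oracle_union_acyclic(dag, dag))
    expect_false(any(duplicated(directed_keys(dag))))
  }
})

test_that("learn_parameters follows the counting rule with uniform fallback", {
  d <- discrete_dataset(data.frame(x = c("0", "0", "0", "1")))
  bn <- learn_parameters(d, bn_dag("x"))
  expect_equal(unname(as.vector(bn$cpts$x$prob)), c(0.75, 0.25))
  expect_identical(bn$weight, 4L)
  # unseen parent configuration -> uniform row
  d2 <- discrete_dataset(data.frame(p = factor(c("0", "0"), c("0", "1")),
                                    x = factor(c("1", "0"), c("0", "1"))))
  bn2 <- learn_parameters(d2, bn_dag(c("p", "x"), rbind(c("p", "x"))))
  expect_equal(unname(cpt_row(bn2$cpts$x, c(p = "1"))), c(0.5, 0.5))
  expect_equal(unname(cpt_row(bn2$cpts$x, c(p = "0"))), c(0.5, 0.5))
})

test_that("learn_bn is deterministic and invariant to row order/state labels", {
  d <- forward_sample(chain_net(), 1500, seed = 77)
  b1 <- learn_bn(d)
  b2 <- learn_bn(d)
  expect_identical(directed_keys(b1$dag), directed_keys(b2$dag))
  expect_equal(b1$cpts, b2$cpts)
  set.seed(3)
  dperm <- discrete_dataset(d[sample.int(nrow(d)), , drop = FALSE])
  expect_identical(directed_keys(learn_bn(dperm)$dag), directed_keys(b1$dag))
  drel <- d
  levels(drel$B) <- c("lo", "hi")
  expect_identical(directed_keys(learn_bn(drel)$dag), directed_keys(b1$dag))
  # one variable -> single-node network
  b1v <- learn_bn(d[, "A", drop = FALSE])
  expect_identical(length(b1v$dag$nodes), 1L)
  expect_identical(nrow(b1v$dag$edges), 0L)
})

test_that("3-variable skeletons match the exhaustive CI-test oracle", {
  gens <- list(chain = chain_net(), collider = collider_net())
  for (nm in names(gens)) {
    for (s in 1:5) {
      d <- forward_sample(gens[[nm]], 5000, seed = 300 + s)
      learned <- skeleton_keys(learn_bn(d)$dag)
      expect_identical(learned, oracle_ci_skeleton_3(d, 0.01),
                       label = paste(nm, s))
    }
  }
})
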