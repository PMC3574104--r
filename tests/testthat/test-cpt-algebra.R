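test_that("extend_cpt replicates rows across bogus parents", {
  bn <- fixture_random_bn(3, 1, 3, seed = 2)
  v <- bn$dag$nodes[[3]]
  cp <- bn$cpts[[v]]
  expect_identical(extend_cpt(cp, character(0)), cp)
  ex <- extend_cpt(cp, "Zq", states = list(Zq = c("a", "b", "c")))
  expect_identical(prod(dim(ex$prob)), 3 * prod(dim(cp$prob)))
  expect_true("Zq" %in% ex$parents)
  grid <- enumerate_assignments(ex$states[ex$parents])
  for (i in seq_len(nrow(grid))) {
    cfg <- cfg_row(grid, i)
    expect_equal(cpt_row(ex, cfg), cpt_row(cp, cfg), tolerance = 1e-15)
  }
  # marginalizing the bogus parent back out recovers the original (summation)
  rt <- simplify_cpt(ex, 0)
  expect_identical(rt$removed, "Zq")
  back <- rt$cpt
  grid0 <- enumerate_assignments(cp$states[cp$parents])
  for (i in seq_len(max(1L, nrow(grid0)))) {
    cfg <- if (length(cp$parents)) cfg_row(grid0, i) else character(0)
    expect_equal(cpt_row(back, cfg), cpt_row(cp, cfg), tolerance = 1e-12)
  }
  expect_error(extend_cpt(cp, cp$parents[1], states = cp$states), "overlaps")
})

test_that("common_form aligns arbitrary parent sets index-by-index", {
  st <- list(x = c("0", "1"), A = c("0", "1"), B = c("0", "1", "2"))
  ca <- bn_cpt("x", "A", st, matrix(c(0.2, 0.8, 0.7, 0.3), 2))
  cb <- bn_cpt("x", "B", st, matrix(c(0.1, 0.9, 0.5, 0.5, 0.9, 0.1), 2))
  cf <- common_form(ca, cb)
  expect_identical(cf[[1]]$parents, cf[[2]]$parents)
  expect_identical(cf[[1]]$parents, c("A", "B"))
  expect_identical(dimnames(cf[[1]]$prob), dimnames(cf[[2]]$prob))
  grid <- enumerate_assignments(st[c("A", "B")])
  for (i in seq_len(nrow(grid))) {
    cfg <- cfg_row(grid, i)
    expect_equal(cpt_row(cf[[1]], cfg), cpt_row(ca, cfg))
    expect_equal(cpt_row(cf[[2]], cfg), cpt_row(cb, cfg))
  }
  # identical parent sets: unchanged tables
  cf2 <- common_form(ca, ca)
  expect_equal(cf2[[1]]$prob, ca$prob)
  # conflicting state space for a shared parent
  st_bad <- list(x = c("0", "1"), A = c("lo", "hi"))
  cbad <- bn_cpt("x", "A", st_bad, matrix(c(0.2, 0.8, 0.7, 0.3), 2))
  expect_error(common_form(ca, cbad), "conflicting state spaces")
})

test_that("aggregation follows the weighted opinion pool arithmetic", {
  st <- list(x = c("0", "1"))
  c1 <- bn_cpt("x", character(0), st, c(0.3, 0.7))
  c2 <- bn_cpt("x", character(0), st, c(0.5, 0.5))
  agg11 <- aggregate_cpts(list(c1, c2), aggregation_spec(c(1, 1)))
  expect_equal(as.vector(agg11$prob), c(0.4, 0.6))
  agg13 <- aggregate_cpts(list(c1, c2), aggregation_spec(c(1, 3)))
  expect_equal(as.vector(agg13$prob), c(0.45, 0.55))
  # identical inputs are a fixed point for any weights
  aggfix <- aggregate_cpts(list(c1, c1), aggregation_spec(c(2, 9)))
  expect_equal(as.vector(aggfix$prob), c(0.3, 0.7))
})

test_that("count-weighted aggregation reproduces the merged database exactly", {
  for (s in 1:10) {
    bn <- fixture_random_bn(5, 2, sample(2:3, 1), seed = s)
    n1 <- 50 + 17 * s
    n2 <- 80 + 11 * s
    d1 <- forward_sample(bn, n1, seed = 2 * s + 1)
    d2 <- forward_sample(bn, n2, seed = 2 * s + 2)
    p1 <- learn_parameters(d1, bn$dag)
    p2 <- learn_parameters(d2, bn$dag)
    pm <- learn_parameters(discrete_dataset(rbind(d1, d2)), bn$dag)
    for (v in bn$dag$nodes) {
      cf <- common_form(p1$cpts[[v]], p2$cpts[[v]])
      agg <- aggregate_cpts(cf, aggregation_spec(c(n1, n2)))
      grid <- enumerate_assignments(agg$states[agg$parents])
      for (i in seq_len(max(1L, nrow(grid)))) {
        cfg <- if (length(agg$parents)) cfg_row(grid, i) else character(0)
        expect_equal(cpt_row(agg, cfg), cpt_row(pm$cpts[[v]], cfg),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("aggregation is associative under weight accumulation", {
  bn <- fixture_random_bn(4, 2, 2, seed = 3)
  ds <- lapply(1:3, function(i) forward_sample(bn, 60 + 30 * i, seed = 40 + i))
  ps <- lapply(ds, learn_parameters, dag = bn$dag)
  w <- vapply(ds, nrow, integer(1))
  for (v in bn$dag$nodes) {
    ab <- aggregate_cpts(common_form(ps[[1]]$cpts[[v]], ps[[2]]$cpts[[v]]),
                         aggregation_spec(w[1:2]))
    ab_c <- aggregate_cpts(common_form(ab, ps[[3]]$cpts[[v]]),
                           aggregation_spec(c(w[1] + w[2], w[3])))
    cf3 <- common_form(ps[[1]]$cpts[[v]], ps[[2]]$cpts[[v]])
    abc <- aggregate_cpts(c(cf3, list(ps[[3]]$cpts[[v]])),
                          aggregation_spec(w))
    expect_equal(ab_c$prob, abc$prob, tolerance = 1e-12)
  }
})

test_that("the dominant-weight limit recovers the first CPT", {
  st <- list(x = c("0", "1"), A = c("0", "1"))
  c1 <- bn_cpt("x", "A", st, matrix(c(0.2, 0.8, 0.9, 0.1), 2))
  c2 <- bn_cpt("x", "A", st, matrix(c(0.6, 0.4, 0.3, 0.7), 2))
  agg <- aggregate_cpts(list(c1, c2), aggregation_spec(c(1000000, 1)))
  expect_equal(agg$prob, c1$prob, tolerance = 1e-5)
})

test_that("variance test flags exactly the near-constant parents", {
  st <- list(x = c("0", "1"), P = c("0", "1"), Q = c("0", "1"))
  arr <- array(0, c(2, 2, 2))
  for (q in 1:2) arr[, , q] <- matrix(c(0.2, 0.8, 0.7, 0.3), 2) # Q constant
  cp <- bn_cpt("x", c("P", "Q"), st, arr)
  expect_identical(detect_bogus_parents(cp, 0), "Q")
  expect_identical(detect_bogus_parents(cp, 1), c("P", "Q"))
  # perturbed bogus parent flagged iff its average variance is below epsilon
  arr2 <- arr
  arr2[1, , 2] <- arr2[1, , 2] + 0.02
  arr2[2, , 2] <- arr2[2, , 2] - 0.02
  cp2 <- bn_cpt("x", c("P", "Q"), st, arr2)
  v <- parent_variance_profile(cp2, "Q")
  expect_equal(v, oracle_variance_profile(cp2, "Q"), tolerance = 1e-12)
  expect_identical("Q" %in% detect_bogus_parents(cp2, v + 1e-9), TRUE)
  expect_identical("Q" %in% detect_bogus_parents(cp2, v / 2), FALSE)
})

test_that("simplification removes flagged parents and matches marginalization", {
  bn <- fixture_random_bn(4, 2, 2, seed = 6)
  v <- bn$dag$nodes[vapply(bn$dag$nodes,
                           function(n) length(bn$cpts[[n]]$parents) == 2,
                           logical(1))][1]
  skip_if(is.na(v))
  cp <- bn$cpts[[v]]
  expect_identical(simplify_cpt(cp, 0)$removed, character(0))
  ex <- extend_cpt(cp, "ZZ", states = list(ZZ = c("0", "1", "2")))
  simp <- simplify_cpt(ex, 1e-9)
  expect_identical(simp$removed, "ZZ")
  expect_equal(sort(simp$cpt$parents), sort(cp$parents))
  # uniform-average marginalization oracle for a removed real parent
  p <- cp$parents[1]
  big <- parent_variance_profile(cp, p)
  simp2 <- simplify_cpt(cp, big + 1e-9)
  expect_true(p %in% simp2$removed)
  if (identical(simp2$removed, p)) {
    other <- setdiff(cp$parents, p)
    for (os in cp$states[[other]]) {
      manual <- rowMeans(vapply(cp$states[[p]], function(ps) {
        cpt_row(cp, stats::setNames(c(ps, os), c(p, other)))
      }, numeric(2)))
      expect_equal(cpt_row(simp2$cpt, stats::setNames(os, other)),
                   manual / sum(manual), tolerance = 1e-12)
    }
  }
})

test_that("extend -> aggregate equal CPTs -> simplify is the identity", {
  for (s in 1:5) {
    bn <- fixture_random_bn(4, 2, 3, seed = 20 + s)
    v <- bn$dag$nodes[[4]]
    cp <- bn$cpts[[v]]
    ex1 <- extend_cpt(cp, "E1", states = list(E1 = c("0", "1")))
    ex2 <- extend_cpt(cp, "E1", states = list(E1 = c("0", "1")))
    agg <- aggregate_cpts(list(ex1, ex2), aggregation_spec(c(3, 5)))
    fin <- simplify_cpt(agg, 0)
    expect_identical(fin$removed, "E1")
    grid <- enumerate_assignments(cp$states[cp$parents])
    for (i in seq_len(max(1L, nrow(grid)))) {
      cfg <- if (length(cp$parents)) cfg_row(grid, i) else character(0)
      expect_equal(cpt_row(fin$cpt, cfg), cpt_row(cp, cfg), tolerance = 1e-12)
    }
  }
})
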