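test_that("an exact scaled copy recovers the full diagonal match", {
  pair <- scaled_copy_pair(n = 5, scale = 2)
  g <- build_compatibility_graph(pair$mat_a, pair$mat_b)
  res <- mmm_solve(g, 0.1)
  expect_equal(res$score, 5)
  expect_equal(length(res$matches), 1)
  expect_identical(res$matches[[1]], 1:5)   # all RPDs identical = 1/scale
  expect_false(res$trivial)
})

test_that("the worked triplet instance yields its size-3 match exactly", {
  ex <- example_triplet_pair()
  g <- build_compatibility_graph(ex$mat_a, ex$mat_b)
  res <- mmm_solve(g, 0.1)
  expect_equal(res$score, 3)
  labs <- match_labels(res, g)
  expect_equal(length(labs), 1)
  got <- labs[[1]][order(labs[[1]]$a), ]
  rownames(got) <- NULL
  expect_identical(got, ex$expected_match)
})

test_that("solver equals the brute-force oracle on random instances", {
  set.seed(211)
  for (rep in 1:60) {
    inst <- random_instance()
    alpha <- sample(c(0, 0.05, 0.1, 0.3), 1)
    g <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    expect_same_matchset(mmm_solve(g, alpha), brute_force_solve(g, alpha))
  }
})

test_that("degenerate graphs score 0, 1 and 2 as documented", {
  # no vertices: disjoint species sets
  ga <- build_compatibility_graph(
    mmm_dist(matrix(c(0, 1, 1, 0), 2), c("a1", "a2"), species = c("x", "y")),
    mmm_dist(matrix(c(0, 1, 1, 0), 2), c("b1", "b2"), species = c("p", "q")))
  res0 <- mmm_solve(ga, 0.1)
  expect_equal(res0$score, 0)
  expect_length(res0$matches, 0)
  expect_true(res0$trivial)

  # vertices but all edges killed by a zero distance
  gb <- build_compatibility_graph(
    mmm_dist(matrix(0, 2, 2), c("a1", "a2"), species = c("s1", "s2")),
    mmm_dist(matrix(c(0, 1, 1, 0), 2), c("b1", "b2"), species = c("s1", "s2")))
  res1 <- mmm_solve(gb, 0.1)
  expect_equal(res1$score, 1)
  expect_length(res1$matches, 2)

  # a single compatible edge at alpha = 0 with mismatched ratios elsewhere
  gc <- build_compatibility_graph(
    mmm_dist(matrix(c(0, 1, 1, 0), 2), c("a1", "a2")),
    mmm_dist(matrix(c(0, 2, 2, 0), 2), c("b1", "b2")))
  res2 <- mmm_solve(gc, 0)
  expect_equal(res2$score, 2)
  expect_identical(match_keys(res2$matches), c("1,4", "2,3"))
})

test_that("subset closure: subsets of reported matches are matches", {
  set.seed(223)
  for (rep in 1:15) {
    inst <- random_instance()
    g <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    res <- mmm_solve(g, 0.1)
    for (m in res$matches) {
      expect_true(is_match(m, g, 0.1))
      if (length(m) > 2) {
        for (drop in seq_along(m)) {
          expect_true(is_match(m[-drop], g, 0.1))
        }
      }
    }
  }
})

test_that("score is invariant under B-rescaling and A/B swap", {
  set.seed(227)
  for (rep in 1:10) {
    inst <- random_instance(zero_dist_prob = 0)
    g <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    res <- mmm_solve(g, 0.1)

    scaled_b <- mmm_dist(inst$mat_b$values * 0.37, inst$mat_b$labels,
                         species = inst$mat_b$species)
    gs <- build_compatibility_graph(inst$mat_a, scaled_b)
    expect_same_matchset(mmm_solve(gs, 0.1), res)

    gswap <- build_compatibility_graph(inst$mat_b, inst$mat_a)
    sw <- mmm_solve(gswap, 0.1)
    expect_equal(sw$score, res$score)
    # mirrored matches: map (b, a) vertices back to (a, b) vertex ids
    remap <- vapply(sw$matches, function(m) {
      ids <- vapply(m, function(v) {
        which(g$vertices$a == gswap$vertices$b[v] &
                g$vertices$b == gswap$vertices$a[v])
      }, integer(1))
      paste(sort(ids), collapse = ",")
    }, character(1))
    expect_identical(sort(remap), match_keys(res$matches))
  }
})

test_that("score is nondecreasing in alpha; alpha = 1 hits the clique bound", {
  set.seed(229)
  for (rep in 1:10) {
    inst <- random_instance()
    g <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    scores <- vapply(c(0, 0.05, 0.1, 0.3, 0.7, 1),
                     function(a) mmm_solve(g, a)$score, integer(1))
    expect_true(all(diff(scores) >= 0))
    clq <- max_cliques_all(g$adj)
    expect_equal(scores[[6]], max(clq$size, min(nrow(g$vertices), 1)))
  }
})

test_that("maxtrees = one returns one of the full enumeration's maxima", {
  set.seed(233)
  for (rep in 1:15) {
    inst <- random_instance()
    alpha <- sample(c(0, 0.1, 0.3), 1)
    g <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    all_res <- mmm_solve(g, alpha, maxtrees = "all")
    one_res <- mmm_solve(g, alpha, maxtrees = "one")
    expect_equal(one_res$score, all_res$score)
    if (all_res$score > 0) {
      expect_length(one_res$matches, 1)
      expect_true(paste(one_res$matches[[1]], collapse = ",") %in%
                    match_keys(all_res$matches))
    }
  }
})

test_that("legacy triplet criterion accepts all solver matches but is weaker", {
  set.seed(239)
  checked <- 0
  insts <- c(
    lapply(1:15, function(i) { random_instance() }),
    lapply(1:5, function(s) {
      generate_pair(synth_spec(noise = 0.02, seed = s))[c("mat_a", "mat_b")]
    }))
  for (inst in insts) {
    g <- build_compatibility_graph(inst$mat_a, inst$mat_b)
    res <- mmm_solve(g, 0.1)
    for (m in res$matches) {
      if (length(m) >= 3) {
        expect_true(legacy_mmm_match_test(m, g, 0.1))
        checked <- checked + 1
      }
    }
  }
  expect_gte(checked, 5)

  # size-3 sets: verdicts are identical by construction
  ex <- example_triplet_pair()
  g3 <- build_compatibility_graph(ex$mat_a, ex$mat_b)
  expect_identical(legacy_mmm_match_test(1:3, g3, 0.1), is_match(1:3, g3, 0.1))

  # constructed witness: legacy accepts the 4-set, the all-pairs test does not
  w <- example_legacy_witness()
  gw <- build_compatibility_graph(w$mat_a, w$mat_b)
  expect_true(legacy_mmm_match_test(1:4, gw, 0.1))
  expect_false(is_match(1:4, gw, 0.1))
  expect_equal(mmm_solve(gw, 0.1)$score, 3)
  expect_error(legacy_mmm_match_test(1:2, gw, 0.1), "at least 3")
})
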