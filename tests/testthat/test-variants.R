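test_that("bounded pair count on the nested fixture", {
  fx <- fixture_nested()
  k1 <- solve_binary_kappa(fx$tree, fx$w, 1)
  expect_equal(k1$score, 3)
  expect_equal(pairs_of(k1), "a-c")
  ## a second pair cannot improve on (a,c): the crossing partner is blocked
  k2 <- solve_binary_kappa(fx$tree, fx$w, 2)
  expect_equal(k2$score, 3)
  expect_lte(nrow(k2$system$pairs), 2L)
  k0 <- solve_binary_kappa(fx$tree, fx$w, 0)
  expect_equal(k0$score, 0)
  expect_equal(nrow(k0$system$pairs), 0L)
})

test_that("bounded-count scores match the oracle and saturate at floor(n/2)", {
  for (i in 1:20) {
    fx <- random_instance(i)
    enum <- enumerate_path_systems(fx$tree, fx$w)
    full <- solve_mpp(fx$tree, fx$w)$score
    prev <- -Inf
    for (k in 0:5) {
      sk <- solve_binary_kappa(fx$tree, fx$w, k)
      ok <- oracle_max(enum, kappa = k)
      expect_equal(sk$score, ok$score)
      expect_lte(nrow(sk$system$pairs), k)
      expect_true(validate_path_system(fx$tree, fx$w, sk$system)$valid)
      expect_gte(sk$score, prev)        # non-decreasing in kappa
      expect_lte(sk$score, full)
      prev <- sk$score
    }
    kmax <- fx$tree$ntip %/% 2L
    expect_equal(solve_binary_kappa(fx$tree, fx$w, kmax)$score, full)
  }
})

test_that("required taxa on the nested fixture", {
  fx <- fixture_nested()
  sr <- solve_binary_required(fx$tree, fx$w, "d")
  expect_true(sr$feasible)
  expect_equal(sr$score, 3)
  expect_equal(pairs_of(sr), "b-d")
  ## empty requirement reduces to the unconstrained problem
  s0 <- solve_binary_required(fx$tree, fx$w, character(0))
  expect_equal(s0$score, solve_binary(fx$tree, fx$w)$score)
  expect_error(solve_binary_required(fx$tree, fx$w, "nope"), "unknown")
})

test_that("an odd tree with every taxon required is infeasible", {
  t3 <- parse_newick("((a,b),c);")
  sr <- solve_binary_required(t3, unit_weights(t3), c("a", "b", "c"))
  expect_false(sr$feasible)
  expect_identical(sr$score, -Inf)
})

test_that("required-taxa solutions match the constrained oracle", {
  for (i in 1:20) {
    fx <- random_instance(i)
    enum <- enumerate_path_systems(fx$tree, fx$w)
    nz <- sample(0:fx$tree$ntip, 1L)
    Z <- sample(fx$tree$tip_label, nz)
    sr <- solve_binary_required(fx$tree, fx$w, Z)
    or <- oracle_max(enum, Z = Z)
    if (or$n_optima == 0L) {
      expect_false(sr$feasible)
    } else {
      expect_true(sr$feasible)
      expect_equal(sr$score, or$score)
      expect_lte(sr$score, solve_mpp(fx$tree, fx$w)$score)
      covered <- c(sr$system$pairs$leaf1, sr$system$pairs$leaf2)
      expect_true(all(Z %in% covered))
    }
  }
})

test_that("prescribed pairs block exactly the edge-sharing pairs", {
  fx <- fixture_nested()
  pre <- apply_prescribed_pairs(fx$tree, fx$w, cbind("a", "b"))
  ## every pair touching a or b shares an edge with the a-b path
  blocked <- !is.finite(pre$weights$mat)
  for (x in c("c", "d")) {
    expect_true(blocked["a", x])
    expect_true(blocked["b", x])
  }
  expect_false(blocked["c", "d"])
  expect_equal(pre$offset, 1)
  sol <- solve_with_prescribed(fx$tree, fx$w, cbind("a", "b"))
  expect_equal(sol$score, 2)            # 1 (a,b) + 1 (c,d)
  expect_equal(pairs_of(sol), c("a-b", "c-d"))

  ## star: paths share only the root vertex, so only endpoints block
  fs <- fixture_star()
  ss <- solve_with_prescribed(fs$tree, fs$w, cbind("a", "b"))
  expect_equal(ss$score, 5 + 1)
  ## empty prescription changes nothing
  s0 <- solve_with_prescribed(fx$tree, fx$w, matrix(character(0), 0, 2))
  expect_equal(s0$score, solve_mpp(fx$tree, fx$w)$score)
  ## conflicting prescription is rejected
  expect_error(
    apply_prescribed_pairs(fx$tree, fx$w, cbind(c("a", "b"), c("c", "d"))),
    "not a valid path-system")
})

test_that("constrained variants refuse multifurcating trees", {
  fs <- fixture_star()
  expect_error(solve_binary_kappa(fs$tree, fs$w, 2),
               class = "mpp_unsupported_variant")
  expect_error(solve_binary_required(fs$tree, fs$w, "a"),
               class = "mpp_unsupported_variant")
  ## prescribed pairs are preprocessing and do work on polytomies
  expect_equal(solve_with_prescribed(fs$tree, fs$w, cbind("a", "b"))$score, 6)
})
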