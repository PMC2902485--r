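test_that("nested-quartet fixture: enumeration and optimum", {
  fx <- fixture_nested()
  enum <- enumerate_path_systems(fx$tree, fx$w)
  expect_equal(enum$count, 8L)          # 10 pairings minus 2 crossing ones
  sol <- solve_binary(fx$tree, fx$w)
  expect_equal(sol$score, 3)
  expect_equal(pairs_of(sol), "a-c")    # tie with (b,d) broken by label
  expect_equal(solve_mpp(fx$tree, fx$w)$score, sol$score)
})

test_that("star fixture: all perfect pairings valid, matching finds the best", {
  fx <- fixture_star()
  enum <- enumerate_path_systems(fx$tree, fx$w)
  expect_equal(enum$count, 10L)         # 3 perfect + 6 singles + empty
  sol <- solve_mpp(fx$tree, fx$w)
  expect_equal(sol$score, 8)
  expect_equal(pairs_of(sol), c("a-c", "b-d"))
  expect_error(solve_binary(fx$tree, fx$w), "solve_mpp")
})

test_that("degenerate inputs: single leaf, two leaves, three-leaf cherry", {
  t1 <- parse_newick("a;")
  expect_equal(solve_mpp(t1, unit_weights(t1))$score, 0)
  expect_equal(nrow(solve_mpp(t1, unit_weights(t1))$system$pairs), 0L)

  t3 <- parse_newick("((a,b),c);")
  s3 <- solve_binary(t3, unit_weights(t3))
  expect_equal(s3$score, 1)
  expect_equal(pairs_of(s3), "a-b")     # lexicographic tie-break
})

test_that("polytomy under a binary root: crossing pair re-uses no edge", {
  tr <- parse_newick("((a,b,c)m,d)r;")
  sol <- solve_mpp(tr, unit_weights(tr))
  expect_equal(sol$score, 2)
  expect_true(validate_path_system(tr, unit_weights(tr), sol$system)$valid)
})

test_that("path-system validation detects shared edges and reused leaves", {
  fx <- fixture_nested()
  ok <- validate_path_system(fx$tree, fx$w, cbind(c("a", "c"), c("b", "d")))
  expect_true(ok$valid)
  expect_equal(ok$score, 2)
  bad <- validate_path_system(fx$tree, fx$w, cbind(c("a", "b"), c("c", "d")))
  expect_false(bad$valid)               # crossing pairs share root edges
  expect_match(bad$reason, "edge")
  reuse <- validate_path_system(fx$tree, fx$w, cbind(c("a", "a"), c("b", "c")))
  expect_false(reuse$valid)
  empty <- validate_path_system(fx$tree, fx$w, matrix(character(0), 0, 2))
  expect_true(empty$valid)
  expect_equal(empty$score, 0)
  expect_error(validate_path_system(fx$tree, fx$w, cbind("a", "zz")),
               "unknown")
})

test_that("cross-pair scores decompose through the R tables", {
  fx <- fixture_star()
  sol <- solve_mpp(fx$tree, fx$w)
  ## leaf children: R terms vanish, so what = omega
  ps <- compute_pair_score_hat(fx$tree, fx$w, sol$tables, "a", "c")
  expect_equal(ps$what, 4)
  expect_equal(sort(ps$pair), c("a", "c"))
  fn <- fixture_nested()
  sn <- solve_mpp(fn$tree, fn$w)
  ph <- compute_pair_score_hat(fn$tree, fn$w, sn$tables, "u", "v")
  expect_equal(ph$what, 3)
  expect_equal(sort(ph$pair), c("a", "c"))
})

test_that("solver equals the brute-force oracle on random instances", {
  for (i in 1:30) {
    fx <- random_instance(i, multifurcating = (i %% 2L == 0L))
    sol <- solve_mpp(fx$tree, fx$w)
    om <- oracle_max(enumerate_path_systems(fx$tree, fx$w))
    expect_equal(sol$score, om$score)
    chk <- validate_path_system(fx$tree, fx$w, sol$system)
    expect_true(chk$valid)
    expect_equal(chk$score, sol$score)
  }
})

test_that("binary solver and general solver agree on binary trees", {
  for (i in 1:15) {
    fx <- random_instance(i)
    sb <- solve_binary(fx$tree, fx$w)
    sm <- solve_mpp(fx$tree, fx$w)
    expect_identical(sb$score, sm$score)
    expect_identical(sb$system$pairs, sm$system$pairs)
  }
})

test_that("score is monotone in single weights and zero for zero weights", {
  fx <- random_instance(7, multifurcating = TRUE)
  base <- solve_mpp(fx$tree, fx$w)$score
  for (rep in 1:5) {
    m <- fx$w$mat
    ij <- sample(fx$tree$ntip, 2L)
    m[ij[1L], ij[2L]] <- m[ij[2L], ij[1L]] <- m[ij[1L], ij[2L]] + 3
    expect_gte(solve_mpp(fx$tree, weights_from_matrix(m, fx$tree))$score,
               base)
  }
  zero <- weights_from_matrix(
    matrix(0, fx$tree$ntip, fx$tree$ntip,
           dimnames = list(fx$tree$tip_label, fx$tree$tip_label)), fx$tree)
  sz <- solve_mpp(fx$tree, zero)
  expect_equal(sz$score, 0)
  expect_equal(nrow(sz$system$pairs), 0L)  # ties prefer fewer pairs
})

test_that("R and Q tables never exceed the subtree optimum", {
  for (i in 1:8) {
    fx <- random_instance(i, multifurcating = TRUE)
    tb <- solve_mpp(fx$tree, fx$w)$tables
    tr <- fx$tree
    for (u in (tr$ntip + 1L):tr$nnode) {
      lx <- tr$leafset[[u]]
      expect_true(all(tb$R[u, lx] <= tb$S[u] + 1e-12))
      expect_true(all(tb$R[u, lx] >= 0))
      qv <- tb$Qval[[u]]
      expect_true(all(qv <= tb$S[u] + 1e-12))
    }
  }
})

test_that("backtraced systems are reproducible across runs", {
  fx <- random_instance(5, multifurcating = TRUE)
  s1 <- solve_mpp(fx$tree, fx$w)
  s2 <- solve_mpp(fx$tree, fx$w)
  expect_identical(s1$system$pairs, s2$system$pairs)
})
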