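## Independent check of the exact matcher: enumerate all matchings of a
## small random graph directly and compare.
brute_mwm <- function(nv, edges) {
  ne <- length(edges$i)
  best <- 0
  if (ne) {
    for (mask in 0:(2^ne - 1)) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)
      vs <- c(edges$i[sel], edges$j[sel])
      if (anyDuplicated(vs)) next
      best <- max(best, sum(edges$w[sel]))
    }
  }
  best
}

test_that("subset-DP matcher is exact on random general graphs", {
  set.seed(17)
  for (rep in 1:25) {
    nv <- sample(2:7, 1)
    full <- t(combn(nv, 2))
    keep <- runif(nrow(full)) < 0.7
    edges <- list(i = full[keep, 1], j = full[keep, 2],
                  w = round(runif(sum(keep), 0, 9), 2))
    res <- mwm_exact(nv, edges)
    expect_equal(res$weight, brute_mwm(nv, edges))
    ## returned matching is a matching and realizes the weight
    vs <- as.vector(res$matching)
    expect_false(anyDuplicated(vs) > 0)
    if (nrow(res$matching)) {
      wsum <- sum(apply(res$matching, 1, function(p) {
        hit <- (edges$i == p[1] & edges$j == p[2]) |
          (edges$i == p[2] & edges$j == p[1])
        max(edges$w[hit])
      }))
      expect_equal(wsum, res$weight)
    }
  }
})

test_that("matcher rejects oversized graphs and handles empties", {
  expect_error(mwm_exact(19, list(i = 1L, j = 2L, w = 1)), "at most")
  expect_equal(mwm_exact(0, list(i = integer(0), j = integer(0),
                                 w = numeric(0)))$weight, 0)
})

test_that("auxiliary graph has the documented size", {
  what <- matrix(1, 4, 4); diag(what) <- -Inf
  aux <- build_aux_graph(5:8, rep(0, 4), what)
  expect_equal(aux$d, 4L)
  expect_length(aux$pair_edges$w, 6L)  # + 4 self edges = 10 edges total
  aux2 <- build_aux_graph(5:6, rep(0, 2), matrix(c(-Inf, 1, 1, -Inf), 2))
  expect_length(aux2$pair_edges$w, 1L) # + 2 self edges = 3 edges total
})

test_that("auxiliary-graph matching covers every child after post-processing", {
  ## star fixture: matching picks the two crossing pairs, weight 8
  fx <- fixture_star()
  sol <- solve_mpp(fx$tree, fx$w)
  m <- sol$tables$Smatch[[fx$tree$root]]
  expect_equal(sol$tables$S[fx$tree$root], 8)
  covered <- sort(unlist(lapply(m, function(e)
    if (e$type == "pair") c(e$i, e$j) else e$i)))
  expect_equal(covered, 1:4)
  expect_equal(sum(vapply(m, function(e) e$type == "pair", logical(1))), 2L)

  ## all-zero scores: matching still covers every vertex via self edges
  what0 <- matrix(0, 3, 3)
  aux0 <- build_aux_graph(1:3, rep(0, 3), what0)
  r0 <- max_weight_matching(aux0)
  expect_equal(r0$weight, 0)
  cov0 <- sort(unlist(lapply(r0$matching, function(e)
    if (e$type == "pair") c(e$i, e$j) else e$i)))
  expect_true(all(1:3 %in% cov0))

  ## single positive pair edge dominates
  what1 <- matrix(c(-Inf, 7, 7, -Inf), 2)
  r1 <- max_weight_matching(build_aux_graph(1:2, c(0, 0), what1))
  expect_equal(r1$weight, 7)
})

test_that("negative inputs to the covered matcher are rejected", {
  what <- matrix(c(-Inf, 1, 1, -Inf), 2)
  expect_error(max_weight_matching(build_aux_graph(1:2, c(-1, 0), what)),
               "non-negative")
  whatn <- matrix(c(-Inf, -2, -2, -Inf), 2)
  expect_error(max_weight_matching(build_aux_graph(1:2, c(0, 0), whatn)),
               "non-negative")
})

test_that("matching translation: polytomy optimum equals the oracle optimum", {
  for (i in 1:10) {
    fx <- random_instance(i, multifurcating = TRUE)
    sol <- solve_mpp(fx$tree, fx$w)
    ## at every multifurcation, S(u) is the oracle optimum of the subproblem
    for (u in which(lengths(fx$tree$children) > 2L)) {
      sub <- subtree_as_tree(fx$tree, u)
      wsub <- weights_from_matrix(
        fx$w$mat[sub$tip_label, sub$tip_label], sub)
      om <- oracle_max(enumerate_path_systems(sub, wsub))
      expect_equal(sol$tables$S[u], om$score)
    }
  }
})
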