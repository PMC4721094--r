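test_that("matrix correlation behaves like off-diagonal Pearson", {
  A <- rand_net(4);
  expect_equal(matrix_correlation(A, A), 1.0)

  ## perfect anti-correlation on a 3-node fixture
  A <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  off <- row(A) != col(A)
  A[off] <- 0:5
  B[off] <- 5:0
  expect_equal(matrix_correlation(A, B), -1.0)

  ## affine invariance
  B2 <- A; B2[off] <- 2 * A[off] + 7
  expect_equal(matrix_correlation(A, B2), 1.0)

  expect_true(is.na(matrix_correlation(A, matrix(1, 3, 3))))
  expect_error(matrix_correlation(A, matrix(0, 4, 4)), "square")
})

test_that("two-node exhaustive QAP enumerates both permutations", {
  A <- matrix(c(0, 3, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- restricted_qap(A, A, one_block_partition(c("a", "b")))
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 2L)
  ## identity gives r = 1; the swap correlates (3,1) with (1,3), giving -1
  expect_setequal(round(res$replicates, 12), c(1, -1))
  ## literal strictly-greater rule: nothing exceeds r_obs = 1
  expect_equal(res$p_value, 0)
  ## the (k+1)/(n+1) estimator never returns zero
  res2 <- restricted_qap(A, A, one_block_partition(c("a", "b")), add_one = TRUE)
  expect_equal(res2$p_value, 1 / 3)
})

test_that("Monte-Carlo p matches the exhaustive p on a two-block fixture", {
  set.seed(14)
  ids <- letters[1:6]
  A <- rand_net(6, 2, ids); B <- rand_net(6, 2, ids)
  part <- structure(list(blocks = list(ids[1:3], ids[4:6]),
                         membership = stats::setNames(rep(1:2, each = 3), ids)),
                    class = "community_partition")
  ex <- restricted_qap(A, B, part)
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 36L)
  mc <- restricted_qap(A, B, part, n_perm = 1000, seed = 2,
                       exhaustive_limit = 0)
  expect_false(mc$exhaustive)
  k <- sum(mc$replicates > mc$r_obs)
  ci <- stats::qbinom(c(0.005, 0.995), 1000, ex$p_value)
  expect_gte(k, ci[1]); expect_lte(k, ci[2])
})

test_that("singleton restriction collapses the null to the identity", {
  ids <- letters[1:5]
  A <- rand_net(5, 2, ids); B <- rand_net(5, 2, ids)
  part <- structure(list(blocks = as.list(ids),
                         membership = stats::setNames(1:5, ids)),
                    class = "community_partition")
  res <- restricted_qap(A, B, part)
  expect_true(all(res$replicates == res$r_obs))
  expect_equal(res$p_value, 0)
})

test_that("one-block restriction equals the unrestricted test", {
  ids <- letters[1:7]
  A <- rand_net(7, 2, ids); B <- rand_net(7, 2, ids)
  r1 <- restricted_qap(A, B, NULL, n_perm = 300, seed = 4,
                       exhaustive_limit = 0)
  r2 <- restricted_qap(A, B, one_block_partition(ids), n_perm = 300, seed = 4,
                       exhaustive_limit = 0)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("every sampled permutation stays within its block", {
  set.seed(8)
  ids <- letters[1:9]
  A <- rand_net(9, 2, ids); B <- rand_net(9, 2, ids)
  blocks <- list(ids[1:4], ids[5:6], ids[7:9])
  part <- structure(list(blocks = blocks,
                         membership = stats::setNames(rep(1:3, c(4, 2, 3)), ids)),
                    class = "community_partition")
  res <- restricted_qap(A, B, part, n_perm = 200, seed = 6,
                        exhaustive_limit = 0, store_perms = TRUE)
  block_of <- rep(1:3, c(4, 2, 3))
  for (perm in res$perms)
    expect_true(all(block_of[perm] == block_of))
})

test_that("roles of the two matrices are exchangeable under the null", {
  ids <- letters[1:5]
  set.seed(77)
  A <- rand_net(5, 2, ids); B <- rand_net(5, 2, ids)
  ab <- restricted_qap(A, B, one_block_partition(ids))
  ba <- restricted_qap(B, A, one_block_partition(ids))
  expect_true(ab$exhaustive && ba$exhaustive)
  expect_equal(sort(ab$replicates), sort(ba$replicates))
  expect_equal(ab$p_value, ba$p_value)
})

test_that("restriction is conservative when structure is purely between-block", {
  set.seed(20)
  ids <- letters[1:8]
  block <- rep(1:2, each = 4)
  part <- structure(list(blocks = split(ids, block),
                         membership = stats::setNames(block, ids)),
                    class = "community_partition")
  p_res <- p_unres <- numeric(20)
  for (i in 1:20) {
    base <- outer(block, block, function(a, b) ifelse(a == b, 1, 6))
    diag(base) <- 0
    A <- base + matrix(stats::runif(64, 0, 0.4), 8); diag(A) <- 0
    B <- base + matrix(stats::runif(64, 0, 0.4), 8); diag(B) <- 0
    dimnames(A) <- dimnames(B) <- list(ids, ids)
    p_res[i] <- restricted_qap(A, B, part, seed = i)$p_value
    p_unres[i] <- restricted_qap(A, B, NULL, n_perm = 576, seed = i,
                                 exhaustive_limit = 0)$p_value
  }
  expect_gte(mean(p_res), mean(p_unres))
})

test_that("temporal autocorrelation flags persistent structure and skips dead days", {
  p1 <- generate_part1(part1_config(n_communities = 2, groups_per_community = 4,
                                    days = 4, takeover_hazard_postday5 = 0,
                                    seed = 3))
  nets <- build_daily_networks(p1$interactions, p1$roster, days = 1:4)
  qres <- temporal_autocorrelation(nets, n_perm = 200, seed = 9)
  expect_true(all(qres$r_obs > 0))
  expect_lt(stats::median(qres$p_value), 0.05)

  ## identical networks on consecutive days give r_obs = 1
  twice <- nets[c(1, 1)]
  twice[[2]]$day <- 2L
  q2 <- suppressWarnings(temporal_autocorrelation(twice[1:2], n_perm = 50,
                                                  seed = 1))
  expect_true(all(q2$r_obs == 1))

  ## an all-zero day is skipped with a warning, not imputed
  dead <- nets[1:2]
  dead[[2]]$W[] <- 0L
  expect_warning(q3 <- temporal_autocorrelation(dead, n_perm = 50, seed = 1),
                 "skipping")
  expect_equal(nrow(q3), 0L)
})

test_that("pre/post contrast matches the closed-form Fisher-z computation", {
  mk <- function(cm, rpre, rpost, m = 90) data.frame(
    community_id = cm, day_from = c(1, 2, 3), day_to = c(2, 3, 4),
    r_obs = c(rpre, rpost), p_value = 0, n_perm = 100, exhaustive = FALSE,
    n_blocks = 1, m = m)
  ## all equal: no contrast
  qres <- rbind(mk("a", c(0.6, 0.6), 0.6), mk("b", c(0.6, 0.6), 0.6))
  ct <- pre_post_contrast(qres, 3)
  expect_equal(ct$z_stat, 0)
  expect_equal(ct$p_value, 1)

  ## independent closed-form oracle
  set.seed(41)
  rpre <- matrix(stats::runif(10, 0.6, 0.8), 5, 2)
  rpost <- stats::runif(5, 0.2, 0.4)
  qres2 <- do.call(rbind, lapply(1:5, function(i)
    mk(letters[i], rpre[i, ], rpost[i])))
  ct2 <- pre_post_contrast(qres2, 3)
  d <- rowMeans(atanh(rpre)) - atanh(rpost)
  v <- (1 / 2 + 1) / (90 - 3)
  z_oracle <- mean(d) / sqrt(5 * v / 25)
  expect_equal(ct2$z_stat, z_oracle)
  expect_gt(ct2$z_stat, 0)
  expect_equal(ct2$p_value, 2 * stats::pnorm(-abs(z_oracle)))
})

test_that("FDR adjustment reproduces the step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  ## direct BH: monotonized p(i) * m / i
  m <- length(p)
  o <- order(p)
  bh <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(fdr_adjust(p), pmin(bh, 1))
  expect_equal(fdr_adjust(p), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.5, 5)), rep(0.5, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
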