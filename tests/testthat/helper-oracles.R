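# Independent oracles and small fixture builders used across the suite.

## Poisson IRLS (log link), independent of any model-fitting package
irls_poisson <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    WX <- X * mu
    beta_new <- solve(t(X) %*% WX, t(WX) %*% z)
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  drop(beta)
}

## all set partitions of n elements as membership vectors (restricted growth)
set_partitions <- function(n) {
  res <- list()
  rec <- function(a, i, mx) {
    if (i > n) {
      res[[length(res) + 1L]] <<- a
      return(invisible(NULL))
    }
    for (k in seq_len(mx + 1L)) rec(`[<-`(a, i, k), i + 1L, max(mx, k))
  }
  rec(integer(n), 1L, 0L)
  res
}

## hand-computed weighted modularity (kept separate from the package's)
modularity_by_hand <- function(S, membership) {
  W <- sum(S) / 2
  q <- 0
  for (b in unique(membership)) {
    idx <- membership == b
    q <- q + sum(S[idx, idx]) / (2 * W) - (sum(S[idx, ]) / (2 * W))^2
  }
  q
}

## exhaustive modularity maximization; ties broken toward fewer blocks
brute_force_best_partition <- function(S) {
  best <- NULL; best_q <- -Inf; best_k <- Inf
  for (m in set_partitions(nrow(S))) {
    q <- modularity_by_hand(S, m)
    k <- length(unique(m))
    if (q > best_q + 1e-12 || (abs(q - best_q) <= 1e-12 && k < best_k)) {
      best <- m; best_q <- q; best_k <- k
    }
  }
  list(membership = best, modularity = best_q)
}

## canonical relabeling so partitions can be compared with identical()
canon <- function(m) match(m, unique(m))

## adjacency of b disjoint blocks of size s with given within/between edge
## probabilities (planted-partition benchmark)
planted_partition_graph <- function(b, s, p_in, p_out) {
  n <- b * s
  member <- rep(seq_len(b), each = s)
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (member[i] == member[j]) p_in else p_out
    S[i, j] <- S[j, i] <- stats::rbinom(1, 1, p)
  }
  dimnames(S) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  list(S = S, membership = member)
}

## small directed matrix with named nodes and zero diagonal
rand_net <- function(n, lambda = 2, ids = sprintf("n%02d", seq_len(n))) {
  W <- matrix(stats::rpois(n * n, lambda), n, n, dimnames = list(ids, ids))
  diag(W) <- 0
  W
}

## minimal three-individual roster used by hand-count examples
tiny_roster <- function() {
  validate_roster(data.frame(
    id = c("M1", "M2", "F1"), sex = c("male", "male", "female"),
    group_id = "g1", community_id = "c1",
    manipulated = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE))
}

## outcomes table with fixed per-arm loss counts (deterministic)
outcomes_from_counts <- function(losses, n_per_arm) {
  arms <- names(losses)
  do.call(rbind, lapply(arms, function(a) {
    data.frame(group_id = sprintf("%s_%02d", a, seq_len(n_per_arm[a])),
               treatment = a,
               lost = seq_len(n_per_arm[a]) <= losses[a],
               delta_males = 0L, delta_females = 0L, delta_juveniles = 0L,
               stringsAsFactors = FALSE)
  }))
}
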