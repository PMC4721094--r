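test_that("near-flat prior recovers the closed-form 2x2 log odds ratio", {
  out <- outcomes_from_counts(c(C2 = 8, R2 = 2), c(C2 = 10, R2 = 10))
  fit <- suppressWarnings(fit_loss_model(out, prior_scale = 100))
  expect_lt(abs((fit$mu["R2"] - fit$mu["C2"]) - (-log(16))), 0.05)
})

test_that("the prior regularizes complete separation to finite estimates", {
  out <- outcomes_from_counts(c(C2 = 0, R2 = 5), c(C2 = 18, R2 = 18))
  fit <- suppressWarnings(fit_loss_model(out))
  expect_true(all(is.finite(fit$mu)))
  expect_lt(abs(fit$mu["C2"]), 10)
  expect_true(all(fit$prob > 0 & fit$prob < 1))
})

test_that("flat-prior MAP matches maximum likelihood for both model families", {
  losses <- stats::setNames(c(2, 3, 1, 2, 4, 3, 9, 5, 8), TREATMENTS)
  n <- stats::setNames(rep(19, 9), TREATMENTS)
  out <- outcomes_from_counts(losses, n)
  fit <- fit_loss_model(out, prior_scale = 1e4)
  ml <- stats::qlogis(losses / 19)
  expect_equal(unname(fit$mu[TREATMENTS]), unname(ml), tolerance = 1e-4)

  ## linear model: MAP arm means equal OLS arm means under a flat prior
  set.seed(4)
  out$lost <- FALSE
  out$delta_females <- stats::rnorm(nrow(out), rep(c(0, 1), length.out = 9)[
    match(out$treatment, TREATMENTS)], 0.7)
  dfit <- fit_delta_model(out, "females", prior_scale = 1e4)
  ols <- as.vector(tapply(out$delta_females, out$treatment, mean)[dfit$levels])
  expect_equal(unname(dfit$mu), ols, tolerance = 1e-4)
})

test_that("omnibus test is calibrated under the null and order-invariant", {
  ## arm counts large enough for the chi-square approximation to hold
  set.seed(6)
  p_null <- replicate(100, {
    out <- outcomes_from_counts(
      stats::setNames(stats::rbinom(9, 40, 0.3), TREATMENTS),
      stats::setNames(rep(40, 9), TREATMENTS))
    if (length(unique(out$lost)) < 2) return(NA_real_)
    fit <- stats::glm(lost ~ factor(treatment), binomial, data = out)
    stats::pchisq(fit$null.deviance - fit$deviance, 8, lower.tail = FALSE)
  })
  expect_gt(mean(p_null, na.rm = TRUE), 0.4)

  out <- outcomes_from_counts(stats::setNames(c(1:4, 4:1, 5), TREATMENTS),
                              stats::setNames(rep(15, 9), TREATMENTS))
  f1 <- fit_loss_model(out)
  f2 <- fit_loss_model(out[rev(seq_len(nrow(out))), ])
  expect_equal(f1$omnibus$statistic, f2$omnibus$statistic)
})

test_that("the nine planned contrasts are exactly the pre-specified family", {
  out <- outcomes_from_counts(stats::setNames(c(2, 2, 2, 3, 3, 3, 8, 6, 7),
                                              TREATMENTS),
                              stats::setNames(rep(19, 9), TREATMENTS))
  fit <- fit_loss_model(out)
  ct <- planned_contrasts(fit)
  expect_identical(ct$label,
                   c("R2-C_repl", "R4-C_repl", "A2-C_add", "A4-C_add",
                     "AR2-pooled", "AR4-pooled", "R4-R2", "A4-A2", "AR4-AR2"))
  expect_true(all(ct$p_fdr >= ct$p))
  ## pooled control is the equal-weight average of the two active controls
  expect_equal(ct$estimate[ct$label == "AR2-pooled"],
               unname(fit$mu["AR2"] - (fit$mu["C2"] + fit$mu["C3"]) / 2))
  ## degenerate self-contrast hook
  K <- matrix(0, 1, 9, dimnames = list("AR2-AR2", TREATMENTS))
  self <- socnetqap:::apply_contrasts(fit, K)
  expect_equal(self$estimate, 0)
  expect_equal(self$p, 1)
})

test_that("contrasts referencing an absent arm fail loudly", {
  out <- outcomes_from_counts(stats::setNames(c(2, 2, 2, 3, 3, 3, 8, 6),
                                              TREATMENTS[-9]),
                              stats::setNames(rep(19, 8), TREATMENTS[-9]))
  fit <- suppressWarnings(fit_loss_model(out))
  expect_error(planned_contrasts(fit), "AR4")
})

test_that("pooled-control contrasts collapse correctly for identical controls", {
  losses <- stats::setNames(c(3, 3, 3, 2, 4, 5, 9, 6, 8), TREATMENTS)
  out <- outcomes_from_counts(losses, stats::setNames(rep(20, 9), TREATMENTS))
  fit <- fit_loss_model(out, prior_scale = 1e4)
  pc <- pooled_control_contrasts(fit)
  expect_equal(nrow(pc), 6L)
  ## identical controls: pool equals each control mean
  expect_equal(pc$estimate[pc$label == "R2-pooledC"],
               unname(fit$mu["R2"] - fit$mu["C1"]), tolerance = 1e-6)
})

test_that("all-zero deltas give null estimates and an omnibus p of 1", {
  out <- outcomes_from_counts(stats::setNames(rep(0, 9), TREATMENTS),
                              stats::setNames(rep(5, 9), TREATMENTS))
  out$lost <- FALSE
  dfit <- fit_delta_model(out, "females")
  expect_equal(unname(dfit$mu), rep(0, 9), tolerance = 1e-6)
  expect_equal(dfit$omnibus$p, 1)
  ct <- planned_contrasts(dfit)
  expect_equal(ct$estimate, rep(0, 9), tolerance = 1e-6)
})

test_that("planted female recruitment is recovered for the augmented arms", {
  hits <- matrix(NA, 60, 9)
  male_hits <- matrix(NA, 60, 9)
  for (i in 1:60) {
    cen <- generate_part2(part2_config(seed = 300 + i))
    out <- to_outcomes(cen)
    ctf <- planned_contrasts(fit_delta_model(out, "females"))
    ctm <- planned_contrasts(fit_delta_model(out, "males"))
    hits[i, ] <- ctf$p_fdr < 0.05
    male_hits[i, ] <- ctm$p_fdr < 0.05
    if (i == 1) colnames(hits) <- colnames(male_hits) <- ctf$label
  }
  planted <- c("A4-C_add", "AR2-pooled", "AR4-pooled")
  expect_true(all(colMeans(hits[, planted]) > 0.5))
  expect_true(all(colMeans(hits[, c("R2-C_repl", "R4-C_repl")]) < 0.2))
  expect_true(all(colMeans(male_hits[, planted]) < 0.5))
})
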