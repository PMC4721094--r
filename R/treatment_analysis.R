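#' @title Territory-loss and membership-change models with planned contrasts
#' @description Part II inference: MAP Bayesian logistic regression of
#'   territory loss on the nine-arm treatment factor, Gaussian models of the
#'   change in group composition, nine planned least-squares-means contrasts
#'   with FDR correction, and the pooled-control alternative contrast family.
#' @name treatment_analysis
NULL

## negative log density of the scaled Student-t(df) prior, elementwise
neg_log_t_prior <- function(beta, scale, df = 3) {
  -sum(stats::dt(beta / scale, df = df, log = TRUE) - log(scale))
}

#' MAP Bayesian logistic regression of territory loss on treatment
#'
#' Territory loss (1 = lost, 0 = kept) is regressed on the nine-level
#' treatment factor, parameterized as one logit mean per arm. Each arm mean
#' carries an independent weakly-informative Student-t(3, 0, `prior_scale`)
#' prior, which regularizes arms with complete separation (e.g. zero losses)
#' to finite estimates. The posterior mode is found by quasi-Newton
#' optimization and summarized with the Laplace (inverse-Hessian) covariance.
#' The omnibus treatment test is a maximum-likelihood likelihood-ratio test of
#' the treatment model against the intercept-only model.
#'
#' @param outcomes `outcomes` table from [to_outcomes()] (or any data frame
#'   with `treatment` and logical `lost`).
#' @param prior_scale scale of the Student-t prior on the logit means
#'   (default 2.5).
#' @return Object of class `loss_model_fit`: `levels`, `mu` (MAP logit mean
#'   per arm), `sigma` (Laplace covariance), `prob` (MAP loss probability per
#'   arm), `omnibus` (statistic, df, p), `n` per arm, `prior_scale`,
#'   `response_scale = "logit"`.
#' @export
fit_loss_model <- function(outcomes, prior_scale = 2.5) {
  y <- as.integer(outcomes$lost)
  arm <- as.character(outcomes$treatment)
  counts <- table(arm)
  empty <- setdiff(unique(TREATMENTS), names(counts))
  if (length(empty))
    warning("treatment arm(s) with zero groups dropped: ",
            paste(empty, collapse = ", "))
  levels <- intersect(TREATMENTS, names(counts))
  if (length(levels) < 2) stop("need at least two represented treatment arms")
  if (length(unique(y)) < 2)
    stop("both outcomes must be represented overall")
  X <- outer(arm, levels, `==`) * 1
  nlp <- function(beta) {
    eta <- drop(X %*% beta)
    ## numerically stable log(1 + exp(eta))
    log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))
    -sum(y * eta - log1pe) + neg_log_t_prior(beta, prior_scale)
  }
  opt <- stats::optim(rep(0, length(levels)), nlp, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 1000, reltol = 1e-14))
  mu <- stats::setNames(opt$par, levels)
  sigma <- solve(opt$hessian)
  dimnames(sigma) <- list(levels, levels)
  ## omnibus LRT at the MLE (treatment vs intercept-only)
  f1 <- stats::glm(y ~ factor(arm), family = stats::binomial())
  stat <- f1$null.deviance - f1$deviance
  df <- length(levels) - 1L
  omnibus <- list(statistic = stat, df = df,
                  p = stats::pchisq(stat, df, lower.tail = FALSE))
  structure(list(levels = levels, mu = mu, sigma = sigma,
                 prob = stats::plogis(mu), omnibus = omnibus,
                 n = as.integer(counts[levels]), prior_scale = prior_scale,
                 response_scale = "logit", model_type = "logistic"),
            class = c("loss_model_fit", "arm_model_fit"))
}

#' MAP Bayesian linear model of membership change on treatment
#'
#' The change in the number of individuals of one class (males, females or
#' juveniles) between the final and first census, modelled as Gaussian with
#' one mean per treatment arm and a common residual standard deviation.
#' Fitted on the non-lost groups only. Arm means carry Student-t(3, 0,
#' `prior_scale * sd(y)`) priors (the scale is standardized by the response
#' spread, as is conventional for weakly-informative linear-model priors);
#' the residual scale has a flat prior on log(sigma). MAP + Laplace summary;
#' omnibus maximum-likelihood LRT against the intercept-only model.
#'
#' @param outcomes `outcomes` table.
#' @param sex which delta to model: `"females"`, `"males"` or `"juveniles"`.
#' @param prior_scale base prior scale (default 2.5), multiplied by `sd(y)`
#'   (floored at 1) to set the prior on arm means.
#' @return Object of class `delta_model_fit` (also `arm_model_fit`) with the
#'   same shape as [fit_loss_model()] plus `sigma_resid`;
#'   `response_scale = "mean"`.
#' @export
fit_delta_model <- function(outcomes, sex = c("females", "males", "juveniles"),
                            prior_scale = 2.5) {
  sex <- match.arg(sex)
  df0 <- outcomes[!outcomes$lost, , drop = FALSE]
  if (!nrow(df0)) stop("no non-lost groups to model")
  y <- df0[[paste0("delta_", sex)]]
  arm <- as.character(df0$treatment)
  counts <- table(arm)
  levels <- intersect(TREATMENTS, names(counts))
  low <- levels[counts[levels] < 2]
  if (length(low))
    warning("arm(s) with < 2 non-lost groups are low-information: ",
            paste(low, collapse = ", "))
  X <- outer(arm, levels, `==`) * 1
  sc <- prior_scale * max(stats::sd(y), 1)
  nlp <- function(par) {
    mu <- par[seq_along(levels)]
    lsig <- par[length(par)]
    sig <- exp(lsig)
    -sum(stats::dnorm(y, drop(X %*% mu), sig, log = TRUE)) +
      neg_log_t_prior(mu, sc)
  }
  start <- c(rep(mean(y), length(levels)), log(max(stats::sd(y), 0.1)))
  opt <- stats::optim(start, nlp, method = "L-BFGS-B",
                      lower = c(rep(-Inf, length(levels)), log(1e-3)),
                      hessian = TRUE, control = list(maxit = 1000))
  mu <- stats::setNames(opt$par[seq_along(levels)], levels)
  H <- opt$hessian
  sigma <- tryCatch({
    S <- solve(H)[seq_along(levels), seq_along(levels), drop = FALSE]
    dimnames(S) <- list(levels, levels)
    S
  }, error = function(e) {
    ## degenerate (e.g. all-zero response): fall back to prior-only curvature
    S <- diag(sc^2, length(levels))
    dimnames(S) <- list(levels, levels)
    S
  })
  ## omnibus ML LRT (treatment vs intercept-only)
  if (stats::var(y) < .Machine$double.eps) {
    omnibus <- list(statistic = 0, df = length(levels) - 1L, p = 1)
  } else {
    f1 <- stats::lm(y ~ factor(arm))
    f0 <- stats::lm(y ~ 1)
    stat <- 2 * (as.numeric(stats::logLik(f1)) - as.numeric(stats::logLik(f0)))
    df <- length(levels) - 1L
    omnibus <- list(statistic = stat, df = df,
                    p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  structure(list(levels = levels, mu = mu, sigma = sigma,
                 sigma_resid = exp(opt$par[length(opt$par)]),
                 omnibus = omnibus, n = as.integer(counts[levels]),
                 prior_scale = prior_scale, response = paste0("delta_", sex),
                 response_scale = "mean", model_type = "linear",
                 low_information = low),
            class = c("delta_model_fit", "arm_model_fit"))
}

#' @export
print.arm_model_fit <- function(x, ...) {
  cat(sprintf("%s model of %s on treatment (MAP + Laplace, t(3, 0, %.3g) priors)\n",
              x$model_type,
              if (x$model_type == "logistic") "territory loss" else x$response,
              x$prior_scale))
  tab <- data.frame(arm = x$levels, n = x$n, estimate = unname(x$mu),
                    se = sqrt(diag(x$sigma)))
  if (!is.null(x$prob)) tab$prob <- unname(x$prob)
  print(tab, digits = 3, row.names = FALSE)
  cat(sprintf("omnibus LRT: chi-sq = %.3f, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  invisible(x)
}

## build the contrast matrix for the nine planned comparisons
nine_contrast_matrix <- function(levels, c_repl = "C2", c_add = "C3") {
  unit <- function(a) stats::setNames(as.numeric(levels == a), levels)
  pooled <- (unit(c_repl) + unit(c_add)) / 2
  rows <- list(
    "R2-C_repl"  = unit("R2") - unit(c_repl),
    "R4-C_repl"  = unit("R4") - unit(c_repl),
    "A2-C_add"   = unit("A2") - unit(c_add),
    "A4-C_add"   = unit("A4") - unit(c_add),
    "AR2-pooled" = unit("AR2") - pooled,
    "AR4-pooled" = unit("AR4") - pooled,
    "R4-R2"      = unit("R4") - unit("R2"),
    "A4-A2"      = unit("A4") - unit("A2"),
    "AR4-AR2"    = unit("AR4") - unit("AR2"))
  do.call(rbind, rows)
}

apply_contrasts <- function(fit, K) {
  need <- colnames(K)[colSums(abs(K)) > 0]
  miss <- setdiff(need, fit$levels)
  if (length(miss)) {
    bad <- rownames(K)[rowSums(abs(K[, miss, drop = FALSE])) > 0]
    stop("contrast(s) reference absent arm(s): ", paste(bad, collapse = ", "))
  }
  K <- K[, fit$levels, drop = FALSE]
  est <- drop(K %*% fit$mu)
  se <- sqrt(diag(K %*% fit$sigma %*% t(K)))
  z <- ifelse(est == 0 & se == 0, 0, est / se)
  p <- ifelse(est == 0, 1, 2 * stats::pnorm(-abs(z)))
  out <- data.frame(label = rownames(K), estimate = est, se = se,
                    z_ratio = z, p = p, stringsAsFactors = FALSE)
  out$p_fdr <- fdr_adjust(out$p)
  rownames(out) <- NULL
  class(out) <- c("contrast_results", "data.frame")
  out
}

#' Nine planned treatment contrasts
#'
#' The pre-specified comparison family of the manipulation experiment:
#' replacing arms against the replacement control (`R2-C_repl`, `R4-C_repl`),
#' adding arms against the adding control (`A2-C_add`, `A4-C_add`),
#' combination arms against the equal-weight pool of the two active controls
#' (`AR2-pooled`, `AR4-pooled`), and the two-versus-four-shell comparisons
#' (`R4-R2`, `A4-A2`, `AR4-AR2`). Estimates are differences of arm means on
#' the model's scale (logit for the loss model, raw mean for delta models)
#' with delta-method SEs from the Laplace covariance; p-values are two-sided
#' normal, FDR-adjusted across the nine.
#'
#' Control arms are addressed by function: `c_repl` is the control whose
#' broken shells were replaced by other broken shells, `c_add` the control
#' that received extra broken shells.
#'
#' @param fit a `loss_model_fit` or `delta_model_fit`.
#' @param c_repl,c_add treatment codes of the replacement-style and
#'   adding-style controls (defaults `"C2"`, `"C3"`).
#' @return `contrast_results` data frame with exactly nine rows.
#' @export
planned_contrasts <- function(fit, c_repl = "C2", c_add = "C3") {
  stopifnot(inherits(fit, "arm_model_fit"))
  apply_contrasts(fit, nine_contrast_matrix(TREATMENTS, c_repl, c_add))
}

#' Pooled-control alternative contrasts
#'
#' Each of the six active arms compared against the equal-weight pool of all
#' three controls (C1-C3); FDR-adjusted across the six. Reported alongside
#' the nine planned contrasts as a robustness check.
#'
#' @param fit a `loss_model_fit` or `delta_model_fit`.
#' @return `contrast_results` data frame with six rows.
#' @export
pooled_control_contrasts <- function(fit) {
  stopifnot(inherits(fit, "arm_model_fit"))
  levels <- TREATMENTS
  unit <- function(a) stats::setNames(as.numeric(levels == a), levels)
  pool <- (unit("C1") + unit("C2") + unit("C3")) / 3
  arms <- c("R2", "R4", "A2", "A4", "AR2", "AR4")
  K <- do.call(rbind, lapply(arms, function(a) unit(a) - pool))
  rownames(K) <- paste0(arms, "-pooledC")
  apply_contrasts(fit, K)
}
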