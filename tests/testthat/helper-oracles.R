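# Small phantom used across tests (fast; same topology as the default)
small_spec <- function(...) {
  phantom_spec(dim = c(16, 16, 6), margin_xy = 3, margin_z = 1,
               shell_xy = 2, shell_z = 1, ...)
}

true_masks <- function(phantom) {
  tissue_masks((phantom$tissue == 2L) + 0L, (phantom$tissue == 1L) + 0L)
}

# Independent numeric-integration oracle for the water-exchange factor:
# integrates the piecewise relaxation of a spin delivered at u over the
# bolus, without using the closed form.
q_oracle <- function(t, ti1, t1a, t1t, tex) {
  integrand <- function(u) {
    dt <- t - u
    ifelse(dt < tex, exp(-t / t1a),
           exp(-(u + tex) / t1a) * exp(-(dt - tex) / t1t))
  }
  stats::integrate(integrand, 0, ti1, rel.tol = 1e-12)$value /
    (ti1 * exp(-t / t1a))
}

# Independent normal-equations oracle for a single OLS block
ols_oracle <- function(y, X) {
  Xi <- cbind(1, X)
  XtX <- t(Xi) %*% Xi
  b <- solve(XtX, t(Xi) %*% y)
  res <- y - Xi %*% b
  n <- length(y); k <- ncol(X)
  rss <- sum(res^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  se <- sqrt(diag(solve(XtX)) * rss / (n - k - 1))
  list(b = drop(b)[-1], intercept = drop(b)[1], se = se[-1], r2 = r2,
       beta = drop(b)[-1] * apply(X, 2, sd) / sd(y))
}

block1_vars <- c("age", "sex", "wtar", "cardiac_index", "heart_rate",
                 "htn", "dm", "afib")

# Monte-Carlo helper: fit the standard two-block model on a simulated
# cohort; returns NULL for the rare degenerate draw (a rank-deficient
# design, e.g. no participant with atrial fibrillation at n = 52), on
# which the F statistic is undefined. Calibration statements are
# conditional on estimable designs.
mc_fit <- function(spec, seed, outcome = "rbans_total") {
  co <- simulate_cohort(spec, seed = seed)
  tryCatch(
    suppressMessages(hierarchical_fit(co, outcome, block1_vars,
                                      "perfusion_total")),
    error = function(e) {
      if (grepl("collinear", conditionMessage(e))) NULL else stop(e)
    })
}
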