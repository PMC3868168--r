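#' @title Cohort-level statistics
#' @description Score standardization, listwise exclusion, the bivariate
#'   correlation screen, and two-block hierarchical ordinary-least-squares
#'   regression with an R-squared-change F-test.
#' @name cohort_stats
NULL

#' Convert raw scores to standard scores (mean 100, SD 15)
#'
#' Linear transform against normative reference moments:
#' \code{100 + 15 * (raw - mean_ref) / sd_ref}. Normative tables themselves
#' are inputs, not part of the package.
#'
#' @param raw Raw score(s).
#' @param mean_ref,sd_ref Reference mean and SD; \code{sd_ref > 0}.
#' @return Standard score(s).
#' @export
standardize_scores <- function(raw, mean_ref, sd_ref) {
  if (any(sd_ref <= 0)) stop("'sd_ref' must be positive")
  100 + 15 * (raw - mean_ref) / sd_ref
}

#' Listwise exclusion for one model
#'
#' Removes every participant missing the outcome or any predictor entering
#' the model, the conservative completion of outcome-wise exclusion.
#'
#' @param cohort Data.frame, one row per participant.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names (optional).
#' @return The filtered data.frame; attribute \code{n_removed} records the
#'   exclusion count.
#' @export
listwise_filter <- function(cohort, outcome, predictors = character()) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("column(s) not in cohort: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(cohort[, cols, drop = FALSE])
  out <- cohort[keep, , drop = FALSE]
  if (!nrow(out))
    stop("no complete cases remain for outcome '", outcome, "'")
  n_rm <- sum(!keep)
  if (n_rm > 0)
    message(n_rm, " participant(s) excluded listwise for '", outcome, "'")
  attr(out, "n_removed") <- n_rm
  out
}

#' Bivariate correlation screen
#'
#' Pearson correlations between each perfusion composite and each
#' cardiovascular variable, pairwise-complete, with the degrees of freedom
#' (n - 2) reported alongside r as in \code{r(df)} notation.
#'
#' @param cohort Data.frame.
#' @param perfusion_columns,cvd_columns Column names to cross.
#' @return Data.frame: \code{perfusion}, \code{cvd}, \code{r}, \code{df},
#'   \code{p}, \code{n}; \code{r} is \code{NA} (flagged) for constant
#'   columns.
#' @export
bivariate_screen <- function(cohort, perfusion_columns, cvd_columns) {
  grid <- expand.grid(perfusion = perfusion_columns, cvd = cvd_columns,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- cohort[[grid$perfusion[i]]]
    y <- cohort[[grid$cvd[i]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L) stop("fewer than 3 complete pairs for ",
                     grid$perfusion[i], " vs ", grid$cvd[i])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(grid[i, ], r = NA_real_, df = n - 2L,
                        p = NA_real_, n = n, row.names = NULL))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(grid[i, ], r = unname(ct$estimate),
               df = unname(ct$parameter), p = ct$p.value, n = n,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Two-block hierarchical regression
#'
#' Fits the nested ordinary-least-squares models
#' outcome ~ block1 (+ extra covariates) and
#' outcome ~ block1 + block2 (+ extra covariates) on the listwise-complete
#' rows, and tests the increment with
#' \deqn{F_{\Delta R^2} = \frac{(R^2_2 - R^2_1)/\Delta k}
#'   {(1 - R^2_2)/(n - k_2 - 1)}.}
#' Standardized betas are computed on the z-scored outcome and predictors
#' (binary predictors z-scored as-is); reported SEs are those of the
#' unstandardized coefficients. No multiple-testing correction is applied;
#' the number of models fit in a session is the user's to track.
#'
#' @param cohort Data.frame, one row per participant.
#' @param outcome Outcome column name.
#' @param block1 Character vector of block-1 predictor columns
#'   (demographic/medical covariates).
#' @param block2 Character vector of block-2 (focal) predictor columns.
#' @param extra_covariates Optional further block-1 covariates (e.g.,
#'   intracranial volume for structural outcomes).
#' @return Object of class \code{hreg}: coefficient tables per block
#'   (standardized beta, unstandardized b, SE of b), per-block R-squared
#'   and overall F with df, and the block-2 increment (delta R-squared, its
#'   F, df and p), plus \code{n} and the listwise exclusion count.
#' @seealso \code{\link{print.hreg}}, \code{\link{summary.hreg}},
#'   \code{\link{coef.hreg}}
#' @export
hierarchical_fit <- function(cohort, outcome, block1, block2,
                             extra_covariates = character()) {
  b1 <- c(block1, extra_covariates)
  preds <- c(b1, block2)
  dat <- listwise_filter(cohort, outcome, preds)
  n <- nrow(dat)
  if (n <= length(preds) + 1L)
    stop("insufficient df: n = ", n, " with ", length(preds), " predictors")
  y <- dat[[outcome]]

  fit_block <- function(vars) {
    X <- cbind(`(Intercept)` = 1, as.matrix(dat[, vars, drop = FALSE]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop_idx <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
      stop("collinear predictors: ",
           paste(colnames(X)[drop_idx], collapse = ", "))
    }
    b <- qr.coef(qrX, y)
    res <- y - X %*% b
    rss <- sum(res^2)
    tss <- sum((y - mean(y))^2)
    k <- length(vars)
    sigma2 <- rss / (n - k - 1L)
    XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
    se <- sqrt(diag(XtXinv) * sigma2)
    r2 <- 1 - rss / tss
    fstat <- (r2 / k) / ((1 - r2) / (n - k - 1L))
    beta_std <- b[-1] * apply(dat[, vars, drop = FALSE], 2, stats::sd) /
      stats::sd(y)
    list(coef = data.frame(predictor = vars,
                           beta = unname(beta_std),
                           b = unname(b[-1]),
                           se_b = unname(se[-1]),
                           row.names = NULL),
         intercept = unname(b[1]), r2 = r2, f = fstat,
         df = c(k, n - k - 1L),
         f_p = stats::pf(fstat, k, n - k - 1L, lower.tail = FALSE))
  }

  m1 <- fit_block(b1)
  m2 <- fit_block(preds)
  dk <- length(preds) - length(b1)
  dr2 <- m2$r2 - m1$r2
  df2 <- n - length(preds) - 1L
  f_delta <- (dr2 / dk) / ((1 - m2$r2) / df2)
  structure(list(outcome = outcome, n = n,
                 n_removed = attr(dat, "n_removed"),
                 block1 = m1, block2 = m2,
                 delta = list(r2 = dr2, f = f_delta, df = c(dk, df2),
                              p = stats::pf(f_delta, dk, df2,
                                            lower.tail = FALSE))),
            class = "hreg")
}

.stars <- function(p) ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))

#' @export
print.hreg <- function(x, digits = 3, ...) {
  cat("Two-block hierarchical regression\n")
  cat("Outcome:", x$outcome, "  n =", x$n,
      if (x$n_removed > 0) sprintf("(%d excluded listwise)", x$n_removed)
      else "", "\n\n")
  fmt <- function(m, label) {
    cat(label, "\n")
    tab <- m$coef
    tab$beta <- round(tab$beta, digits)
    tab$se_b <- signif(tab$se_b, digits)
    tab$b <- signif(tab$b, digits)
    print(tab, row.names = FALSE)
    cat(sprintf("  R^2 = %.*f, F(%d, %d) = %.*f%s\n", digits, m$r2,
                m$df[1], m$df[2], digits, m$f, .stars(m$f_p)))
  }
  fmt(x$block1, "Block 1")
  cat("\n")
  fmt(x$block2, "Block 2")
  cat(sprintf("\n  Delta R^2 = %.*f, F(%d, %d) for Delta R^2 = %.*f%s (p = %.3g)\n",
              digits, x$delta$r2, x$delta$df[1], x$delta$df[2], digits,
              x$delta$f, .stars(x$delta$p), x$delta$p))
  invisible(x)
}

#' Summarize a hierarchical regression as a tidy table
#'
#' One row per predictor and block, mirroring the columns of a published
#' two-block regression table (standardized beta, SE of b, block R-squared,
#' block F, F for the R-squared change).
#'
#' @param object An \code{hreg} object.
#' @param ... Unused.
#' @return Data.frame of class \code{summary.hreg}.
#' @export
summary.hreg <- function(object, ...) {
  rows <- rbind(
    cbind(block = 1L, object$block1$coef),
    cbind(block = 2L, object$block2$coef))
  rows$r2 <- ifelse(rows$block == 1L, object$block1$r2, object$block2$r2)
  rows$outcome <- object$outcome
  rows$n <- object$n
  out <- rows[, c("outcome", "n", "block", "predictor", "beta", "b",
                  "se_b", "r2")]
  attr(out, "block_f") <- c(object$block1$f, object$block2$f)
  attr(out, "delta") <- object$delta
  class(out) <- c("summary.hreg", "data.frame")
  out
}

#' @export
print.summary.hreg <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  d <- attr(x, "delta")
  cat(sprintf("F for Delta R^2: F(%d, %d) = %.3f, p = %.3g\n",
              d$df[1], d$df[2], d$f, d$p))
  invisible(x)
}

#' @export
#' @rdname summary.hreg
#' @param standardized Return standardized betas (default) or raw b.
coef.hreg <- function(object, standardized = TRUE, ...) {
  tab <- object$block2$coef
  out <- if (standardized) tab$beta else tab$b
  names(out) <- tab$predictor
  out
}
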