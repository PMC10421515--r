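#' Validation statistics for a prediction set
#'
#' Computes the standard QSAR validation suite from observed and predicted
#' activities:
#' \itemize{
#'   \item \eqn{R^2 = 1 - \sum(y_i - f_i)^2 / \sum(y_i - \bar y)^2}
#'   \item adjusted \eqn{R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)}
#'   \item \eqn{MAE = \frac{1}{n}\sum |y_i - f_i|}
#'   \item \eqn{RSS = \sum (y_i - f_i)^2}
#'   \item \eqn{SDEC = \sqrt{RSS / n}}
#' }
#'
#' The headline \code{r2} is the squared Pearson correlation between
#' observed and predicted values ("correlation coefficient between
#' experimental and predicted"); for in-sample OLS predictions it equals
#' the residual-based \eqn{1 - RSS/SS_{tot}}, which is also reported
#' separately as \code{r2_resid} because the two differ on an external
#' prediction set.
#'
#' @param y_obs Observed pIC50 values.
#' @param y_pred Predicted pIC50 values (same length, n >= 3).
#' @param p Number of predictors in the model generating \code{y_pred}
#'   (used only for adjusted R2); must satisfy \code{p < n - 1}.
#' @return Object of class \code{validation_report}: list with fields
#'   \code{r2}, \code{r2_adj}, \code{r2_resid}, \code{mae}, \code{rss},
#'   \code{sdec}, \code{n}, \code{p}.
#' @examples
#' qsar_validate(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), p = 1)
#' @export
qsar_validate <- function(y_obs, y_pred, p) {
  stopifnot(is.numeric(y_obs), is.numeric(y_pred),
            length(y_obs) == length(y_pred))
  n <- length(y_obs)
  if (n < 3L) stopf("need at least 3 observations")
  stopifnot(is_count(p), p < n - 1L)
  if (anyNA(y_obs) || anyNA(y_pred)) stopf("NA in observed/predicted values")
  sstot <- sum((y_obs - mean(y_obs))^2)
  if (sstot == 0) stopf("zero variance in observed values: R2 undefined")
  rss <- sum((y_obs - y_pred)^2)
  r2 <- if (stats::var(y_pred) == 0) 0 else
    stats::cor(y_obs, y_pred)^2
  structure(list(r2 = r2,
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
                 r2_resid = 1 - rss / sstot,
                 mae = mean(abs(y_obs - y_pred)),
                 rss = rss,
                 sdec = sqrt(rss / n),
                 n = n, p = as.integer(p)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d, p = %d\n", x$n, x$p))
  cat(sprintf("  R2        %8.4f\n  adj R2    %8.4f\n  R2 resid  %8.4f\n",
              x$r2, x$r2_adj, x$r2_resid))
  cat(sprintf("  MAE       %8.4f\n  RSS       %8.4f\n  SDEC      %8.4f\n",
              x$mae, x$rss, x$sdec))
  invisible(x)
}

#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(r2 = x$r2, r2_adj = x$r2_adj, r2_resid = x$r2_resid,
             mae = x$mae, rss = x$rss, sdec = x$sdec, n = x$n, p = x$p)
}

#' Leave-one-out cross-validated Q2
#'
#' \eqn{Q^2 = 1 - PRESS / SS_{tot}} where PRESS sums the squared
#' leave-one-out prediction errors, each from a model refit without the
#' held-out observation. Computed through the exact hat-matrix identity
#' \eqn{e_{(i)} = e_i / (1 - h_{ii})} for OLS, which equals the n-refit
#' result to machine precision.
#'
#' @param x Descriptor matrix (selected columns only).
#' @param y Activity vector.
#' @return Q2 as a single numeric value.
#' @export
loo_q2 <- function(x, y) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 2L) stopf("need n > p + 2 for leave-one-out validation")
  X <- cbind(1, x)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X))
    stopf("rank-deficient design in leave-one-out refit",
          class = "plqsar_rank_deficient")
  Q <- qr.Q(fit$qr)
  h <- rowSums(Q^2)
  if (any(h >= 1 - 1e-12))
    stopf("leverage-one observation: leave-one-out refit rank-deficient",
          class = "plqsar_rank_deficient")
  press <- sum((fit$residuals / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Drop highly correlated descriptor columns
#'
#' Greedy correlation pre-filter used before subset selection: constant
#' (zero-variance) columns are dropped first; then column pairs with
#' \eqn{|r| >} \code{threshold} (Pearson) are visited in decreasing
#' \eqn{|r|} and the lower-variance member of each surviving pair is
#' dropped (ties broken by dropping the alphabetically later name). The
#' surviving matrix has all pairwise \eqn{|r| \le} threshold.
#'
#' @param x Numeric matrix with named columns (>= 2).
#' @param threshold Correlation cutoff in (0, 1]; default 0.9.
#' @return The filtered matrix; attribute \code{"removed"} is a data frame
#'   (dropped, partner, r, reason) logging every removal.
#' @export
correlation_filter <- function(x, threshold = 0.9) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2L, is_number(threshold),
            threshold > 0, threshold <= 1)
  if (is.null(colnames(x))) stopf("matrix must have column names")
  log <- data.frame(dropped = character(), partner = character(),
                    r = numeric(), reason = character())
  v <- apply(x, 2L, stats::var)
  const <- names(v)[v == 0 | is.na(v)]
  for (nm in const)
    log <- rbind(log, data.frame(dropped = nm, partner = NA_character_,
                                 r = NA_real_, reason = "zero variance"))
  keep <- setdiff(colnames(x), const)
  if (length(keep) >= 2L) {
    cm <- suppressWarnings(stats::cor(x[, keep, drop = FALSE]))
    pairs <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(-abs(cm[pairs]))
      pairs <- pairs[ord, , drop = FALSE]
      dropped <- character()
      for (r in seq_len(nrow(pairs))) {
        a <- keep[pairs[r, 1L]]; b <- keep[pairs[r, 2L]]
        if (a %in% dropped || b %in% dropped) next
        va <- v[a]; vb <- v[b]
        out <- if (va < vb) a else if (vb < va) b else max(a, b)
        other <- if (out == a) b else a
        dropped <- c(dropped, out)
        log <- rbind(log, data.frame(dropped = out, partner = other,
                                     r = cm[pairs[r, 1L], pairs[r, 2L]],
                                     reason = "high correlation"))
      }
      keep <- setdiff(keep, dropped)
    }
  }
  out <- x[, keep, drop = FALSE]
  attr(out, "removed") <- log
  out
}
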