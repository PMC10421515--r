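#' pIC50 / IC50 unit conversions
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50; with IC50 in
#' micromolar, \code{pic50 = -log10(ic50 * 1e-6) = 6 - log10(ic50)} and the
#' inverse \code{ic50 = 10^(6 - pic50)}.
#'
#' @param ic50,pic50 Numeric vectors (IC50 in micromolar).
#' @return Numeric vector.
#' @examples
#' pic50_from_ic50(1)      # 6
#' ic50_from_pic50(6.31)   # ~0.49 uM
#' @export
pic50_from_ic50 <- function(ic50) {
  stopifnot(is.numeric(ic50), all(ic50 > 0 | is.na(ic50)))
  -log10(ic50 * 1e-6)
}

#' @rdname pic50_from_ic50
#' @export
ic50_from_pic50 <- function(pic50) {
  stopifnot(is.numeric(pic50))
  10^(6 - pic50)
}

#' Construct a QSAR multiple-linear-regression model
#'
#' A fitted (or externally specified) linear pIC50 model: an intercept plus
#' one coefficient per canonical descriptor name.
#'
#' @param intercept Numeric scalar.
#' @param coefficients Named numeric vector (canonical descriptor names).
#' @param provenance Free-text note on where the model came from.
#' @param fit Optional list of fit internals (kept by [qsar_fit()]).
#' @return Object of class \code{qsar_model}.
#' @export
qsar_model <- function(intercept, coefficients, provenance = "manual",
                       fit = NULL) {
  stopifnot(is_number(intercept), is.numeric(coefficients),
            length(coefficients) >= 1L)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stopf("coefficients must be named by descriptor")
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 provenance = provenance,
                 fit = fit),
            class = "qsar_model")
}

#' Fit a pIC50 MLR model by ordinary least squares
#'
#' Ordinary least squares of activity on the selected descriptor columns,
#' through a QR factorization (\code{lm.fit}). The returned model keeps the
#' training data, fitted values and residuals so that [summary.qsar_model()]
#' and [loo_q2()] can work from it directly.
#'
#' @param x Numeric descriptor matrix (rows = compounds, named columns);
#'   no masked (\code{NA}) cells.
#' @param y Numeric pIC50 vector, \code{length(y) == nrow(x)}.
#' @param provenance Note recorded on the model.
#' @return A \code{qsar_model} with a \code{fit} component.
#' @export
qsar_fit <- function(x, y, provenance = "OLS fit") {
  x <- as.matrix(x)
  stopifnot(is.numeric(x), is.numeric(y), nrow(x) == length(y))
  if (is.null(colnames(x))) stopf("descriptor matrix must have column names")
  if (anyNA(x) || anyNA(y)) stopf("masked cells in the modelling data")
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1L)
    stopf("need n > p + 1 observations (n = %d, p = %d)", n, p)
  X <- cbind(`(Intercept)` = 1, x)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    drop <- colnames(X)[is.na(fit$coefficients)]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(drop, collapse = ", "), class = "plqsar_rank_deficient")
  }
  cf <- fit$coefficients
  qsar_model(cf[1L], cf[-1L], provenance = provenance,
             fit = list(x = x, y = y, fitted = fit$fitted.values,
                        residuals = fit$residuals, qr = fit$qr,
                        n = n, p = p))
}

#' @export
coef.qsar_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.qsar_model <- function(x, digits = 6, ...) {
  cat("<qsar_model>", x$provenance, "\n")
  terms <- sprintf("(%s) * %s", format(x$coefficients, digits = digits),
                   names(x$coefficients))
  cat("  pIC50 =", format(x$intercept, digits = digits), "+",
      paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' Predict pIC50 for new compounds
#'
#' @param object A \code{qsar_model}.
#' @param newdata Descriptor matrix (or data frame) containing every
#'   descriptor the model names; extra columns are ignored. Masked
#'   (\code{NA}) cells yield masked predictions.
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50, named by row when
#'   \code{newdata} has row names.
#' @export
predict.qsar_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fit)) stopf("no training data stored in the model")
    newdata <- object$fit$x
  }
  newdata <- as.matrix(newdata)
  need <- names(object$coefficients)
  missing <- setdiff(need, colnames(newdata))
  if (length(missing))
    stopf("descriptor column(s) missing from newdata: %s",
          paste(missing, collapse = ", "))
  drop(object$intercept + newdata[, need, drop = FALSE] %*%
         object$coefficients)
}

#' @export
residuals.qsar_model <- function(object, ...) {
  if (is.null(object$fit)) stopf("no training data stored in the model")
  object$fit$residuals
}

#' @export
summary.qsar_model <- function(object, ...) {
  if (is.null(object$fit)) {
    cat("externally specified model (no stored fit)\n")
    print(object)
    return(invisible(object))
  }
  rep <- qsar_validate(object$fit$y, object$fit$fitted, p = object$fit$p)
  q2 <- tryCatch(loo_q2(object$fit$x, object$fit$y), error = function(e) NA)
  out <- structure(list(model = object, report = rep, q2 = q2),
                   class = "summary.qsar_model")
  out
}

#' @export
print.summary.qsar_model <- function(x, ...) {
  print(x$model)
  print(x$report)
  if (!is.na(x$q2)) cat(sprintf("  LOO Q2    %8.4f\n", x$q2))
  invisible(x)
}

#' The reference five-descriptor pancreatic lipase model
#'
#' The published benchmark MLR equation for flavonoid pancreatic-lipase
#' inhibition:
#' \deqn{pIC_{50} = 3.83259 + 5.84689\,MATS1p - 0.30375\,ATSC6e
#'       - 1.41739\,GATS2p + 4.23423\,SpMin8Bhi - 0.07596\,VR2D.}
#'
#' @return A \code{qsar_model} (no stored fit).
#' @examples
#' predict(pl_reference_model(),
#'         matrix(0, 1, 5, dimnames = list("x", reference_descriptor_names())))
#' @export
pl_reference_model <- function() {
  qsar_model(3.83259,
             c(MATS1p = 5.84689, ATSC6e = -0.30375, GATS2p = -1.41739,
               SpMin8_Bhi = 4.23423, VR2_D = -0.07596),
             provenance = "published 40-flavonoid benchmark equation")
}
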