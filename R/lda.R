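#' Closed-form linear discriminant analysis
#'
#' Two-class LDA fitted in closed form from the class means and the
#' within-class scatter matrix `S = sum_k sum_{x in D_k} (x - mu_k)(x -
#' mu_k)'` (no 1/N scaling; any positive scaling of S cancels in the
#' decision rule).  The discriminant is `g(x) = w'x + b` with
#' `w = S^{-1}(mu_1 - mu_2)` and `b = -(mu_1 + mu_2)' S^{-1} (mu_1 -
#' mu_2) / 2`, so `g` vanishes exactly at the midpoint of the class means.
#' `S` is ridge-regularized by `1e-8 trace(S)/d` on the diagonal when
#' ill-conditioned.  If the class means coincide the fit degenerates
#' (`w = 0`) and a warning is raised; prediction then falls back to the
#' tie-break.
#'
#' @param features A `feature_set` tibble (or numeric matrix).
#' @param labels Integer labels (1 or 2); taken from `features$label` when
#'   omitted.
#' @return An `lda_model`: `w`, `b`, `S`, `mu1`, `mu2`, `n1`, `n2`.
#' @export
fit_lda <- function(features, labels = NULL) {
  x <- feature_matrix(features)
  labels <- labels %||% features$label
  stopifnot(nrow(x) == length(labels), all(labels %in% c(1L, 2L)))
  if (sum(labels == 1L) < 2 || sum(labels == 2L) < 2) {
    abort("Both classes need at least two trials.")
  }
  x1 <- x[labels == 1L, , drop = FALSE]
  x2 <- x[labels == 2L, , drop = FALSE]
  mu1 <- colMeans(x1)
  mu2 <- colMeans(x2)
  s <- crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))
  d <- ncol(x)
  if (rcond(s) < 1e-12) {
    s <- s + 1e-8 * sum(diag(s)) / d * diag(d)
  }
  diff <- mu1 - mu2
  if (all(abs(diff) < .Machine$double.eps^0.5)) {
    warn("Degenerate separation: class means coincide; w = 0.")
    w <- rep(0, d)
    b <- 0
  } else {
    w <- drop(solve(s, diff))
    b <- -0.5 * sum((mu1 + mu2) * w)
  }
  structure(
    list(w = w, b = b, S = s, mu1 = mu1, mu2 = mu2,
         n1 = sum(labels == 1L), n2 = sum(labels == 2L)),
    class = "lda_model"
  )
}

#' Predict with a fitted LDA model
#'
#' Evaluates `g(x) = w'x + b` per trial: class 1 when `g(x) > 0`, class 2
#' when `g(x) < 0`, and class 1 on an exact tie (`g(x) = 0`,
#' deterministic).
#'
#' @param object An `lda_model`.
#' @param newdata A `feature_set` or numeric matrix with matching
#'   dimension.
#' @param type `"class"` for labels, `"score"` for the discriminant
#'   values.
#' @param ... Unused.
#' @return Integer labels or numeric scores.
#' @export
predict.lda_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata)
  if (ncol(x) != length(object$w)) {
    abort("Feature dimension does not match the fitted model.")
  }
  g <- drop(x %*% object$w) + object$b
  if (type == "score") return(g)
  ifelse(g >= 0, 1L, 2L)
}

#' Classification accuracy in percent
#'
#' @param pred,truth Equal-length label vectors.
#' @return `100 * mean(pred == truth)`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    abort("`pred` and `truth` must be non-empty and of equal length.")
  }
  100 * mean(pred == truth)
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d-D discriminant, n = %d + %d trials, |w| = %.3g\n",
              length(x$w), x$n1, x$n2, sqrt(sum(x$w^2))))
  invisible(x)
}
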