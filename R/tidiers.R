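#' Tidy a CSP model
#'
#' One row per channel and spatial filter with the filter weight and the
#' generalized eigenvalue of the filter.
#'
#' @param x A `csp_model`.
#' @param ... Unused.
#' @return A tibble: `filter`, `rank` (`top`/`bottom`), `eigenvalue`,
#'   `channel`, `weight`.
#' @export
tidy.csp_model <- function(x, ...) {
  f <- x$filters
  tibble(
    filter = rep(colnames(f), each = nrow(f)),
    rank = rep(sub("[0-9]+$", "", colnames(f)), each = nrow(f)),
    eigenvalue = rep(x$eigenvalues, each = nrow(f)),
    channel = rep(rownames(f) %||% paste0("ch", seq_len(nrow(f))),
                  ncol(f)),
    weight = as.vector(f)
  )
}

#' @rdname tidy.csp_model
#' @export
glance.csp_model <- function(x, ...) {
  tibble(
    n_pairs = x$n_pairs,
    n_channels = nrow(x$filters),
    lambda_max = max(x$eigenvalues),
    lambda_min = min(x$eigenvalues)
  )
}

#' Tidy an LDA model
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per term (`bias` plus one per feature) with
#'   `estimate`; `glance()`: dimension, class counts and the separation
#'   `|w|`.
#' @export
tidy.lda_model <- function(x, ...) {
  tibble(
    term = c("bias", paste0("f", seq_along(x$w))),
    estimate = c(x$b, x$w)
  )
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble(
    n_features = length(x$w),
    n1 = x$n1,
    n2 = x$n2,
    w_norm = sqrt(sum(x$w^2))
  )
}

#' Tidy a transfer matrix
#'
#' @param x A `cross_matrix`.
#' @param ... Unused.
#' @return `tidy()`: one row per cell with `train`, `test`, `cell`
#'   (diagonal/offdiagonal) and `accuracy`; `glance()`: mean diagonal and
#'   off-diagonal accuracy.
#' @export
tidy.cross_matrix <- function(x, ...) {
  m <- length(x$sessions)
  tibble(
    train = rep(x$sessions, times = m),
    test = rep(x$sessions, each = m),
    cell = ifelse(rep(x$sessions, times = m) == rep(x$sessions, each = m),
                  "diagonal", "offdiagonal"),
    accuracy = as.vector(x$acc[cbind(rep(seq_len(m), times = m),
                                     rep(seq_len(m), each = m))])
  )
}

#' @rdname tidy.cross_matrix
#' @export
glance.cross_matrix <- function(x, ...) {
  offd <- x$acc[row(x$acc) != col(x$acc)]
  tibble(
    n_sessions = length(x$sessions),
    mean_selftest = mean(diag(x$acc)),
    mean_transfer = mean(offd),
    min_transfer = min(offd),
    max_transfer = max(offd)
  )
}
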