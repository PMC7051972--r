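#' Fit supervised scaling weights from martingale residuals
#'
#' The core of the outcome-guided clustering method: an ordinary
#' least-squares regression (with intercept) of the null-model martingale
#' residuals on the standardized features. The fitted coefficients become
#' per-feature weights so that, after scaling, Manhattan distances emphasise
#' features whose variation tracks excess hazard.
#'
#' @param features a `standardized_matrix` or numeric matrix in the
#'   standardized space.
#' @param residuals numeric vector of null-model martingale residuals, one
#'   per row.
#' @return object of class `scaling_weights`: `intercept` and named
#'   `coefficients`.
#' @export
fit_scaling_weights <- function(features, residuals) {
  x <- if (inherits(features, "standardized_matrix")) features$values
       else as_feature_matrix(features)
  stopifnot(length(residuals) == nrow(x))
  if (nrow(x) <= ncol(x) + 1L)
    stop("need more subjects than features to fit scaling weights",
         call. = FALSE)
  design <- cbind(`(Intercept)` = 1, x)
  fit <- stats::lm.fit(design, as.numeric(residuals))
  beta <- fit$coefficients
  if (any(is.na(beta)))
    stop("rank-deficient design; collinear feature(s): ",
         paste(setdiff(names(beta)[is.na(beta)], "(Intercept)"),
               collapse = ", "), call. = FALSE)
  structure(list(intercept = unname(beta[1L]),
                 coefficients = beta[-1L]),
            class = "scaling_weights")
}

#' @export
print.scaling_weights <- function(x, ...) {
  cat("scaling_weights (|coefficient| is the column weight):\n")
  print(sort(abs(x$coefficients), decreasing = TRUE))
  invisible(x)
}

#' Scale a standardized feature matrix by the fitted coefficients
#'
#' Each column is multiplied by the magnitude of its coefficient. Distance
#' computations are sign-invariant (|w| |x - y|), so magnitudes preserve the
#' importance semantics; the intercept shifts all points equally and is not
#' used.
#'
#' @param features a `standardized_matrix` or numeric matrix.
#' @param weights a `scaling_weights` object.
#' @return the scaled numeric matrix (same dimensions).
#' @export
apply_scaling <- function(features, weights) {
  stopifnot(inherits(weights, "scaling_weights"))
  x <- if (inherits(features, "standardized_matrix")) features$values
       else as_feature_matrix(features)
  nm <- names(weights$coefficients)
  if (!all(colnames(x) %in% nm) || !all(nm %in% colnames(x)))
    stop("feature names do not match the scaling weights", call. = FALSE)
  x <- x[, nm, drop = FALSE]
  sweep(x, 2L, abs(weights$coefficients), "*")
}

#' Serialize scaling weights to JSON (per-fold inspection/reuse)
#' @param weights a `scaling_weights` object.
#' @param path output file.
#' @export
write_scaling_weights <- function(weights, path) {
  jsonlite::write_json(list(intercept = weights$intercept,
                            coefficients = as.list(weights$coefficients)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
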