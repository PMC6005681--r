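#' Linear maximum-margin classifier (soft-margin SVM, L1 loss)
#'
#' Minimizes `0.5*||w||^2 + C * sum_i hinge(1 - y_i*(w.x_i + b))` by
#' deterministic dual coordinate descent. The bias is handled by augmenting
#' the feature vector with a constant 1 (so it is weakly regularized, as in
#' LIBLINEAR's `-B 1`). Cost defaults to 1, the value used for the population
#' readout.
#'
#' @param x numeric feature matrix (rows = observations).
#' @param y labels, any two-level vector; the first sorted level maps to -1.
#' @param cost soft-margin cost C (> 0).
#' @param autoscale center and scale each feature column before fitting
#'   (default TRUE, as in classic SVM training routines). Without centering,
#'   all-positive feature clouds far from the origin make the weakly
#'   regularized bias favor degenerate near-origin separators.
#' @param max_epochs,tol solver budget and projected-gradient stopping
#'   tolerance.
#' @return object of class `linear_svm` with `w`, `b`, `levels`, `cost`,
#'   `center`, `scale`.
#' @export
svm_linear <- function(x, y, cost = 1, autoscale = TRUE, max_epochs = 1000,
                       tol = 0.01) {
  stopifnot(is.matrix(x), nrow(x) == length(y), cost > 0)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop("svm_linear needs exactly two classes")
  ypm <- ifelse(as.character(y) == lev[2], 1, -1)
  if (autoscale) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  } else {
    center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  }
  xa <- cbind(x, 1)
  w <- svm_dcd(xa, ypm, cost, as.integer(max_epochs), tol)
  structure(list(w = w[-length(w)], b = w[length(w)], levels = lev,
                 cost = cost, center = center, scale = scale),
            class = "linear_svm")
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  score <- drop(z %*% object$w) + object$b
  factor(ifelse(score >= 0, object$levels[2], object$levels[1]),
         levels = object$levels)
}
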