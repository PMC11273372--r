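# Partial least squares (PLS1, NIPALS) with VIP scores. The discriminant
# case (PLS-DA) codes the class as a 0/1 column standardized like a
# response.

#' Fit a univariate-response PLS model (NIPALS)
#'
#' Centers and scales `X` and `y` (training statistics are stored for
#' prediction), then extracts `A` components by the NIPALS algorithm:
#' unit-norm weight vectors \eqn{w_a \propto X_a^T y}, scores
#' \eqn{t_a = X_a w_a}, X-loadings \eqn{p_a = X_a^T t_a / t_a^T t_a},
#' y-loadings \eqn{c_a = y^T t_a / t_a^T t_a}, with deflation of `X` (and
#' `y`) after each component. Successive score vectors are mutually
#' orthogonal. The regression coefficient vector on the standardized scale
#' is \eqn{W (P^T W)^{-1} c}.
#'
#' @param X samples x variables matrix.
#' @param y numeric response, or a two-level factor/character vector for
#'   the discriminant case (coded 0/1 alphabetically).
#' @param A number of components, `1 <= A <= min(n - 1, p)`.
#' @return object of class `pls_model`: weights `W`, loadings `P`, scores
#'   `Tm`, y-loadings `c_load`, `coef` (standardized scale), explained
#'   y-variance per component `ssy`, training centers/scales, `A`, and the
#'   class coding (`levels`) when discriminant.
#' @export
fit_pls <- function(X, y, A) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  levels_y <- NULL
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop("discriminant PLS needs exactly two classes")
    levels_y <- lev
    y <- as.numeric(as.character(y) == lev[2])
  }
  y <- as.numeric(y)
  stopifnot(length(y) == n, A >= 1, A <= min(n - 1, p))
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  }
  y_center <- mean(y); y_scale <- stats::sd(y)
  if (y_scale == 0) stop("response has zero variance")
  Xs <- scale(X, x_center, x_scale)
  ys <- (y - y_center) / y_scale

  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  c_load <- numeric(A)
  ssy <- numeric(A)
  Xa <- Xs; ya <- ys
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # remaining X carries no covariance with y
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      c_load <- c_load[seq_len(a - 1)]
      ssy <- ssy[seq_len(a - 1)]
      A <- a - 1L
      break
    }
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xa, t_a)) / tt
    c_a <- sum(ya * t_a) / tt
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; c_load[a] <- c_a
    ssy[a] <- c_a^2 * tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * c_a
  }
  if (A == 0) stop("no usable PLS component (X orthogonal to y)")
  coef <- drop(W %*% solve(crossprod(P, W), c_load))
  structure(list(W = W, P = P, Tm = Tm, c_load = c_load, coef = coef,
                 ssy = ssy, x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale, A = A,
                 levels = levels_y, var_names = colnames(X)),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata samples x variables matrix with the training columns.
#' @param type `"response"` for predictions on the original response scale
#'   (for the discriminant case, the continuous 0/1 code), or `"class"` for
#'   the predicted class by thresholding the code at 0.5.
#' @param ... unused.
#' @return numeric vector of predictions, or class labels.
#' @export
predict.pls_model <- function(object, newdata, type = c("response", "class"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$var_names)) {
    newdata <- newdata[, object$var_names, drop = FALSE]
  }
  Xs <- scale(newdata, object$x_center, object$x_scale)
  yhat <- object$y_center + drop(Xs %*% object$coef) * object$y_scale
  if (type == "class") {
    if (is.null(object$levels)) stop("not a discriminant model")
    return(ifelse(yhat > 0.5, object$levels[2], object$levels[1]))
  }
  yhat
}

#' Variable importance in the projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\lVert w_a \rVert)^2 /
#'   \sum_a SSY_a}}
#' where \eqn{SSY_a} is the response variance explained by component a. The
#' squared VIPs average to 1 (\eqn{\sum_j VIP_j^2 = p}).
#'
#' @param model a `pls_model`.
#' @return named vector of VIP scores; all-`NA` with a warning when the
#'   model explains no response variance (VIP undefined).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  p <- nrow(model$W)
  tot <- sum(model$ssy)
  if (tot <= 0) {
    warning("VIP undefined: model explains no response variance")
    return(stats::setNames(rep(NA_real_, p), model$var_names))
  }
  wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  v <- sqrt(p * drop(wn^2 %*% model$ssy) / tot)
  stats::setNames(v, model$var_names)
}
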