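# Two-class PLS-DA fitted by NIPALS (PLS1 on a -1/+1 group code), with
# leave-one-out cross-validated Q2 and VIP scores. This is the supervised
# latent-variable model behind the metabolomic group-separation analysis.

plsda_code <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes")
  if (any(table(y) < 1L)) stop("y must not be constant")
  list(code = ifelse(y == levels(y)[2L], 1, -1), levels = levels(y))
}

# NIPALS PLS1 core on a centred X and centred y; returns weights, loadings,
# scores and per-component explained response sum of squares
nipals_pls1 <- function(Xc, yc, ncomp) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp); SS <- numeric(ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break              # response fully deflated
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xc, t_)) / tt
    qk <- sum(yc * t_) / tt
    a <- k
    W[, k] <- w; P[, k] <- pl; Tm[, k] <- t_; q[k] <- qk
    SS[k] <- qk^2 * tt                 # response SS explained by component k
    Xc <- Xc - tcrossprod(t_, pl)
    yc <- yc - qk * t_
  }
  if (a == 0L) stop("PLS-DA fit failed: X carries no covariance with y")
  list(W = W[, 1:a, drop = FALSE], P = P[, 1:a, drop = FALSE],
       Tm = Tm[, 1:a, drop = FALSE], q = q[1:a], SS = SS[1:a], ncomp = a)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis for a two-group design,
#' fitted by the NIPALS algorithm on the group indicator coded -1/+1 and
#' mean-centred. `x` is expected on the modelling scale (typically
#' [log2_autoscale()] output); columns are centred internally, not
#' rescaled.
#'
#' @param x numeric samples x features matrix (complete).
#' @param y two-level factor (or coercible) of group labels, length
#'   `nrow(x)`.
#' @param ncomp number of latent components (default 2; capped at
#'   `min(n - 1, p)`).
#' @return object of class `"plsda"` with weights `W` (unit-norm columns),
#'   loadings `P`, scores `scores`, response loadings `q`, per-component
#'   explained response sum of squares `SS`, coefficients, fitted values
#'   and class levels.
#' @seealso [vip_scores()], [loocv_q2()], [predict.plsda()]
#' @export
plsda <- function(x, y, ncomp = 2L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("x must be complete; impute first (see impute_knn)")
  yy <- plsda_code(y)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("ncomp must be at least 1")
  if (ncomp > min(nrow(x) - 1L, ncol(x)))
    stop("ncomp must not exceed min(samples - 1, features)")
  x_center <- colMeans(x)
  Xc <- sweep(x, 2L, x_center)
  y_mean <- mean(yy$code)
  fit <- nipals_pls1(Xc, yy$code - y_mean, ncomp)
  # regression coefficients on the code scale: B = W (P'W)^-1 q
  B <- drop(fit$W %*% solve(crossprod(fit$P, fit$W), fit$q))
  names(B) <- colnames(x)
  fitted_code <- drop(Xc %*% B) + y_mean
  structure(list(W = fit$W, P = fit$P, scores = fit$Tm, q = fit$q,
                 SS = fit$SS, ncomp = fit$ncomp, coefficients = B,
                 x_center = x_center, y_mean = y_mean, levels = yy$levels,
                 y = factor(y, levels = yy$levels), y_code = yy$code,
                 fitted_code = fitted_code,
                 feature_names = colnames(x), call = match.call()),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d samples x %d features, %d component(s)\n",
              nrow(x$scores), length(x$coefficients), x$ncomp))
  cat(sprintf("  groups: %s (coded -1) vs %s (coded +1)\n",
              x$levels[1L], x$levels[2L]))
  tss <- sum((x$y_code - mean(x$y_code))^2)
  cat(sprintf("  cumulative R2Y: %s\n",
              paste(sprintf("%.3f", cumsum(x$SS) / tss), collapse = ", ")))
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  tss <- sum((object$y_code - mean(object$y_code))^2)
  tab <- data.frame(component = seq_len(object$ncomp),
                    SS_explained = object$SS,
                    R2Y = object$SS / tss,
                    R2Y_cum = cumsum(object$SS) / tss)
  print(object)
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' @export
fitted.plsda <- function(object, ...) object$fitted_code

#' @export
residuals.plsda <- function(object, ...) object$y_code - object$fitted_code

#' Predict from a PLS-DA model
#'
#' @param object a [plsda()] fit.
#' @param newdata samples x features matrix on the training scale.
#' @param type `"response"` for the continuous prediction on the -1/+1 code
#'   scale, `"class"` for the predicted group label, `"scores"` for
#'   projected latent scores.
#' @param ... unused.
#' @return numeric vector, factor or score matrix.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata must have the training features")
  Xc <- sweep(newdata, 2L, object$x_center)
  if (type == "scores") {
    R <- object$W %*% solve(crossprod(object$P, object$W))
    return(Xc %*% R)
  }
  yhat <- drop(Xc %*% object$coefficients) + object$y_mean
  if (type == "response") return(yhat)
  factor(object$levels[(yhat > 0) + 1L], levels = object$levels)
}

#' @export
plot.plsda <- function(x, comps = c(1L, 2L), ...) {
  if (x$ncomp < 2L || any(comps > x$ncomp)) {
    plot(x$scores[, 1L], x$y_code, col = as.integer(x$y) + 1L, pch = 19,
         xlab = "t1", ylab = "group code", ...)
  } else {
    plot(x$scores[, comps[1L]], x$scores[, comps[2L]],
         col = as.integer(x$y) + 1L, pch = 19,
         xlab = sprintf("t%d", comps[1L]), ylab = sprintf("t%d", comps[2L]),
         ...)
    legend("topright", legend = x$levels, col = 2:3, pch = 19, bty = "n")
  }
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a )` with unit-norm
#' component weights, so the mean squared VIP over the p features is 1
#' (`sum VIP^2 = p`). Features with VIP above ~1.5 are conventionally
#' treated as important discriminators.
#'
#' @param model a [plsda()] fit.
#' @return named non-negative vector, one VIP per feature.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  p <- nrow(model$W)
  num <- drop(model$W^2 %*% model$SS)
  setNames(sqrt(p * num / sum(model$SS)), model$feature_names)
}

#' Predictive Q2 from observed and predicted responses
#'
#' `Q2 = 1 - PRESS / TSS` where `PRESS = sum (y - yhat)^2` and
#' `TSS = sum (y - mean(y))^2`.
#'
#' @param y observed responses (group codes).
#' @param yhat predictions (held-out, for a cross-validated Q2).
#' @return Q2, at most 1; negative when predictions are worse than the
#'   mean.
#' @export
q2_score <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Leave-one-out cross-validated Q2 of a PLS-DA model
#'
#' Each sample is held out in turn, the model is refitted on the rest
#' (including recentring) and the held-out response is predicted;
#' `Q2 = 1 - PRESS / TSS` over the held-out predictions.
#'
#' @param x samples x features matrix on the modelling scale.
#' @param y two-level group factor.
#' @param ncomp number of latent components.
#' @return the LOOCV Q2.
#' @export
loocv_q2 <- function(x, y, ncomp = 2L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("LOOCV needs at least 3 samples")
  code <- plsda_code(y)$code
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    fit <- plsda(x[-i, , drop = FALSE], y[-i],
                 ncomp = min(ncomp, n - 2L, ncol(x)))
    yhat[i] <- predict(fit, x[i, , drop = FALSE], type = "response")
  }
  q2_score(code, yhat)
}
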