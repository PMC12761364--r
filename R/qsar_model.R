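# Centred single-response PLS regression (NIPALS), prediction, and
# interpretation vectors refolded into MIA maps.

.as_X <- function(X) {
  if (inherits(X, "mia_descriptors")) X$X else as.matrix(X)
}

#' Fit a centred PLS regression model by NIPALS
#'
#' Classic chemometric NIPALS with deflation of both blocks. X columns and y
#' are mean-centred but not autoscaled: MIA pixel intensities share one
#' physical scale, so autoscaling would only inflate near-constant pixels
#' (set `scale = TRUE` to override). The initial weight of each component is
#' `X'y`, so the fit is fully deterministic. For a single response the inner
#' NIPALS loop converges in one pass per component; the iteration cap only
#' guards degenerate input.
#'
#' @param X Descriptor matrix (n x p) or a [build_descriptor_matrix()] object.
#' @param y Numeric response (pKi), length n.
#' @param A Number of latent variables.
#' @param scale Autoscale X columns to unit variance (default `FALSE`).
#' @param tol Convergence / degeneracy tolerance.
#' @param max_iter Inner-loop iteration cap.
#' @return Object of class `mia_pls` with components `weights` (W),
#'   `loadings` (P), `y_loadings` (q), `scores` (T), `coefficients` (b),
#'   `intercept`, `x_mean`, `y_mean`, `fitted.values`, `residuals`,
#'   `ss_y` (per-component explained y sum of squares) and, when fitted
#'   from descriptors, `meta` for refolding.
#' @export
fit_pls <- function(X, y, A, scale = FALSE, tol = 1e-10, max_iter = 500L) {
  meta <- if (inherits(X, "mia_descriptors"))
    list(kept_columns = X$kept_columns, spec = X$spec, channel = X$channel,
         n_pixels = X$n_pixels)
  Xm <- .as_X(X)
  y <- as.numeric(y)
  n <- nrow(Xm); p <- ncol(Xm)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(Xm) || anyNA(y)) stop("X and y must be complete")
  A <- as.integer(A)
  if (A < 1L) stop("A must be >= 1")
  if (A > min(n - 1L, p))
    stop("A = ", A, " exceeds min(n - 1, p) = ", min(n - 1L, p))

  xm <- colMeans(Xm); ym <- mean(y)
  xs <- if (scale) {
    s <- apply(Xm, 2, sd); s[s == 0] <- 1; s
  } else rep(1, p)
  E <- sweep(sweep(Xm, 2, xm), 2, xs, "/")
  f <- y - ym

  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A); ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < tol || sum(E^2) < 1e-12)
      stop("X exhausted after ", a - 1L,
           " components; attainable maximum is ", a - 1L)
    w <- w / nw
    t_old <- NULL
    for (it in seq_len(max_iter)) {
      tvec <- E %*% w
      tt <- sum(tvec^2)
      if (tt < tol) stop("degenerate score vector at component ", a,
                         "; attainable maximum is ", a - 1L)
      qa <- sum(f * tvec) / tt
      # single-y: weight update w <- E'f/||.|| reproduces itself, one pass
      if (!is.null(t_old) && sqrt(sum((tvec - t_old)^2) / tt) < tol) break
      if (it == 1L) break
      t_old <- tvec
    }
    pa <- crossprod(E, tvec)[, 1] / tt
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- tvec; q[a] <- qa
    ssy[a] <- qa^2 * tt
    E <- E - tcrossprod(tvec, pa)
    f <- f - qa * tvec
  }
  b_scaled <- W %*% solve(crossprod(P, W), q)
  b <- b_scaled[, 1] / xs
  intercept <- ym - sum(xm * b)
  fitted <- as.numeric(Xm %*% b + intercept)
  structure(list(n_components = A, x_mean = xm, y_mean = ym, x_scale = xs,
                 weights = W, loadings = P, y_loadings = q, scores = Tm,
                 coefficients = b, intercept = intercept, ss_y = ssy,
                 fitted.values = fitted, residuals = y - fitted, y = y,
                 scaled = scale, meta = meta),
            class = "mia_pls")
}

#' @export
print.mia_pls <- function(x, ...) {
  cat("Centred NIPALS PLS model\n")
  cat("  components:", x$n_components, "  predictors:", length(x$coefficients),
      "  samples:", length(x$y), "\n")
  cat("  RMSEC:", signif(sqrt(mean(x$residuals^2)), 4),
      "  r2:", signif(1 - sum(x$residuals^2) / sum((x$y - x$y_mean)^2), 4), "\n")
  invisible(x)
}

#' @export
summary.mia_pls <- function(object, ...) {
  ssy <- object$ss_y
  out <- data.frame(component = seq_along(ssy),
                    ss_y = ssy,
                    cum_y_explained = cumsum(ssy) / sum((object$y - object$y_mean)^2))
  structure(list(model = object, components = out), class = "summary.mia_pls")
}

#' @export
print.summary.mia_pls <- function(x, ...) {
  print(x$model)
  cat("\nPer-component explained response sum of squares:\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mia_pls <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict activities for new descriptor rows
#'
#' @param object Fitted `mia_pls` model.
#' @param newdata Matrix with `length(coefficients)` columns (i.e. the kept
#'   pixels of the training descriptor block), or a `mia_descriptors`
#'   object built with the identical canvas (its kept columns must match).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mia_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "mia_descriptors")) {
    if (!is.null(object$meta) &&
        !identical(newdata$kept_columns, object$meta$kept_columns))
      stop("descriptor kept_columns do not match the training block; ",
           "use predict_sketches() for raw sketches")
    newdata <- newdata$X
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients))
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' @export
fitted.mia_pls <- function(object, ...) object$fitted.values

#' @export
residuals.mia_pls <- function(object, ...) object$residuals

#' Score (t) vectors for new samples
#' @param model Fitted `mia_pls`.
#' @param X Matrix with the model's predictor columns.
#' @return n x A score matrix.
#' @export
pls_scores <- function(model, X) {
  X <- .as_X(X)
  E <- sweep(sweep(X, 2, model$x_mean), 2, model$x_scale, "/")
  A <- model$n_components
  Tn <- matrix(0, nrow(E), A)
  for (a in seq_len(A)) {
    Tn[, a] <- E %*% model$weights[, a]
    E <- E - tcrossprod(Tn[, a], model$loadings[, a])
  }
  Tn
}

#' Observed-vs-fitted plot for a PLS model
#' @param x Fitted `mia_pls`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mia_pls <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values, xlab = "observed pKi",
                 ylab = "fitted pKi", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# -- kernel-space (Gram matrix) NIPALS for resampling ------------------------
#
# For MIA descriptors n << p, so every refit in cross-validation is done on
# the n x n Gram matrix K = Xc Xc'. Single-y NIPALS only touches X through
# XX' and X'y, so train/test predictions are exact functions of K; this is
# algebraically identical to refitting on X (enforced by oracle tests).

# Predictions for test rows at every component count 1..A_max.
# K: raw (uncentred) Gram matrix over all samples; y: full response.
.pls_kernel_cv <- function(K, y, train, test, A_max, tol = 1e-12) {
  Kt <- K[train, train, drop = FALSE]
  kc <- K[test, train, drop = FALSE]
  s <- length(train)
  ym <- mean(y[train])
  colm <- colMeans(Kt); allm <- mean(Kt)
  Ktc <- Kt - matrix(colm, s, s, byrow = TRUE) - matrix(colm, s, s) + allm
  kcc <- kc - matrix(rowMeans(kc), nrow(kc), s) -
    matrix(colm, nrow(kc), s, byrow = TRUE) + allm
  f <- y[train] - ym
  pred <- matrix(ym, nrow(kc), A_max)
  acc <- rep(ym, nrow(kc))
  attained <- 0L
  nw2_first <- NA_real_
  for (a in seq_len(A_max)) {
    Kf <- Ktc %*% f
    nw2 <- sum(f * Kf)                       # ||X'f||^2 = f'Kf
    if (is.na(nw2_first)) nw2_first <- nw2
    if (!is.finite(nw2) || !(nw2 > tol) || nw2 < 1e-16 * nw2_first ||
        sum(diag(Ktc)) < tol) break
    tvec <- Kf / sqrt(nw2)
    tt <- sum(tvec^2)
    if (tt < tol) break
    qa <- sum(f * tvec) / tt
    tnew <- (kcc %*% f) / sqrt(nw2)
    acc <- acc + qa * tnew[, 1]
    pred[, a] <- acc
    attained <- a
    # deflate cross-kernel first (needs pre-deflation Ktc)
    Kt_t <- Ktc %*% tvec                      # = X p * tt ... (s)
    kt <- kcc %*% tvec
    kcc <- kcc - tcrossprod(tnew, Kt_t) / tt -
      tcrossprod(kt, tvec) / tt +
      (sum(tvec * Kt_t) / tt^2) * tcrossprod(tnew, tvec)
    G <- diag(s) - tcrossprod(tvec) / tt
    Ktc <- G %*% Ktc %*% G
    f <- f - qa * tvec
  }
  if (attained < A_max && attained > 0L)
    pred[, (attained + 1L):A_max] <- pred[, attained]
  list(pred = pred, attained = attained)
}

# Leave-one-out predictions for all A in 1..A_max (n x A_max matrix).
.loo_predictions <- function(X, y, A_max) {
  X <- .as_X(X)
  n <- nrow(X)
  if (A_max > n - 2L)
    stop("A_max = ", A_max, " infeasible for leave-one-out on n = ", n,
         " samples (need A_max <= n - 2)")
  K <- tcrossprod(X)
  pred <- matrix(NA_real_, n, A_max)
  att <- integer(n)
  for (i in seq_len(n)) {
    cv <- .pls_kernel_cv(K, y, setdiff(seq_len(n), i), i, A_max)
    pred[i, ] <- cv$pred
    att[i] <- cv$attained
  }
  if (any(att < A_max))
    stop("A_max = ", A_max, " exceeds usable components in some folds; ",
         "attainable maximum is ", min(att))
  pred
}

#' Select the number of PLS components by leave-one-out RMSECV
#'
#' Scans `A = 1..A_max`, computing the leave-one-out root mean square error
#' of cross-validation, and returns the minimiser; ties are broken toward
#' the smaller (more parsimonious) model.
#'
#' @inheritParams fit_pls
#' @param A_max Largest component count scanned.
#' @return List with `A` (selected), `rmsecv` (length `A_max` curve) and
#'   `press`.
#' @export
select_components <- function(X, y, A_max) {
  y <- as.numeric(y)
  pred <- .loo_predictions(X, y, A_max)
  press <- colSums((pred - y)^2)
  rmsecv <- sqrt(press / length(y))
  list(A = which.min(rmsecv), rmsecv = rmsecv, press = press)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a(ssy_a * (w_ja / ||w_a||)^2) / sum_a(ssy_a))`
#' where `ssy_a` is the response sum of squares explained by component `a`.
#' Mean square over predictors is 1 by construction.
#'
#' @param model Fitted `mia_pls`.
#' @return Numeric vector, one VIP per kept pixel.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "mia_pls"))
  W <- model$weights; ssy <- model$ss_y
  p <- nrow(W)
  wn2 <- colSums(W^2)
  sqrt(p * as.numeric((W^2 %*% (ssy / wn2))) / sum(ssy))
}
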