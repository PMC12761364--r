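# The chemometric validation battery: calibration, leave-one-out
# cross-validation, Y-randomization with c-r2p, bootstrap external
# validation with Roy's metrics and Lin's CCC, and Williams-plot outlier
# analysis.

# local, restorable RNG scope
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Calibration statistics (r2, RMSEC)
#'
#' @param model Fitted [fit_pls()] model.
#' @param X Training descriptors (matrix or `mia_descriptors`).
#' @param y Training response.
#' @return List with `r2 = 1 - SSres/SStot` and `RMSEC = sqrt(SSres/n)`.
#' @export
calibration_stats <- function(model, X, y) {
  y <- as.numeric(y)
  yhat <- predict(model, .as_X(X))
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("constant response: r2 undefined")
  ssres <- sum((y - yhat)^2)
  list(r2 = 1 - ssres / sstot, RMSEC = sqrt(ssres / length(y)))
}

#' Leave-one-out cross-validation (q2, RMSECV)
#'
#' Each sample is predicted by a model refitted without it at the same
#' component count. `q2 = 1 - PRESS/SStot`, `RMSECV = sqrt(PRESS/n)`.
#'
#' @inheritParams calibration_stats
#' @param A Number of PLS components for every fold.
#' @return List with `q2`, `RMSECV`, and the vector of LOO `predictions`.
#' @export
loo_q2 <- function(X, y, A) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop("leave-one-out needs n >= 3")
  pred <- .loo_predictions(X, y, A)[, A]
  press <- sum((y - pred)^2)
  sstot <- sum((y - mean(y))^2)
  list(q2 = 1 - press / sstot, RMSECV = sqrt(press / n), predictions = pred)
}

#' Y-randomization test with the c-r2p penalty statistic
#'
#' The response is permuted `n_perm` times and the model refitted each time
#' at the same component count; a real structure-activity relationship
#' should collapse (`r2_y_rand << r2`). The penalty statistic is
#' `c_r2_p = r * sqrt(r2 - mean(r2_y_rand))` with `r`, `r2` from the
#' unpermuted model; if `r2 < mean(r2_y_rand)` it is reported as 0 with a
#' warning.
#'
#' @inheritParams loo_q2
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutations.
#' @param perms Optional list of explicit permutation vectors (overrides
#'   `n_perm`/`seed`); intended for deterministic testing.
#' @return List with `r2_y_rand` (mean), `RMSE_y_rand` (mean), `c_r2_p`,
#'   and the per-permutation `r2_perm` vector.
#' @export
y_randomization <- function(X, y, A, n_perm = 50L, seed = NULL, perms = NULL) {
  X <- .as_X(X)
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(perms)) {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    perms <- .with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }
  if (any(lengths(perms) != n) ||
      !all(vapply(perms, function(p) setequal(p, seq_len(n)), logical(1))))
    stop("each permutation must rearrange all ", n, " samples")
  K <- tcrossprod(X)
  all <- seq_len(n)
  stat <- vapply(perms, function(pp) {
    yp <- y[pp]
    fitp <- .pls_kernel_cv(K, yp, all, all, A)
    yhat <- fitp$pred[, min(A, max(fitp$attained, 1L))]
    c(r2 = 1 - sum((yp - yhat)^2) / sum((yp - mean(yp))^2),
      rmse = sqrt(mean((yp - yhat)^2)))
  }, numeric(2))
  fit0 <- .pls_kernel_cv(K, y, all, all, A)
  yhat0 <- fit0$pred[, A]
  r2 <- 1 - sum((y - yhat0)^2) / sum((y - mean(y))^2)
  r <- cor(y, yhat0)
  mr2r <- mean(stat["r2", ])
  c_r2_p <- if (r2 < mr2r) {
    warning("r2 below mean randomized r2; c_r2_p set to 0")
    0
  } else r * sqrt(r2 - mr2r)
  list(r2_y_rand = mr2r, RMSE_y_rand = mean(stat["rmse", ]),
       c_r2_p = c_r2_p, r2_perm = stat["r2", ])
}

#' Roy's r2m external-validation metrics
#'
#' `r2_m = r2 * (1 - sqrt(|r2 - r0_2|))` where `r2` is the squared Pearson
#' correlation of observed and predicted values and `r0_2` the coefficient
#' of determination of the through-origin regression of observed on
#' predicted. The reverse metric swaps the roles; `avg_r2_m` and
#' `delta_r2_m` are their mean and absolute difference.
#'
#' @param y_obs,y_pred Observed and predicted responses (length >= 3).
#' @return List with `r2_m`, `r2_m_reverse`, `avg_r2_m`, `delta_r2_m`.
#' @export
roy_metrics <- function(y_obs, y_pred) {
  if (length(y_obs) < 3L || length(y_obs) != length(y_pred))
    stop("need >= 3 paired observations")
  if (sd(y_obs) == 0 || sd(y_pred) == 0) stop("zero-variance input")
  r2 <- cor(y_obs, y_pred)^2
  r0sq <- function(obs, pred) {
    k <- sum(obs * pred) / sum(pred^2)
    1 - sum((obs - k * pred)^2) / sum((obs - mean(obs))^2)
  }
  m1 <- r2 * (1 - sqrt(abs(r2 - r0sq(y_obs, y_pred))))
  m2 <- r2 * (1 - sqrt(abs(r2 - r0sq(y_pred, y_obs))))
  list(r2_m = m1, r2_m_reverse = m2, avg_r2_m = (m1 + m2) / 2,
       delta_r2_m = abs(m1 - m2))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2*cov / (var_obs + var_pred + (mean_obs - mean_pred)^2)` with
#' population (1/n) moments, so both precision (correlation) and accuracy
#' (bias from the identity line) are penalised.
#'
#' @param y_obs,y_pred Numeric vectors of equal length >= 2.
#' @return Scalar in \[-1, 1\].
#' @export
ccc <- function(y_obs, y_pred) {
  n <- length(y_obs)
  if (n < 2L || length(y_pred) != n) stop("need >= 2 paired observations")
  mx <- mean(y_obs); my <- mean(y_pred)
  vx <- mean((y_obs - mx)^2); vy <- mean((y_pred - my)^2)
  if (vx == 0 && vy == 0) stop("both inputs are constant")
  cxy <- mean((y_obs - mx) * (y_pred - my))
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Bootstrap external validation
#'
#' In each of `n_iter` cycles a random holdout of `floor(frac * n)` samples
#' is set aside, the component count is re-selected by leave-one-out on the
#' remaining calibration samples, the model refitted, and the holdout
#' predicted. The external-set denominator of `r2_pred` uses the
#' training-set mean (Golbraikh-Tropsha convention). The "best" cycle is
#' the one passing the most cutoff checks (`r2_pred >= 0.5`,
#' `avg_r2_m >= 0.5`, `delta_r2_m < 0.2`, `CCC >= 0.8`), ties broken by the
#' higher mean of those statistics.
#'
#' @inheritParams y_randomization
#' @param A_max Largest component count scanned per cycle.
#' @param frac Holdout fraction.
#' @param n_iter Number of bootstrap cycles.
#' @return List with `iterations` (per-cycle data.frame: `A`, `RMSEP`,
#'   `r2_pred`, `avg_r2_m`, `delta_r2_m`, `ccc`), `holdouts` (index lists),
#'   `summary` (means and sds), `best` (cycle index).
#' @export
bootstrap_external <- function(X, y, A_max, frac = 0.25, n_iter = 10L,
                               seed = NULL) {
  X <- .as_X(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(frac > 0, frac < 1, n_iter >= 1)
  m <- floor(frac * n)
  if (m < 3L) stop("holdout of ", m, " samples is too small (need >= 3)")
  holdouts <- .with_seed(seed,
    replicate(n_iter, sort(sample.int(n, m)), simplify = FALSE))
  K <- tcrossprod(X)
  rows <- lapply(seq_len(n_iter), function(it) {
    test <- holdouts[[it]]
    train <- setdiff(seq_len(n), test)
    # component selection by LOO within the calibration subset
    loo <- vapply(seq_along(train), function(j) {
      .pls_kernel_cv(K, y, train[-j], train[j], A_max)$pred[1, ]
    }, numeric(A_max))
    press <- rowSums((loo - matrix(y[train], A_max, length(train), byrow = TRUE))^2)
    A <- which.min(sqrt(press / length(train)))
    yhat <- .pls_kernel_cv(K, y, train, test, A)$pred[, A]
    roy <- roy_metrics(y[test], yhat)
    data.frame(iter = it, A = A,
               RMSEP = sqrt(mean((y[test] - yhat)^2)),
               r2_pred = 1 - sum((y[test] - yhat)^2) /
                 sum((y[test] - mean(y[train]))^2),
               avg_r2_m = roy$avg_r2_m, delta_r2_m = roy$delta_r2_m,
               ccc = ccc(y[test], yhat))
  })
  iters <- do.call(rbind, rows)
  stats <- iters[, c("A", "RMSEP", "r2_pred", "avg_r2_m", "delta_r2_m", "ccc")]
  pass <- with(iters, cbind(r2_pred >= 0.5, avg_r2_m >= 0.5,
                            delta_r2_m < 0.2, ccc >= 0.8))
  score <- rowSums(pass)
  mean4 <- rowMeans(iters[, c("r2_pred", "avg_r2_m", "ccc")])
  best <- order(-score, -mean4)[1]
  list(iterations = iters, holdouts = holdouts,
       summary = data.frame(statistic = names(stats),
                            mean = colMeans(stats),
                            sd = apply(stats, 2, sd), row.names = NULL),
       best = best)
}

#' Williams-plot outlier and leverage analysis
#'
#' Leverage in latent-variable space, `h_i = 1/n + t_i'(T'T)^-1 t_i`, versus
#' studentized residuals `e_i / (RMSE * sqrt(1 - h_i))`. A sample is a
#' response outlier when its absolute studentized residual exceeds
#' `resid_threshold` (default 2.5) and structurally influential when
#' `h > leverage_factor * (A + 1) / n` (warning leverage, default factor 3).
#'
#' @param model Fitted `mia_pls`.
#' @param X,y Data the diagnostics are computed on (training data for the
#'   classical plot).
#' @param resid_threshold Studentized-residual cutoff.
#' @param leverage_factor Multiplier on `(A + 1)/n` for the leverage cutoff.
#' @param ids Optional sample identifiers.
#' @return data.frame of class `mia_williams`: `id`, `leverage`,
#'   `stud_residual`, `residual_outlier`, `high_leverage`; the leverage
#'   cutoff is attached as attribute `h_star`.
#' @export
williams <- function(model, X, y, resid_threshold = 2.5, leverage_factor = 3,
                     ids = NULL) {
  X <- .as_X(X)
  y <- as.numeric(y)
  n <- nrow(X)
  Tn <- pls_scores(model, X)
  TtT <- crossprod(model$scores)
  h <- 1 / length(model$y) + rowSums((Tn %*% solve(TtT)) * Tn)
  if (any(h >= 1 - 1e-12))
    stop("leverage of 1: sample exactly interpolated, studentized residual undefined")
  res <- y - predict(model, X)
  rmse <- sqrt(mean(res^2))
  stud <- res / (rmse * sqrt(1 - h))
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- data.frame(id = ids, leverage = h, stud_residual = stud,
                    residual_outlier = abs(stud) > resid_threshold,
                    high_leverage = h > leverage_factor *
                      (model$n_components + 1) / length(model$y),
                    stringsAsFactors = FALSE)
  structure(out, class = c("mia_williams", "data.frame"),
            h_star = leverage_factor * (model$n_components + 1) / length(model$y),
            resid_threshold = resid_threshold)
}

#' @export
plot.mia_williams <- function(x, ...) {
  graphics::plot(x$leverage, x$stud_residual, xlab = "leverage h",
                 ylab = "studentized residual", ...)
  graphics::abline(h = c(-1, 1) * attr(x, "resid_threshold"), lty = 2)
  graphics::abline(v = attr(x, "h_star"), lty = 3)
  invisible(x)
}

# -- whole-battery orchestration --------------------------------------------

#' Run the full validation battery for one property channel
#'
#' Selects the component count by minimum leave-one-out RMSECV, fits the
#' final model, and computes the complete statistic set: calibration (r2,
#' RMSEC), Y-randomization (r2_y_rand, RMSE_y_rand, c_r2_p),
#' cross-validation (q2, RMSECV), and bootstrap external validation
#' (RMSEP, r2_pred, avg_r2_m, delta_r2_m, CCC; `pls_comp` is the mean
#' re-selected component count across bootstrap cycles).
#'
#' @param X Descriptors for one channel.
#' @param y pKi response.
#' @param A_max Largest component count scanned.
#' @param frac,n_iter Bootstrap holdout fraction and cycle count.
#' @param n_perm Y-randomization permutations.
#' @param seed Seed controlling permutation and holdout draws.
#' @return List of class `mia_channel_validation`: `stats` (named numeric
#'   vector of the 13 battery statistics), `model`, `A`, `rmsecv_curve`,
#'   `bootstrap`, `y_rand`, `williams`.
#' @export
validate_channel <- function(X, y, A_max = 10L, frac = 0.25, n_iter = 10L,
                             n_perm = 50L, seed = NULL) {
  y <- as.numeric(y)
  sel <- select_components(X, y, A_max)
  model <- fit_pls(X, y, sel$A)
  cal <- calibration_stats(model, X, y)
  cv <- loo_q2(X, y, sel$A)
  yr <- y_randomization(X, y, sel$A, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  bt <- bootstrap_external(X, y, A_max, frac = frac, n_iter = n_iter,
                           seed = if (is.null(seed)) NULL else seed + 2L)
  wil <- williams(model, X, y)
  bs <- bt$summary
  bmean <- setNames(bs$mean, bs$statistic)
  stats <- c(pls_comp = unname(bmean["A"]), RMSEC = cal$RMSEC, r2 = cal$r2,
             RMSE_y_rand = yr$RMSE_y_rand, r2_y_rand = yr$r2_y_rand,
             c_r2_p = yr$c_r2_p, RMSECV = cv$RMSECV, q2 = cv$q2,
             RMSEP = unname(bmean["RMSEP"]), r2_pred = unname(bmean["r2_pred"]),
             avg_r2_m = unname(bmean["avg_r2_m"]),
             delta_r2_m = unname(bmean["delta_r2_m"]),
             ccc = unname(bmean["ccc"]))
  structure(list(stats = stats, model = model, A = sel$A,
                 rmsecv_curve = sel$rmsecv, bootstrap = bt, y_rand = yr,
                 williams = wil),
            class = "mia_channel_validation")
}

#' @export
print.mia_channel_validation <- function(x, ...) {
  cat("Validation battery (", x$model$meta$channel %||% "matrix",
      " channel), A = ", x$A, "\n", sep = "")
  print(round(x$stats, 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cutoffs of the standard acceptance table
.battery_cutoffs <- data.frame(
  statistic = c("r2", "c_r2_p", "q2", "r2_pred", "avg_r2_m", "delta_r2_m", "ccc"),
  operator = c(">=", ">=", ">=", ">=", ">=", "<", ">="),
  cutoff = c(0.6, 0.5, 0.5, 0.5, 0.5, 0.2, 0.8))

#' Cross-channel summary of the validation battery
#'
#' Assembles the familiar statistics table: one column per property
#' channel, plus the cross-channel `Average` and `Std.Dev.` columns and the
#' cutoff verdict evaluated on the Average column (`r2 >= 0.6`,
#' `c_r2_p >= 0.5`, `q2 >= 0.5`, `r2_pred >= 0.5`, `avg_r2_m >= 0.5`,
#' `delta_r2_m < 0.2`, `CCC >= 0.8`).
#'
#' @param channel_stats Named list (channel name -> named statistic vector,
#'   as in `validate_channel()$stats`) or a statistics matrix with channels
#'   in columns.
#' @return data.frame of class `mia_validation_report` with one row per
#'   statistic.
#' @export
channel_summary <- function(channel_stats) {
  M <- if (is.list(channel_stats) && !is.data.frame(channel_stats))
    do.call(cbind, channel_stats) else as.matrix(channel_stats)
  avg <- unname(rowMeans(M))
  sdev <- unname(apply(M, 1, sd))
  out <- data.frame(statistic = rownames(M), M, Average = avg, Std.Dev = sdev,
                    row.names = NULL, check.names = FALSE)
  cut <- .battery_cutoffs[match(out$statistic, .battery_cutoffs$statistic), ]
  out$cutoff <- ifelse(is.na(cut$operator), "",
                       paste(cut$operator, cut$cutoff))
  out$verdict <- ifelse(is.na(cut$operator), NA,
                        ifelse(cut$operator == ">=", avg >= cut$cutoff,
                               avg < cut$cutoff))
  structure(out, class = c("mia_validation_report", "data.frame"))
}

#' @export
print.mia_validation_report <- function(x, digits = 4, ...) {
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write a validation report as CSV
#' @param report From [channel_summary()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_validation_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
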