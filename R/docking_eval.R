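# Docking-evaluation arithmetic: pose RMSD, the Docking Accuracy score,
# binding-energy decomposition totals, and the predicted-activity versus
# binding-energy regression with outlier and lack-of-fit analysis.

#' Root mean square deviation between two matched pose coordinate sets
#'
#' Atom order must correspond and both poses must live in the same frame
#' (no superposition is performed -- redocking poses share the receptor
#' frame). No symmetry correction is applied; docking engines preserve
#' ligand atom order.
#'
#' @param coords_a,coords_b Numeric matrices (n_atoms x n_dims).
#' @return RMSD in the coordinate units (Angstrom for docking output).
#' @export
pose_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)))
    stop("coordinate sets differ in shape: ", paste(dim(coords_a), collapse = "x"),
         " vs ", paste(dim(coords_b), collapse = "x"))
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Docking Accuracy (DA) score for a redocking pose set
#'
#' With `f_l` and `f_h` the cumulative fractions of poses whose RMSD from
#' the crystallographic reference is at most `l` and at most `h`
#' respectively (closed intervals, `l < h`),
#' `DA = f_l + 0.5 * (f_h - f_l)`: poses inside the tight limit count in
#' full, poses between the limits count half, so DA lies in \[0, 1\] with 1
#' for a perfectly reproduced pose ensemble.
#'
#' @param poses Numeric vector of pose RMSDs (Angstrom), or a list with
#'   elements `rmsd`, `l`, `h` as produced by [generate_pose_set()].
#' @param l,h Lower and upper RMSD limits in Angstrom (defaults 2 and 3).
#' @return DA score in \[0, 1\].
#' @export
docking_accuracy <- function(poses, l = 2, h = 3) {
  if (is.list(poses)) {
    if (!is.null(poses$l)) l <- poses$l
    if (!is.null(poses$h)) h <- poses$h
    poses <- poses$rmsd
  }
  if (length(poses) == 0L) stop("empty pose set")
  if (any(poses < 0)) stop("RMSD values must be >= 0")
  if (!(l < h)) stop("limits must satisfy l < h")
  f_l <- mean(poses <= l)
  f_h <- mean(poses <= h)
  f_l + 0.5 * (f_h - f_l)
}

#' Recompute binding free energy totals from a decomposition table
#'
#' The total binding free energy is the sum of the interaction terms --
#' electrostatic + van der Waals + torsional -- excluding the ligand
#' internal energy. When a reported total is present, the row is flagged
#' inconsistent if the recomputed sum deviates by more than `tol`
#' (default 0.015 kcal/mol, covering rounding of values printed to 0.01).
#'
#' @param decomp data.frame with columns `electrostatic`, `vdw`,
#'   `internal`, `torsional` and optionally `reported_total` and `id`
#'   (kcal/mol).
#' @param tol Consistency tolerance in kcal/mol.
#' @return data.frame with `id`, `total`, `reported_total`, `consistent`.
#' @export
total_binding_energy <- function(decomp, tol = 0.015) {
  decomp <- as.data.frame(decomp)
  need <- c("electrostatic", "vdw", "internal", "torsional")
  miss <- setdiff(need, names(decomp))
  if (length(miss)) stop("missing energy term(s): ", paste(miss, collapse = ", "))
  for (cn in need) if (anyNA(decomp[[cn]]))
    stop("NA in energy term '", cn, "'")
  total <- decomp$electrostatic + decomp$vdw + decomp$torsional
  rep_tot <- if ("reported_total" %in% names(decomp))
    decomp$reported_total else rep(NA_real_, nrow(decomp))
  data.frame(id = if ("id" %in% names(decomp)) decomp$id
             else as.character(seq_len(nrow(decomp))),
             total = total, reported_total = rep_tot,
             consistent = ifelse(is.na(rep_tot), NA,
                                 abs(total - rep_tot) <= tol),
             stringsAsFactors = FALSE)
}

#' Linear regression of predicted activity on binding energy
#'
#' Fits ordinary least squares to all replicate observations (three
#' predicted pKi values per candidate, one per property channel) against
#' the candidate's binding free energy, and assesses adequacy with a
#' replicate-based lack-of-fit F test:
#' `F = (SS_lof / (k - 2)) / (SS_pe / (N - k))` with `k` distinct energies
#' and `N` total observations. Studentized residuals use the hat values of
#' the two-parameter line and `RMSE = sqrt(SS_res / N)`.
#'
#' @param points data.frame with columns `id`, `energy` (kcal/mol) and
#'   `pki` in long format: one row per replicate, exactly three replicates
#'   per candidate.
#' @return List of class `mia_energyfit`: `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r2`, `adj_r2`, `lof_F`, `lof_p`, `max_stud_residual`,
#'   and the underlying `lm` fit.
#' @export
activity_energy_fit <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("id", "energy", "pki") %in% names(points)))
  reps <- table(points$id)
  if (any(reps != 3L))
    stop("each candidate needs exactly 3 activity replicates (one per channel)")
  k <- length(unique(points$energy))
  if (k < 3L) stop("need >= 3 distinct binding-energy values")
  N <- nrow(points)
  fit <- lm(pki ~ energy, data = points)
  sm <- summary(fit)
  ssres <- sum(residuals(fit)^2)
  # pure error: within groups of identical x
  full <- lm(pki ~ factor(energy), data = points)
  sspe <- sum(residuals(full)^2)
  sslof <- ssres - sspe
  df_lof <- k - 2L
  df_pe <- N - k
  if (sspe <= .Machine$double.eps * ssres && sslof > 1e-12) {
    warning("zero pure error with nonzero lack-of-fit; F reported as Inf")
    lof_F <- Inf; lof_p <- 0
  } else if (sspe == 0 && sslof <= 1e-12) {
    lof_F <- 0; lof_p <- 1
  } else {
    lof_F <- (sslof / df_lof) / (sspe / df_pe)
    lof_p <- pf(lof_F, df_lof, df_pe, lower.tail = FALSE)
  }
  hat <- stats::hatvalues(fit)
  rmse <- sqrt(ssres / N)
  stud <- residuals(fit) / (rmse * sqrt(1 - hat))
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 intercept = unname(coef(fit)[1]),
                 intercept_se = sm$coefficients[1, 2],
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 lof_F = lof_F, lof_p = lof_p,
                 max_stud_residual = max(abs(stud)),
                 fit = fit),
            class = "mia_energyfit")
}

#' @export
print.mia_energyfit <- function(x, ...) {
  cat("Predicted activity vs binding energy (OLS on replicates)\n")
  cat(sprintf("  slope     %.4g +/- %.2g\n", x$slope, x$slope_se))
  cat(sprintf("  intercept %.4g +/- %.2g\n", x$intercept, x$intercept_se))
  cat(sprintf("  R2 %.4f   adj. R2 %.4f\n", x$r2, x$adj_r2))
  cat(sprintf("  lack-of-fit F = %.4g, p = %.4g\n", x$lof_F, x$lof_p))
  cat(sprintf("  max |studentized residual| = %.4f\n", x$max_stud_residual))
  invisible(x)
}
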