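# Synthetic congeneric-series generator with planted, known
# structure-activity effects, plus pose-RMSD and energy-decomposition
# fixtures, so every pipeline stage is testable without external data.

#' Default triketone-like scaffold template
#'
#' An aromatic six-ring carrying a 1,3,5-tricarbonyl chain (the metal
#' chelating motif of triketone HPPD inhibitors) drawn on a fixed 2D
#' template, with four ring positions R1-R4 open for substitution. The
#' scaffold defines the congeneric core shared by every generated sketch;
#' substituent fragments are stamped outward along the radial direction of
#' their attachment vertex, so each position occupies its own canvas
#' region.
#'
#' @return List with `atoms`, `bonds` and `positions` (per tag: `atom`
#'   index + outward unit `dir`ection).
#' @export
default_scaffold <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- data.frame(element = "C", x = 1.4 * cos(ang), y = 1.4 * sin(ang))
  chain <- data.frame(
    element = c("C", "O", "C", "C", "O", "C", "O"),
    x = c(2.70, 2.70, 4.00, 5.30, 5.30, 6.60, 6.60),
    y = c(0.75, 2.15, 0.00, 0.75, 2.15, 0.00, -1.40))
  atoms <- rbind(ring, chain)
  bonds <- data.frame(
    a1 = c(1, 2, 3, 4, 5, 6, 1, 7, 7, 9, 10, 10, 12),
    a2 = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 11, 12, 13),
    order = c(2, 1, 2, 1, 2, 1, 1, 2, 1, 1, 2, 1, 2))
  rad <- function(i) { v <- c(atoms$x[i], atoms$y[i]); v / sqrt(sum(v^2)) }
  list(atoms = atoms, bonds = bonds,
       positions = list(R1 = list(atom = 2L, dir = rad(2)),
                        R2 = list(atom = 3L, dir = rad(3)),
                        R3 = list(atom = 4L, dir = rad(4)),
                        R4 = list(atom = 5L, dir = rad(5))))
}

#' Substituent fragment library
#'
#' Small substituents drawn relative to an attachment point: `along` is the
#' distance outward along the position's radial direction, `perp` the
#' in-plane offset perpendicular to it (template units). Fragments are
#' chained by single bonds starting at the scaffold attachment atom.
#'
#' @return Named list of fragments, each a data.frame
#'   (`element`, `along`, `perp`).
#' @export
substituent_fragments <- function() {
  list(H     = data.frame(element = "H", along = 1.0, perp = 0),
       CH3   = data.frame(element = "C", along = 1.5, perp = 0),
       C2H5  = data.frame(element = c("C", "C"), along = c(1.5, 2.9),
                          perp = c(0, 0.6)),
       OCH3  = data.frame(element = c("O", "C"), along = c(1.4, 2.8),
                          perp = c(0, 0.6)),
       F     = data.frame(element = "F", along = 1.3, perp = 0),
       Cl    = data.frame(element = "Cl", along = 1.7, perp = 0),
       Br    = data.frame(element = "Br", along = 1.8, perp = 0))
}

# stamp fragments onto the scaffold; returns a mia_sketch
.assemble_sketch <- function(id, assignment, scaffold = default_scaffold(),
                             fragments = substituent_fragments(),
                             min_core_dist = 0.6) {
  atoms <- scaffold$atoms
  bonds <- scaffold$bonds
  n_core <- nrow(atoms)
  subst <- list()
  for (tag in names(assignment)) {
    posn <- scaffold$positions[[tag]]
    if (is.null(posn)) stop("unknown position tag: ", tag)
    frag <- fragments[[assignment[[tag]]]]
    if (is.null(frag)) stop("unknown substituent '", assignment[[tag]],
                            "' at ", tag)
    u <- posn$dir; v <- c(-u[2], u[1])
    ax <- atoms$x[posn$atom] + frag$along * u[1] + frag$perp * v[1]
    ay <- atoms$y[posn$atom] + frag$along * u[2] + frag$perp * v[2]
    d2core <- outer(ax, scaffold$atoms$x, "-")^2 + outer(ay, scaffold$atoms$y, "-")^2
    d2core[, posn$atom] <- Inf
    if (any(d2core < min_core_dist^2))
      stop("fragment '", assignment[[tag]], "' collides with the core at ",
           tag)
    idx <- nrow(atoms) + seq_len(nrow(frag))
    atoms <- rbind(atoms, data.frame(element = frag$element, x = ax, y = ay))
    prev <- c(posn$atom, idx[-length(idx)])
    bonds <- rbind(bonds, data.frame(a1 = prev, a2 = idx, order = 1))
    subst[[tag]] <- idx
  }
  sketch(id, atoms, bonds, substituents = subst)
}

#' Generator configuration for a synthetic congeneric series
#'
#' Defaults emulate a 59-compound triketone series with activities near the
#' reference inhibitor (baseline pKi 7.0, planted per-substituent additive
#' effects within \[-0.8, +0.8\] pKi units, Gaussian noise of 0.2 pKi
#' units). The strongest planted effects sit at R3 (methoxy, chloro),
#' alkyls at R1 are deleterious, and halogens at R2 / methyl at R4 help
#' moderately -- an additive caricature of the substituent pattern such
#' series show.
#'
#' @param n_samples Number of compounds.
#' @param positions Named list: per position a list with `pool` (substituent
#'   names) and `effects` (named additive pKi contributions covering the
#'   pool).
#' @param baseline Baseline pKi of the unsubstituted scaffold.
#' @param noise_sd Gaussian response noise, pKi units.
#' @param noise_cap_sd Truncate noise draws at this many sd (inverse-CDF
#'   truncated normal); `Inf` disables. Used to construct clean-background
#'   outlier fixtures.
#' @param jitter_sd Coordinate jitter sd in template units (0 = exact
#'   alignment).
#' @param outlier Optional list `list(index =, shift_sd =)` adding
#'   `shift_sd * noise_sd` to one sample's response (a planted response
#'   outlier).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return List of class `mia_generator_config`.
#' @export
generator_config <- function(n_samples = 59L,
                             positions = list(
                               R1 = list(pool = c("H", "CH3", "C2H5", "Cl"),
                                         effects = c(H = 0, CH3 = -0.45,
                                                     C2H5 = -0.75, Cl = 0.15)),
                               R2 = list(pool = c("H", "Cl", "F", "CH3"),
                                         effects = c(H = 0, Cl = 0.5,
                                                     F = 0.35, CH3 = -0.15)),
                               R3 = list(pool = c("H", "CH3", "Cl", "OCH3"),
                                         effects = c(H = 0, CH3 = 0.25,
                                                     Cl = 0.55, OCH3 = 0.8)),
                               R4 = list(pool = c("H", "CH3", "F", "Cl"),
                                         effects = c(H = 0, CH3 = 0.45,
                                                     F = 0.15, Cl = 0.3))),
                             baseline = 7.0, noise_sd = 0.2,
                             noise_cap_sd = Inf, jitter_sd = 0,
                             outlier = NULL, seed = 1L) {
  stopifnot(n_samples >= 1L, noise_sd >= 0, jitter_sd >= 0, noise_cap_sd > 0)
  for (tag in names(positions)) {
    p <- positions[[tag]]
    if (!length(p$pool)) stop("empty substituent pool at ", tag)
    if (!all(p$pool %in% names(p$effects)))
      stop("effects table at ", tag, " does not cover the pool")
  }
  structure(list(n_samples = as.integer(n_samples), positions = positions,
                 baseline = baseline, noise_sd = noise_sd,
                 noise_cap_sd = noise_cap_sd, jitter_sd = jitter_sd,
                 outlier = outlier, seed = as.integer(seed)),
            class = "mia_generator_config")
}

#' Generate a synthetic congeneric dataset with planted effects
#'
#' Substituents are assigned uniformly at random per position; the response
#' is `baseline + sum(position effects) + noise`. Sketches are built by
#' stamping fragments onto the shared scaffold template, so the core is
#' identically placed in every sketch (plus optional jitter). The returned
#' ground truth records every assignment, effect sum and noise draw.
#'
#' @param config From [generator_config()].
#' @return List with `sketches`, `activities` (data.frame `id`, `pki`) and
#'   `truth` (`assignments`, `effect_sum`, `noise`, `config`).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "mia_generator_config"))
  .with_seed(config$seed, {
    n <- config$n_samples
    tags <- names(config$positions)
    assign <- as.data.frame(lapply(config$positions, function(p)
      p$pool[sample.int(length(p$pool), n, replace = TRUE)]),
      stringsAsFactors = FALSE)
    names(assign) <- tags
    eff <- rowSums(vapply(tags, function(tag)
      config$positions[[tag]]$effects[assign[[tag]]], numeric(n)))
    noise <- if (is.finite(config$noise_cap_sd)) {
      lim <- stats::pnorm(c(-1, 1) * config$noise_cap_sd)
      qnorm(runif(n, lim[1], lim[2])) * config$noise_sd
    } else rnorm(n, 0, config$noise_sd)
    pki <- config$baseline + eff + noise
    if (!is.null(config$outlier))
      pki[config$outlier$index] <- pki[config$outlier$index] +
        config$outlier$shift_sd * config$noise_sd
    ids <- sprintf("S%03d", seq_len(n))
    sketches <- lapply(seq_len(n), function(i)
      .assemble_sketch(ids[i], as.list(assign[i, , drop = FALSE])))
    if (config$jitter_sd > 0) {
      sketches <- lapply(sketches, function(s) {
        s$atoms$x <- s$atoms$x + rnorm(nrow(s$atoms), 0, config$jitter_sd)
        s$atoms$y <- s$atoms$y + rnorm(nrow(s$atoms), 0, config$jitter_sd)
        s
      })
    }
    list(sketches = sketches,
         activities = data.frame(id = ids, pki = pki, stringsAsFactors = FALSE),
         truth = list(assignments = cbind(id = ids, assign),
                      effect_sum = eff, noise = noise,
                      outlier = config$outlier, config = config))
  })
}

#' Atom indices of the scaffold core (for alignment checks)
#' @param scaffold From [default_scaffold()].
#' @return Integer vector.
#' @export
core_atom_indices <- function(scaffold = default_scaffold())
  seq_len(nrow(scaffold$atoms))

#' Pixel regions occupied by each substituent position
#'
#' Union, over the pool of a position, of the pixels whose intensity the
#' fragment could touch (its disks and attachment bond), computed by
#' rendering each fragment alone on the scaffold and diffing against the
#' bare scaffold. Used to check that interpretation maps concentrate where
#' the planted variation lives.
#'
#' @param config Generator configuration (pools per position).
#' @param spec Canvas specification.
#' @param props Element property table.
#' @param channel Property channel used for rendering.
#' @return Named list: position tag -> integer vector of unfolded pixel
#'   indices.
#' @export
substituent_pixel_regions <- function(config = generator_config(),
                                      spec = canvas_spec(),
                                      props = load_property_table(),
                                      channel = "r_vdw") {
  scaffold <- default_scaffold()
  base_assign <- lapply(config$positions, function(p) p$pool[1])
  lapply(setNames(names(config$positions), names(config$positions)),
         function(tag) {
    pix <- integer(0)
    for (sub in config$positions[[tag]]$pool) {
      a <- base_assign; a[[tag]] <- sub
      with_f <- unfold_image(rasterize(.assemble_sketch("tmp", a), channel,
                                       spec, props))
      a2 <- base_assign[setdiff(names(base_assign), tag)]
      without <- unfold_image(rasterize(.assemble_sketch("tmp", a2), channel,
                                        spec, props))
      pix <- union(pix, which(with_f != without))
    }
    sort(pix)
  })
}

#' Recover planted per-substituent effects from a fitted model
#'
#' For every position, builds single-substituent probe sketches (reference
#' substituents elsewhere), predicts their activity with the fitted model,
#' and pairs the predictions with the planted effects. Ranking agreement
#' (e.g. Kendall tau of `predicted` vs `planted` per position) measures how
#' well the pipeline recovered the planted structure-activity pattern.
#'
#' @param model Fitted `mia_pls` carrying descriptor metadata.
#' @param config Generator configuration the data came from.
#' @param props Element property table.
#' @return data.frame with `position`, `substituent`, `planted`,
#'   `predicted`.
#' @export
recover_position_effects <- function(model, config = generator_config(),
                                     props = load_property_table()) {
  if (is.null(model$meta)) stop("model carries no descriptor metadata")
  base_assign <- lapply(config$positions, function(p) p$pool[1])
  rows <- list()
  for (tag in names(config$positions)) {
    pool <- config$positions[[tag]]$pool
    sks <- lapply(pool, function(sub) {
      a <- base_assign; a[[tag]] <- sub
      .assemble_sketch(paste0(tag, "_", sub), a)
    })
    pred <- predict_sketches(model, sks, props)
    rows[[tag]] <- data.frame(position = tag, substituent = pool,
                              planted = unname(config$positions[[tag]]$effects[pool]),
                              predicted = pred, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate a synthetic redocking pose-RMSD set
#'
#' Draws `round(frac_within_l * n)` RMSDs inside the tight limit,
#' `round(frac_within_h * n) - round(frac_within_l * n)` between the
#' limits, and the remainder above `h`, then shuffles the order.
#'
#' @param n Number of poses.
#' @param frac_within_l,frac_within_h Cumulative target fractions within
#'   `l` and within `h` (`0 <= frac_within_l <= frac_within_h <= 1`).
#' @param seed RNG seed.
#' @param l,h RMSD limits (Angstrom).
#' @return List (`rmsd`, `l`, `h`) consumable by [docking_accuracy()].
#' @export
generate_pose_set <- function(n, frac_within_l, frac_within_h, seed = 1L,
                              l = 2, h = 3) {
  if (!(frac_within_l >= 0 && frac_within_l <= frac_within_h &&
        frac_within_h <= 1))
    stop("need 0 <= frac_within_l <= frac_within_h <= 1")
  if (!(l < h)) stop("limits must satisfy l < h")
  n_l <- round(frac_within_l * n)
  n_m <- round(frac_within_h * n) - n_l
  n_o <- n - n_l - n_m
  .with_seed(seed, {
    rmsd <- c(runif(n_l, 0.2 * l, l), runif(n_m, l + 0.01 * (h - l), h),
              runif(n_o, h + 0.1, h + 2))
    list(rmsd = rmsd[sample.int(n)], l = l, h = h)
  })
}

#' Generate a synthetic binding-energy decomposition table
#'
#' Random electrostatic / van der Waals / internal / torsional terms with
#' `reported_total` equal to the interaction sum (excluding internal) for
#' every row except those listed in `inconsistent`, whose reported totals
#' are shifted by `perturbation` kcal/mol (recorded in the
#' `"perturbations"` attribute).
#'
#' @param rows Number of rows.
#' @param seed RNG seed.
#' @param inconsistent Integer indices of rows to perturb.
#' @param perturbation Shift(s) applied to the perturbed rows, kcal/mol.
#' @return data.frame with `id` and the energy columns; attribute
#'   `perturbations` records the planted shifts.
#' @export
generate_energy_table <- function(rows, seed = 1L, inconsistent = integer(0),
                                  perturbation = 1.07) {
  stopifnot(rows >= 1L, all(inconsistent >= 1L & inconsistent <= rows))
  .with_seed(seed, {
    df <- data.frame(id = sprintf("E%02d", seq_len(rows)),
                     electrostatic = round(runif(rows, -3, -1), 2),
                     vdw = round(runif(rows, -10, -4), 2),
                     internal = round(runif(rows, -2.2, 0), 2),
                     torsional = round(runif(rows, 0.8, 1.8), 2),
                     stringsAsFactors = FALSE)
    df$reported_total <- round(df$electrostatic + df$vdw + df$torsional, 2)
    pert <- rep(perturbation, length.out = length(inconsistent))
    df$reported_total[inconsistent] <- df$reported_total[inconsistent] + pert
    structure(df, perturbations = setNames(pert, as.character(inconsistent)))
  })
}
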