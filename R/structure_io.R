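#' @importFrom stats coef cor lm pf predict fitted residuals rnorm runif sd var setNames qnorm anova
#' @importFrom utils read.csv write.csv
NULL

# -- MoleculeSketch ----------------------------------------------------------

#' Create an aligned 2D molecule sketch
#'
#' A sketch is the unit of input for image-based (MIA) QSAR descriptor
#' generation: a set of atoms with fixed 2D template coordinates, bonds, and
#' (optionally) a labelling of which atoms belong to which substituent
#' position (R1..R4). All sketches of a congeneric series must share the
#' coordinates of their common core; see [check_alignment()].
#'
#' @param id Unique compound identifier.
#' @param atoms data.frame with columns `element` (symbol), `x`, `y`
#'   (template units, finite).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (bond order). May have zero rows.
#' @param substituents Optional named list mapping a position tag (e.g. "R3")
#'   to an integer vector of atom indices.
#' @return An object of class `mia_sketch`.
#' @export
sketch <- function(id, atoms, bonds = NULL, substituents = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- as.data.frame(atoms)
  if (!all(c("element", "x", "y") %in% names(atoms)))
    stop("atoms must have columns element, x, y")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)))
    stop("sketch '", id, "': atom coordinates must be finite")
  if (is.null(bonds)) bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  bonds <- as.data.frame(bonds)
  n <- nrow(atoms)
  if (nrow(bonds) > 0L) {
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1L | idx > n))
      stop("sketch '", id, "': bond references atom index outside 1..", n)
  }
  if (!is.null(substituents)) {
    bad <- vapply(substituents, function(ix) any(ix < 1L | ix > n), logical(1))
    if (any(bad)) stop("sketch '", id, "': substituent atom index out of range")
  }
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 substituents = substituents),
            class = "mia_sketch")
}

#' @export
print.mia_sketch <- function(x, ...) {
  cat("<mia_sketch> ", x$id, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# -- element property table --------------------------------------------------

#' Load the element property table
#'
#' Properties used to weight pixel intensities: Pauling electronegativity
#' (`epsilon`), Bondi van der Waals radius in Angstrom (`r_vdw`) and the
#' derived ratio `r_vdw / epsilon`. The bundled table covers H, C, N, O, F,
#' P, S, Cl, Br; alternative compilations can be supplied as a CSV with
#' columns `element`, `epsilon`, `r_vdw`.
#'
#' @param path Optional path to a CSV; defaults to the bundled table.
#' @return data.frame with rownames = element symbols and columns
#'   `epsilon`, `r_vdw`, `ratio`.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "element_properties.csv", package = "miaqsar")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("element", "epsilon", "r_vdw") %in% names(tab)))
    stop("property table needs columns element, epsilon, r_vdw")
  if (any(tab$epsilon <= 0) || any(tab$r_vdw <= 0))
    stop("element properties must be strictly positive")
  if (anyDuplicated(tab$element)) stop("duplicated element in property table")
  rownames(tab) <- tab$element
  tab$ratio <- tab$r_vdw / tab$epsilon
  tab
}

#' Look up a property for a set of elements
#'
#' Unlisted elements are an error, never a silent default.
#'
#' @param props Table from [load_property_table()].
#' @param elements Character vector of element symbols.
#' @param channel One of `"r_vdw"`, `"epsilon"`, `"ratio"`.
#' @return Numeric vector of property values.
#' @export
element_property <- function(props, elements, channel = c("r_vdw", "epsilon", "ratio")) {
  channel <- match.arg(channel)
  miss <- setdiff(unique(elements), rownames(props))
  if (length(miss))
    stop("element(s) not in property table: ", paste(miss, collapse = ", "))
  props[elements, channel]
}

# -- readers / writers -------------------------------------------------------

#' Read aligned 2D sketches from an SDF (V2000) or MOL2 file
#'
#' Coordinates are read verbatim (no re-layout); a file whose records carry
#' truly 3D coordinates (non-constant z) is rejected, because the descriptor
#' method is defined on flat drawings.
#'
#' @param path File path.
#' @param dialect `"sdf"` or `"mol2"`.
#' @return List of [sketch()] objects with unique ids.
#' @export
read_sketches <- function(path, dialect = c("sdf", "mol2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  out <- switch(dialect, sdf = .read_sdf(path), mol2 = .read_mol2(path))
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate sketch ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

.read_sdf <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  n <- length(sdfs)
  lapply(seq_len(n), function(i) {
    rec <- tryCatch(sdfs[[i]], error = function(e)
      stop("malformed SDF record ", i, ": ", conditionMessage(e)))
    ab <- ChemmineR::atomblock(rec)
    bb <- ChemmineR::bondblock(rec)
    if (is.null(dim(ab)) || nrow(ab) == 0L)
      stop("malformed SDF record ", i, ": empty atom block")
    z <- if (ncol(ab) >= 3) ab[, 3] else rep(0, nrow(ab))
    if (diff(range(z)) > 1e-6)
      stop("SDF record ", i, " has 3D (non-constant z) coordinates; ",
           "flatten the structures before use")
    el <- sub("_.*$", "", rownames(ab))
    id <- trimws(ChemmineR::header(rec)[[1]])
    if (!nzchar(id)) id <- paste0("record_", i)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) NULL else
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.numeric(bb[, 3]))
    sketch(id, data.frame(element = el, x = ab[, 1], y = ab[, 2]), bonds)
  })
}

.read_mol2 <- function(path) {
  lines <- readLines(path)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) stop("no @<TRIPOS>MOLECULE record found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    blk <- lines[starts[i]:ends[i]]
    id <- trimws(blk[2])
    a0 <- grep("^@<TRIPOS>ATOM", blk)
    b0 <- grep("^@<TRIPOS>BOND", blk)
    if (length(a0) != 1L)
      stop("malformed MOL2 record ", i, ": missing ATOM section")
    sec_ends <- function(from) {
      nxt <- grep("^@<TRIPOS>", blk)
      nxt <- nxt[nxt > from]
      if (length(nxt)) nxt[1] - 1L else length(blk)
    }
    atom_lines <- blk[(a0 + 1L):sec_ends(a0)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    bad <- which(vapply(fields, length, integer(1)) < 6L)
    if (length(bad))
      stop("malformed MOL2 record ", i, ": atom line ", bad[1])
    xyz <- t(vapply(fields, function(f) as.numeric(f[3:5]), numeric(3)))
    if (anyNA(xyz)) stop("malformed MOL2 record ", i, ": non-numeric coordinates")
    if (diff(range(xyz[, 3])) > 1e-6)
      stop("MOL2 record ", i, " has 3D (non-constant z) coordinates; ",
           "flatten the structures before use")
    el <- sub("\\..*$", "", vapply(fields, `[[`, character(1), 6L))
    bonds <- NULL
    if (length(b0) == 1L && sec_ends(b0) >= b0 + 1L) {
      bl <- blk[(b0 + 1L):sec_ends(b0)]
      bl <- bl[nzchar(trimws(bl))]
      if (length(bl)) {
        bf <- strsplit(trimws(bl), "[[:space:]]+")
        ord <- vapply(bf, `[[`, character(1), 4L)
        ordn <- suppressWarnings(as.numeric(ord))
        ordn[ord == "ar"] <- 1.5
        ordn[ord == "am"] <- 1
        bonds <- data.frame(a1 = as.integer(vapply(bf, `[[`, character(1), 2L)),
                            a2 = as.integer(vapply(bf, `[[`, character(1), 3L)),
                            order = ordn)
      }
    }
    sketch(id, data.frame(element = el, x = xyz[, 1], y = xyz[, 2]), bonds)
  })
}

#' Write sketches to SDF (V2000) or MOL2
#'
#' @param sketches List of [sketch()] objects.
#' @param path Output file.
#' @param dialect `"sdf"` or `"mol2"`.
#' @return `path`, invisibly.
#' @export
write_sketches <- function(sketches, path, dialect = c("sdf", "mol2")) {
  dialect <- match.arg(dialect)
  txt <- unlist(lapply(sketches, switch(dialect, sdf = .fmt_sdf, mol2 = .fmt_mol2)))
  writeLines(txt, path)
  invisible(path)
}

.fmt_sdf <- function(s) {
  na <- nrow(s$atoms); nb <- nrow(s$bonds)
  c(s$id, "  miaqsar 2D", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            s$atoms$x, s$atoms$y, 0, s$atoms$element),
    if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                    s$bonds$a1, s$bonds$a2, as.integer(round(s$bonds$order))),
    "M  END", "$$$$")
}

.fmt_mol2 <- function(s) {
  na <- nrow(s$atoms); nb <- nrow(s$bonds)
  c("@<TRIPOS>MOLECULE", s$id,
    sprintf("%5d %5d     0     0     0", na, nb),
    "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s", seq_len(na),
            paste0(s$atoms$element, seq_len(na)),
            s$atoms$x, s$atoms$y, 0, s$atoms$element),
    if (nb) c("@<TRIPOS>BOND",
              sprintf("%6d %5d %5d %s", seq_len(nb), s$bonds$a1, s$bonds$a2,
                      ifelse(s$bonds$order == 1.5, "ar",
                             as.character(as.integer(round(s$bonds$order)))))))
}

# -- alignment ---------------------------------------------------------------

#' Check that the congeneric core is identically placed in every sketch
#'
#' MIA descriptors compare images pixel by pixel, so the shared core of the
#' series must sit at the same template coordinates in every drawing. The
#' first sketch serves as reference. Deviations beyond `tol` indicate a data
#' error (a re-drawn or shifted structure), not noise.
#'
#' @param sketches List of sketches.
#' @param core_atom_map Integer vector of core atom indices common to all
#'   sketches, or a list of per-sketch index vectors of equal length.
#' @param tol Maximum allowed per-atom deviation in template units.
#' @return List with `pass` (logical), `max_deviation` (named per-sketch
#'   maxima) and `tol`.
#' @export
check_alignment <- function(sketches, core_atom_map, tol = 1e-3) {
  n <- length(sketches)
  stopifnot(n >= 1L)
  maps <- if (is.list(core_atom_map)) core_atom_map else
    rep(list(as.integer(core_atom_map)), n)
  if (length(maps) != n) stop("core_atom_map list length must match sketches")
  coords <- lapply(seq_len(n), function(i) {
    s <- sketches[[i]]; ix <- maps[[i]]
    if (any(ix < 1L | ix > nrow(s$atoms)))
      stop("core atom missing in sketch '", s$id, "'")
    cbind(s$atoms$x[ix], s$atoms$y[ix])
  })
  ref <- coords[[1]]
  dev <- vapply(coords, function(co) {
    if (nrow(co) != nrow(ref)) stop("core atom count differs between sketches")
    max(sqrt(rowSums((co - ref)^2)))
  }, numeric(1))
  names(dev) <- vapply(sketches, `[[`, character(1), "id")
  list(pass = all(dev <= tol), max_deviation = dev, tol = tol)
}

# -- activities --------------------------------------------------------------

#' Load inhibitory activities (Ki / pKi) from a CSV
#'
#' The CSV needs an `id` column plus `ki` (mol/L) or `pki`; when only `ki`
#' is given, `pki = -log10(ki)` is computed. Records carrying both must be
#' mutually consistent to 1e-6 on the pKi scale.
#'
#' @param path CSV path.
#' @return data.frame with columns `id`, `ki`, `pki` (pki always populated).
#' @export
load_activities <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_activities(df)
}

#' Coerce a data.frame of activities, filling in pKi from Ki
#'
#' @param df data.frame with `id` and `ki` and/or `pki` columns.
#' @return data.frame with `id`, `ki`, `pki`.
#' @export
as_activities <- function(df) {
  if (!"id" %in% names(df)) stop("activities need an 'id' column")
  if (!any(c("ki", "pki") %in% names(df)))
    stop("activities need a 'ki' or 'pki' column")
  ki <- if ("ki" %in% names(df)) as.numeric(df$ki) else rep(NA_real_, nrow(df))
  pki <- if ("pki" %in% names(df)) as.numeric(df$pki) else rep(NA_real_, nrow(df))
  if (any(!is.na(ki) & ki <= 0)) stop("ki must be > 0")
  both <- !is.na(ki) & !is.na(pki)
  if (any(both) && any(abs(pki[both] + log10(ki[both])) > 1e-6))
    stop("inconsistent ki / pki pair for id(s): ",
         paste(df$id[both][abs(pki[both] + log10(ki[both])) > 1e-6], collapse = ", "))
  fill <- is.na(pki) & !is.na(ki)
  pki[fill] <- -log10(ki[fill])
  if (anyNA(pki)) stop("records with neither ki nor pki: ",
                       paste(df$id[is.na(pki)], collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate activity ids")
  data.frame(id = as.character(df$id), ki = ki, pki = pki,
             stringsAsFactors = FALSE)
}

#' Write an activity table as CSV
#' @param activities data.frame from [as_activities()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_activities <- function(activities, path) {
  write.csv(activities, path, row.names = FALSE)
  invisible(path)
}

#' Join activities onto sketches by id
#'
#' Activity records without a sketch counterpart trigger a warning;
#' sketches without an activity are dropped with a warning.
#'
#' @param sketches List of sketches.
#' @param activities Activity data.frame.
#' @return List with `sketches` (reordered to match) and `y` (pKi vector).
#' @export
match_activities <- function(sketches, activities) {
  sid <- vapply(sketches, `[[`, character(1), "id")
  orphans <- setdiff(activities$id, sid)
  if (length(orphans))
    warning("activity record(s) with no sketch: ", paste(orphans, collapse = ", "))
  keep <- sid %in% activities$id
  if (any(!keep))
    warning("sketch(es) with no activity dropped: ",
            paste(sid[!keep], collapse = ", "))
  sk <- sketches[keep]
  m <- match(vapply(sk, `[[`, character(1), "id"), activities$id)
  list(sketches = sk, y = activities$pki[m])
}
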