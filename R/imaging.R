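# Rasterisation of aligned sketches into fixed-size property-weighted pixel
# matrices -- the MIA descriptor X-block.

#' Canvas specification for sketch rasterisation
#'
#' The canvas matches the descriptor-image geometry of the method: 432 x 300
#' pixels with intensities on a 0-765 summed-RGB scale. `scale` converts
#' template units to pixels and `origin` places template coordinate (0, 0)
#' on the canvas (column, row). Every sketch of one dataset must be rendered
#' with the identical spec.
#'
#' @param width,height Canvas size in pixels.
#' @param background Background intensity (default 765, white).
#' @param scale Pixels per template unit.
#' @param origin Numeric length-2: canvas (column, row) of template (0, 0).
#' @param bond_intensity Intensity used for 1-px bond lines.
#' @return Object of class `canvas_spec`.
#' @export
canvas_spec <- function(width = 432L, height = 300L, background = 765,
                        scale = 8, origin = c(200, 150), bond_intensity = 0) {
  stopifnot(width > 0, height > 0, scale > 0, length(origin) == 2,
            background >= 0, background <= 765,
            bond_intensity >= 0, bond_intensity <= 765)
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, scale = scale,
                 origin = as.numeric(origin), bond_intensity = bond_intensity),
            class = "canvas_spec")
}

#' @export
print.canvas_spec <- function(x, ...) {
  cat("<canvas_spec> ", x$width, "x", x$height, " px, scale ", x$scale,
      " px/unit, origin (", x$origin[1], ", ", x$origin[2], "), background ",
      x$background, "\n", sep = "")
  invisible(x)
}

# template (x, y) -> canvas (col, row); row grows downwards
.to_pixel <- function(spec, x, y) {
  cbind(col = spec$origin[1] + spec$scale * x,
        row = spec$origin[2] - spec$scale * y)
}

#' Rasterise one sketch into a property-weighted pixel image
#'
#' Bonds are drawn first as 1-px lines at `spec$bond_intensity`; atoms are
#' then painted in file order as filled disks (later atoms overwrite). Disk
#' radius is `scale * r_vdw` pixels for every channel; the channel only sets
#' the fill intensity, `background * (1 - prop / prop_max)`, so a larger
#' property value paints a darker disk. Pixel membership is exact integer
#' Euclidean distance (no anti-aliasing), making images bit-reproducible.
#'
#' @param sk A [sketch()].
#' @param channel `"r_vdw"`, `"epsilon"` or `"ratio"`.
#' @param spec A [canvas_spec()].
#' @param props Element property table from [load_property_table()].
#' @param prop_max Property value mapped to intensity 0; defaults to the
#'   channel maximum of `props` so all images share one mapping.
#' @return `height x width` numeric matrix with values in \[0, 765\],
#'   class `pixel_image`.
#' @export
rasterize <- function(sk, channel = c("r_vdw", "epsilon", "ratio"),
                      spec = canvas_spec(), props = load_property_table(),
                      prop_max = NULL) {
  channel <- match.arg(channel)
  if (is.null(prop_max)) prop_max <- max(props[[channel]])
  img <- matrix(spec$background, nrow = spec$height, ncol = spec$width)
  if (nrow(sk$atoms) == 0L) return(structure(img, class = "pixel_image"))

  pc <- .to_pixel(spec, sk$atoms$x, sk$atoms$y)
  radii <- spec$scale * element_property(props, sk$atoms$element, "r_vdw")
  out <- pc[, "col"] - radii < 1 | pc[, "col"] + radii > spec$width |
         pc[, "row"] - radii < 1 | pc[, "row"] + radii > spec$height
  if (any(out))
    stop("atom(s) ", paste(which(out), collapse = ", "), " of sketch '",
         sk$id, "' fall outside the canvas; adjust scale/origin")

  if (nrow(sk$bonds) > 0L) {
    for (b in seq_len(nrow(sk$bonds))) {
      p1 <- pc[sk$bonds$a1[b], ]; p2 <- pc[sk$bonds$a2[b], ]
      nstep <- max(abs(p2 - p1))
      nstep <- max(1L, ceiling(nstep))
      tt <- seq(0, 1, length.out = nstep + 1L)
      cols <- round(p1[1] + tt * (p2[1] - p1[1]))
      rows <- round(p1[2] + tt * (p2[2] - p1[2]))
      img[cbind(rows, cols)] <- spec$bond_intensity
    }
  }

  vals <- spec$background *
    (1 - element_property(props, sk$atoms$element, channel) / prop_max)
  for (a in seq_len(nrow(sk$atoms))) {
    r <- radii[a]; cx <- pc[a, "col"]; cy <- pc[a, "row"]
    ci <- seq.int(ceiling(cx - r), floor(cx + r))
    ri <- seq.int(ceiling(cy - r), floor(cy + r))
    d2 <- outer((ri - cy)^2, (ci - cx)^2, "+")
    inside <- d2 <= r^2
    img[ri, ci][inside] <- vals[a]
  }
  structure(img, class = "pixel_image")
}

#' @export
plot.pixel_image <- function(x, ...) {
  m <- unclass(x)
  graphics::image(t(m)[, nrow(m):1], col = grDevices::grey.colors(256, 0, 1),
                  zlim = c(0, 765), axes = FALSE, asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' Unfold an image row-major into a descriptor vector
#'
#' Pixel `(row, col)` maps to index `(row - 1) * width + col`.
#'
#' @param img Matrix (height x width).
#' @return Numeric vector of length `width * height`.
#' @export
unfold_image <- function(img) as.vector(t(unclass(img)))

#' Build the MIA descriptor matrix for one property channel
#'
#' Rasterises every sketch, unfolds each image row-major into one row of the
#' X-block, and prunes pixels that are constant across all samples (they
#' carry no variance for regression; typically background, core atoms and
#' core bonds). The pruning metadata (`kept_columns`) is retained so that
#' model vectors can be refolded into interpretable maps.
#'
#' @inheritParams rasterize
#' @param sketches List of sketches (alignment-checked).
#' @return Object of class `mia_descriptors`: list with `X` (n x
#'   n_kept matrix), `kept_columns`, `channel`, `spec`, `ids`, `n_pixels`.
#' @export
build_descriptor_matrix <- function(sketches, channel = c("r_vdw", "epsilon", "ratio"),
                                    spec = canvas_spec(),
                                    props = load_property_table(),
                                    prop_max = NULL) {
  channel <- match.arg(channel)
  n <- length(sketches)
  stopifnot(n >= 1L)
  np <- spec$width * spec$height
  X <- matrix(0, nrow = n, ncol = np)
  for (i in seq_len(n))
    X[i, ] <- unfold_image(rasterize(sketches[[i]], channel, spec, props, prop_max))
  cmax <- X[1, ]; cmin <- X[1, ]
  if (n > 1L) for (i in 2:n) {
    cmax <- pmax(cmax, X[i, ]); cmin <- pmin(cmin, X[i, ])
  }
  kept <- which(cmax != cmin)
  structure(list(X = X[, kept, drop = FALSE], kept_columns = kept,
                 channel = channel, spec = spec,
                 ids = vapply(sketches, `[[`, character(1), "id"),
                 n_pixels = np),
            class = "mia_descriptors")
}

#' @export
print.mia_descriptors <- function(x, ...) {
  cat("<mia_descriptors> channel ", x$channel, ": ", nrow(x$X), " samples, ",
      length(x$kept_columns), " / ", x$n_pixels, " pixels kept\n", sep = "")
  invisible(x)
}

#' Refold a descriptor-space vector into a pixel map
#'
#' Exact inverse of the row-major unfolding restricted to the kept columns;
#' pruned pixels are rendered as `NA` (background sentinel).
#'
#' @param values Numeric vector, one value per kept column.
#' @param meta A `mia_descriptors` object or a fitted [fit_pls()] model
#'   carrying descriptor metadata.
#' @param kind Map label, e.g. `"vip"` or `"coefficient"`.
#' @return `height x width` matrix of class `mia_map`.
#' @export
refold <- function(values, meta, kind = "coefficient") {
  if (inherits(meta, "mia_pls")) meta <- meta$meta
  if (is.null(meta)) stop("no descriptor metadata available for refolding")
  if (length(values) != length(meta$kept_columns))
    stop("vector length ", length(values), " != number of kept columns ",
         length(meta$kept_columns))
  flat <- rep(NA_real_, meta$n_pixels)
  flat[meta$kept_columns] <- values
  m <- matrix(flat, nrow = meta$spec$height, ncol = meta$spec$width, byrow = TRUE)
  structure(m, class = "mia_map", kind = kind, channel = meta$channel)
}

#' @export
print.mia_map <- function(x, ...) {
  v <- x[!is.na(x)]
  cat("<mia_map> ", attr(x, "kind"), " map (channel ", attr(x, "channel"),
      "): ", length(v), " active pixels, range [",
      signif(min(v), 4), ", ", signif(max(v), 4), "]\n", sep = "")
  invisible(x)
}

#' Plot an interpretation map
#'
#' Coefficient maps use a diverging palette centred on zero; VIP maps a
#' sequential one. Pruned pixels are drawn as white.
#'
#' @param x A `mia_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.mia_map <- function(x, ...) {
  m <- unclass(x)
  kind <- attr(x, "kind")
  if (identical(kind, "coefficient")) {
    lim <- max(abs(m), na.rm = TRUE)
    col <- grDevices::hcl.colors(255, "Blue-Red 3")
    zlim <- c(-lim, lim)
  } else {
    col <- grDevices::hcl.colors(255, "YlOrRd", rev = TRUE)
    zlim <- range(m, na.rm = TRUE)
  }
  graphics::image(t(m)[, nrow(m):1], col = col, zlim = zlim, axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' Export an image or map as 16-bit greyscale PNG
#'
#' Intensities 0-765 are stored as `value / 765` in a 16-bit channel, which
#' is lossless for integer-valued images. Requires the `png` package.
#'
#' @param img A `pixel_image` or `mia_map` (NA rendered as white).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  m <- unclass(img)
  if (inherits(img, "mia_map")) {
    rng <- range(m, na.rm = TRUE)
    m <- (m - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    m[is.na(m)] <- 1
  } else m <- m / 765
  png::writePNG(m, path, dpi = NULL)
  invisible(path)
}
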