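# Candidate design: enumerate substituent combinations favoured by the
# interpretation maps, predict their activity per property channel, and
# rank against a reference inhibitor.

#' Enumerate candidate structures from per-position substituent shortlists
#'
#' Takes the Cartesian product of the supplied substituent sets (the
#' shortlist is user input, typically read off the VIP and coefficient
#' maps), removes duplicates by substituent composition, and stamps each
#' combination onto the scaffold template in a deterministic order.
#'
#' @param substituent_sets Named list: position tag -> character vector of
#'   substituent names (non-empty).
#' @param scaffold Scaffold template, see [default_scaffold()].
#' @param fragments Fragment library, see [substituent_fragments()].
#' @param prefix Candidate id prefix.
#' @return List of sketches; each carries its assignment as attribute
#'   `"assignment"`.
#' @export
enumerate_candidates <- function(substituent_sets,
                                 scaffold = default_scaffold(),
                                 fragments = substituent_fragments(),
                                 prefix = "P") {
  if (!length(substituent_sets) || any(!lengths(substituent_sets)))
    stop("every varied position needs a non-empty substituent set")
  grid <- expand.grid(substituent_sets, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- apply(grid, 1, paste, collapse = "|")
  grid <- grid[!duplicated(key), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    a <- as.list(grid[i, , drop = FALSE])
    s <- .assemble_sketch(sprintf("%s%d", prefix, i), a,
                          scaffold = scaffold, fragments = fragments)
    attr(s, "assignment") <- a
    s
  })
}

#' Predict activity for sketches with a fitted model
#'
#' Rasterises the sketches with the model's own canvas and channel,
#' restricts the unfolded pixels to the model's kept columns, and predicts.
#'
#' @param model Fitted `mia_pls` carrying descriptor metadata.
#' @param sketches List of sketches on the training template.
#' @param props Element property table.
#' @return Numeric vector of predicted pKi.
#' @export
predict_sketches <- function(model, sketches, props = load_property_table()) {
  if (is.null(model$meta))
    stop("model carries no descriptor metadata; fit it from a descriptor block")
  meta <- model$meta
  Xk <- t(vapply(sketches, function(s)
    unfold_image(rasterize(s, meta$channel, meta$spec, props))[meta$kept_columns],
    numeric(length(meta$kept_columns))))
  predict(model, Xk)
}

#' Predict candidates across the three property channels
#'
#' Each candidate is rasterised and predicted once per channel; the
#' reported activity is the mean of the three channel predictions and its
#' error bar their standard deviation.
#'
#' @param candidates List of candidate sketches.
#' @param models_by_channel Named list of fitted `mia_pls` models, one per
#'   channel (`r_vdw`, `epsilon`, `ratio`), sharing one canvas.
#' @param props Element property table.
#' @return data.frame: `id`, one `pki_<channel>` column per channel,
#'   `mean`, `sd`.
#' @export
predict_candidates <- function(candidates, models_by_channel,
                               props = load_property_table()) {
  need <- c("r_vdw", "epsilon", "ratio")
  miss <- setdiff(need, names(models_by_channel))
  if (length(miss)) stop("missing channel model(s): ", paste(miss, collapse = ", "))
  preds <- vapply(need, function(ch)
    predict_sketches(models_by_channel[[ch]], candidates, props),
    numeric(length(candidates)))
  if (length(candidates) == 1L) preds <- matrix(preds, nrow = 1L,
                                                dimnames = list(NULL, need))
  out <- data.frame(id = vapply(candidates, `[[`, character(1), "id"),
                    preds, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("pki_", need)
  out$mean <- rowMeans(preds)
  out$sd <- apply(preds, 1, sd)
  out
}

#' Rank candidates against a reference compound
#'
#' Orders candidates by descending mean predicted pKi (ties broken by id)
#' and counts how many exceed the reference activity.
#'
#' @param records data.frame from [predict_candidates()].
#' @param reference_pki Reference activity (e.g. mesotrione, pKi 7.699).
#' @return The records, reordered, with a `rank` column and attributes
#'   `n_above` and `reference_pki`.
#' @export
rank_vs_reference <- function(records, reference_pki) {
  stopifnot(is.finite(reference_pki) || reference_pki == -Inf)
  ord <- order(-records$mean, records$id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, n_above = sum(records$mean > reference_pki),
            reference_pki = reference_pki)
}
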