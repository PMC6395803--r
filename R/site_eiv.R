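#' Compute site ecological indicator values
#'
#' The site EIV of a plot on a dimension is the unweighted arithmetic mean
#' of the indicator values of the species present at the plot, skipping
#' species whose indicator value on that dimension is missing. When a
#' focal species is given it is excluded from every plot's mean
#' (leave-one-out), so the predictor never contains information about the
#' species being modelled. Plots where no species contributes to a
#' dimension get a missing value.
#'
#' @param x an `eiv_community`, a plot x species 0/1 matrix with dimnames,
#'   or a wide presence table with a `plot_id` column.
#' @param eivs species indicator table: tibble with `species_id` and
#'   ordinal columns among `T`, `M`, `L`, `K`, `R`, `N` (`F` accepted as an
#'   alias of `M`).
#' @param focal_species optional species id to exclude from all means.
#' @param dimensions dimensions to compute (default: all present in
#'   `eivs`).
#' @return A tibble with `plot_id`, `focal_species`, one mean column per
#'   dimension, and matching `n_<dim>` contributor counts.
#' @export
compute_site_eivs <- function(x, eivs, focal_species = NULL,
                              dimensions = NULL) {
  presence <- as_presence_matrix(x)
  names(eivs) <- canonical_eiv_names(names(eivs))
  dimensions <- dimensions %||% intersect(EIV_DIMS, names(eivs))
  missing_dims <- setdiff(dimensions, names(eivs))
  if (length(missing_dims) > 0) {
    stopf("dimension(s) absent from the species EIV table: %s",
          paste(missing_dims, collapse = ", "))
  }
  if (length(dimensions) == 0) abort("no indicator dimensions to compute")
  if (anyDuplicated(eivs$species_id)) {
    abort("species_id in the EIV table must be unique")
  }
  sp <- colnames(presence)
  unknown_sp <- setdiff(sp, eivs$species_id)
  if (length(unknown_sp) > 0) {
    warn(sprintf("%d species in the community have no EIV entry and are skipped: %s%s",
                 length(unknown_sp), paste(head(unknown_sp, 5), collapse = ", "),
                 if (length(unknown_sp) > 5) ", ..." else ""))
  }
  if (!is.null(focal_species)) {
    if (!focal_species %in% sp) {
      stopf("unknown focal species id: %s", focal_species)
    }
    presence <- presence[, sp != focal_species, drop = FALSE]
    sp <- colnames(presence)
  }
  # align EIVs to the (possibly reduced) species columns
  idx <- match(sp, eivs$species_id)
  e <- as.matrix(eivs[idx, dimensions, drop = FALSE])
  e[is.na(idx), ] <- NA   # species without an EIV entry contribute nothing
  known <- !is.na(e)
  storage.mode(presence) <- "double"
  sums <- presence %*% replace(e, !known, 0)
  counts <- presence %*% known
  values <- sums / counts
  values[counts == 0] <- NA_real_
  out <- tibble(plot_id = rownames(presence) %||%
                  sprintf("plot%05d", seq_len(nrow(presence))),
                focal_species = focal_species %||% NA_character_)
  for (d in dimensions) out[[d]] <- unname(values[, d])
  for (d in dimensions) out[[paste0("n_", d)]] <- as.integer(counts[, d])
  out
}
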