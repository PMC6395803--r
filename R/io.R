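#' Read a relevé (plot x species) table
#'
#' Accepts either a long table with `plot_id` and `species_id` columns
#' (one row per occurrence) or a wide 0/1 table with a `plot_id` column
#' and one column per species; the layout is auto-detected from the
#' header. Duplicated (plot, species) rows collapse to a single presence
#' with a warning.
#'
#' @param path CSV file path.
#' @param predictors optional CSV of plot-level predictors (must have a
#'   `plot_id` column) to attach.
#' @return A list of class `eiv_community` with `plots`, `presence` and,
#'   when supplied, `predictors`.
#' @export
read_releve_table <- function(path, predictors = NULL) {
  tab <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (all(c("plot_id", "species_id") %in% names(tab))) {
    dup <- duplicated(tab[, c("plot_id", "species_id")])
    if (any(dup)) {
      warn(sprintf("%d duplicated (plot, species) row(s) collapsed to single presences",
                   sum(dup)))
      tab <- tab[!dup, ]
    }
    plot_ids <- unique(tab$plot_id)
    species_ids <- unique(tab$species_id)
    presence <- matrix(0L, length(plot_ids), length(species_ids),
                       dimnames = list(plot_ids, species_ids))
    presence[cbind(match(tab$plot_id, plot_ids),
                   match(tab$species_id, species_ids))] <- 1L
  } else if ("plot_id" %in% names(tab)) {
    sp_cols <- setdiff(names(tab), "plot_id")
    vals <- as.matrix(tab[sp_cols])
    if (!all(vals %in% c(0, 1))) {
      abort("wide relevé table must contain only 0/1 presence values")
    }
    presence <- matrix(as.integer(vals), nrow(vals), ncol(vals),
                       dimnames = list(tab$plot_id, sp_cols))
    plot_ids <- tab$plot_id
  } else {
    abort(paste("unknown relevé layout: expected either columns",
                "(plot_id, species_id) [long] or plot_id plus one 0/1",
                "column per species [wide]"))
  }
  pred_tbl <- NULL
  if (!is.null(predictors)) {
    pred_tbl <- as_tibble(utils::read.csv(predictors, check.names = FALSE))
    if (!"plot_id" %in% names(pred_tbl)) {
      abort("predictor table must have a plot_id column")
    }
  }
  structure(list(plots = tibble(plot_id = rownames(presence)),
                 predictors = pred_tbl, presence = presence),
            class = "eiv_community")
}

#' Write a community presence matrix as a wide CSV
#'
#' @param x an `eiv_community` or presence matrix.
#' @param path output CSV path.
#' @export
write_presence_csv <- function(x, path) {
  m <- as_presence_matrix(x)
  out <- data.frame(plot_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species indicator-value table
#'
#' CSV with a `species_id` column and ordinal indicator columns (letters
#' among `T`, `M`, `L`, `K`, `R`, `N`; `F` accepted as an alias of `M`).
#' Empty cells are missing values; present values outside the ordinal
#' range are rejected with their row number.
#'
#' @param path CSV file path.
#' @param range allowed ordinal range (default 1-5).
#' @return A tibble with `species_id` and integer indicator columns.
#' @export
read_species_eivs <- function(path, range = c(1L, 5L)) {
  tab <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!"species_id" %in% names(tab)) {
    abort("species EIV table must have a species_id column")
  }
  names(tab) <- canonical_eiv_names(names(tab))
  for (d in intersect(EIV_DIMS, names(tab))) {
    v <- tab[[d]]
    bad <- which(!is.na(v) & (v < range[1] | v > range[2] | v != floor(v)))
    if (length(bad) > 0) {
      stopf("invalid %s value %s at row %d (allowed: integers %d-%d)",
            d, format(v[bad[1]]), bad[1], range[1], range[2])
    }
    tab[[d]] <- as.integer(v)
  }
  tab
}

#' Write a species indicator-value table
#'
#' @param eivs tibble with `species_id` and indicator columns.
#' @param path output CSV path.
#' @export
write_species_eivs <- function(eivs, path) {
  utils::write.csv(eivs, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write site EIVs to CSV
#'
#' @param site_eivs output of [compute_site_eivs()].
#' @param path output CSV path.
#' @export
write_site_eivs <- function(site_eivs, path) {
  utils::write.csv(site_eivs, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a layer matrix as an ESRI ASCII grid
#'
#' @param layer numeric matrix (row 1 = northernmost row).
#' @param path output `.asc` path.
#' @param cell_size grid cell size.
#' @param xll,yll lower-left corner coordinates.
#' @export
write_ascii_grid <- function(layer, path, cell_size = 25, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(layer)),
               sprintf("nrows %d", nrow(layer)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cell_size),
               "NODATA_value -9999"), con)
  apply(layer, 1, function(row) {
    writeLines(paste(format(row, digits = 15, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  })
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @return A numeric matrix with `cell_size`, `xll`, `yll` attributes;
#'   NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  attr(m, "cell_size") <- hdr$cellsize
  attr(m, "xll") <- hdr$xllcorner
  attr(m, "yll") <- hdr$yllcorner
  m
}

#' Write all landscape layers as ASCII grids
#'
#' One `.asc` file per layer, named `latent_<dim>.asc` / `mapped_<name>.asc`.
#'
#' @param landscape an `eiv_landscape`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(landscape$latent)) {
    write_ascii_grid(landscape$latent[[d]],
                     file.path(dir, paste0("latent_", d, ".asc")),
                     cell_size = landscape$cell_size)
  }
  for (m in names(landscape$mapped)) {
    write_ascii_grid(landscape$mapped[[m]],
                     file.path(dir, paste0("mapped_", m, ".asc")),
                     cell_size = landscape$cell_size)
  }
  invisible(dir)
}
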