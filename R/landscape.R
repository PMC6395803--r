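#' Configure a synthetic landscape
#'
#' Describes the latent environmental gradients of a simulated mountain
#' landscape and the imperfect "mapped" proxy layers derived from them.
#' Each latent gradient is a spatially autocorrelated random field; each
#' mapped layer equals its latent parent plus a smoothed error field whose
#' standard deviation is expressed in units of the latent layer's SD, so an
#' `error_sd` of `k` yields an expected latent-mapped Pearson correlation of
#' `1 / sqrt(1 + k^2)`.
#'
#' The default configuration encodes the study design the package is built
#' around: a temperature map that is essentially exact, moderately degraded
#' maps for soil pH, precipitation (standing in for moisture) and solar
#' radiation (standing in for light), two very noisy topographic proxies
#' (topographic position and slope) for continentality, and a nutrient
#' gradient that has no map of its own but co-varies with soil reaction.
#'
#' @param grid integer vector `c(rows, cols)`; at least 16 x 16.
#' @param cell_size edge length of a grid cell (arbitrary units).
#' @param dims named list of per-dimension settings. Each element may set
#'   `range` (length-2 numeric), `length_scale` (smoothing scale in cells,
#'   positive), `mapped` (named numeric vector: mapped layer name ->
#'   error SD in latent-SD units), and optionally `mix_with` / `mix_rho`
#'   to correlate the dimension with an earlier one.
#' @param orthogonal make the latent gradients (and the map-error fields)
#'   mutually uncorrelated by residualizing each new field against the
#'   previous ones (default TRUE). Smooth random fields on a finite grid
#'   have few effective degrees of freedom, so without this step sizeable
#'   spurious cross-correlations between nominally independent gradients
#'   are common; orthogonalizing keeps any configured correlation
#'   (`mix_rho`) the only cross-gradient structure.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(grid = c(120L, 120L), cell_size = 25,
                             dims = NULL, orthogonal = TRUE) {
  default_dims <- list(
    temperature    = list(range = c(-2, 18), length_scale = 14,
                          mapped = c(temperature = 0)),
    moisture       = list(range = c(0, 10), length_scale = 8,
                          mapped = c(precipitation = 2)),
    light          = list(range = c(0, 10), length_scale = 6,
                          mapped = c(radiation = 2)),
    reaction       = list(range = c(3, 8), length_scale = 8,
                          mapped = c(ph = 1)),
    nutrients      = list(range = c(0, 10), length_scale = 6,
                          mapped = c(), mix_with = "reaction",
                          mix_rho = 0.85),
    continentality = list(range = c(0, 10), length_scale = 10,
                          mapped = c(topo_position = 10, slope = 10))
  )
  dims <- dims %||% default_dims
  if (is.null(names(dims)) || any(names(dims) == "")) {
    abort("every landscape dimension must be named")
  }
  unknown <- setdiff(names(dims), names(EIV_LETTERS))
  if (length(unknown) > 0) {
    stopf("unknown dimension name(s): %s", paste(unknown, collapse = ", "))
  }
  for (d in names(dims)) {
    dims[[d]]$range <- dims[[d]]$range %||% c(0, 10)
    dims[[d]]$length_scale <- dims[[d]]$length_scale %||% 8
    dims[[d]]$mapped <- dims[[d]]$mapped %||% c()
    if (dims[[d]]$length_scale <= 0) {
      stopf("length_scale for dimension '%s' must be positive", d)
    }
    if (any(dims[[d]]$mapped < 0)) {
      stopf("mapped error SDs for dimension '%s' must be nonnegative", d)
    }
    mw <- dims[[d]]$mix_with
    if (!is.null(mw) && !mw %in% head(names(dims), match(d, names(dims)) - 1)) {
      stopf("dimension '%s' mixes with '%s', which is not defined before it",
            d, mw)
    }
  }
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 16)) {
    abort("grid must be at least 16 x 16")
  }
  structure(list(grid = grid, cell_size = cell_size, dims = dims,
                 orthogonal = isTRUE(orthogonal)),
            class = "landscape_config")
}

# Spatially autocorrelated standard field: white noise convolved with a
# Gaussian kernel (circular, via FFT), standardized to mean 0 / SD 1.
smooth_field <- function(nr, nc, length_scale) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(di^2, dj^2, "+") / (2 * length_scale^2))
  kern <- kern / sum(kern)
  sm <- Re(fft(fft(noise) * fft(kern), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / sd(as.vector(sm))
}

# residualize a standardized field against a list of standardized fields
# (least squares, so the basis need not be mutually orthogonal), then
# re-standardize
orthogonalize_field <- function(f, basis) {
  v <- as.vector(f)
  B <- vapply(basis, as.vector, numeric(length(v)))
  r <- qr.resid(qr(B), v)
  m <- matrix(r, nrow(f), ncol(f))
  (m - mean(m)) / sd(r)
}

#' Generate a synthetic landscape
#'
#' Draws every latent gradient and its mapped proxy layers described by a
#' [landscape_config()]. Layers with error SD zero are bit-identical copies
#' of their latent parent.
#'
#' @param config a [landscape_config()].
#' @param seed integer seed; the landscape is a pure function of
#'   `(config, seed)`.
#' @return An object of class `eiv_landscape`: latent and mapped layer
#'   matrices plus the mapping from mapped layer to parent dimension.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1L) {
  if (!inherits(config, "landscape_config")) config <- do.call(landscape_config, config)
  nr <- config$grid[1]; nc <- config$grid[2]
  withr::with_seed(seed, {
    std <- list()     # standardized latent fields
    latent <- list()
    mapped <- list()
    mapped_parent <- character()
    error_sd <- numeric()
    # pass 1: all latent gradients
    for (d in names(config$dims)) {
      cfg <- config$dims[[d]]
      f <- smooth_field(nr, nc, cfg$length_scale)
      if (config$orthogonal && length(std) > 0) {
        f <- orthogonalize_field(f, std)
      }
      if (!is.null(cfg$mix_with)) {
        rho <- cfg$mix_rho %||% 0.5
        f <- rho * std[[cfg$mix_with]] + sqrt(1 - rho^2) * f
        f <- (f - mean(f)) / sd(as.vector(f))
      }
      std[[d]] <- f
      latent[[d]] <- cfg$range[1] +
        (f - min(f)) / (max(f) - min(f)) * diff(cfg$range)
    }
    # pass 2: mapped proxies; each error field is kept orthogonal to every
    # latent gradient (and earlier error fields), so map error cannot leak
    # signal about any other dimension
    basis <- std
    for (d in names(config$dims)) {
      cfg <- config$dims[[d]]
      f <- std[[d]]
      rescale <- function(x) {
        cfg$range[1] + (x - min(f)) / (max(f) - min(f)) * diff(cfg$range)
      }
      for (m in names(cfg$mapped)) {
        k <- cfg$mapped[[m]]
        if (k == 0) {
          mapped[[m]] <- latent[[d]]
        } else {
          err <- smooth_field(nr, nc, cfg$length_scale)
          if (config$orthogonal) {
            err <- orthogonalize_field(err, basis)
            basis <- c(basis, list(err))
          }
          mapped[[m]] <- rescale(f + k * err)
        }
        mapped_parent[m] <- d
        error_sd[m] <- k
      }
    }
    structure(
      list(grid = c(nr, nc), cell_size = config$cell_size,
           latent = latent, mapped = mapped,
           mapped_parent = mapped_parent, layer_error_sd = error_sd,
           config = config, seed = as.integer(seed)),
      class = "eiv_landscape"
    )
  })
}

#' @export
print.eiv_landscape <- function(x, ...) {
  cat(sprintf("<eiv_landscape> %d x %d cells (cell size %s)\n",
              x$grid[1], x$grid[2], format(x$cell_size)))
  cat("  latent: ", paste(names(x$latent), collapse = ", "), "\n", sep = "")
  cat("  mapped: ",
      paste(sprintf("%s (err %.3g x %s)", names(x$mapped),
                    x$layer_error_sd, x$mapped_parent), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract layer values at grid cells
#'
#' @param landscape an `eiv_landscape`.
#' @param cells tibble/data frame with integer columns `x` (column index)
#'   and `y` (row index).
#' @param which `"mapped"` or `"latent"`.
#' @return A tibble with one column per layer, rows aligned with `cells`.
#' @export
extract_layers <- function(landscape, cells, which = c("mapped", "latent")) {
  which <- match.arg(which)
  layers <- landscape[[which]]
  if (any(cells$y < 1 | cells$y > landscape$grid[1] |
          cells$x < 1 | cells$x > landscape$grid[2])) {
    abort("cell coordinates fall outside the landscape grid")
  }
  idx <- cbind(cells$y, cells$x)
  as_tibble(lapply(layers, function(m) m[idx]))
}
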