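#' Labeled spectral dataset
#'
#' The unit of data every stage of the package consumes: `N` reflectance
#' spectra of `D` bands each, with one integer class label per spectrum.
#' Labels are 0-based class indices in `[0, C)` (matching the confusion-matrix
#' conventions); `class_names` gives the human-readable class names, e.g. the
#' burn temperatures `"50 °C" ... "300 °C"`.
#'
#' @param spectra Numeric matrix `[N x D]` of reflectance values.
#' @param labels Integer vector of length `N`, values in `[0, C)`.
#' @param wavelengths Numeric vector of length `D`, strictly increasing, in nm.
#'   Defaults to an even grid over 400-1000 nm.
#' @param class_names Character vector of length `C`. Defaults to
#'   `"class 0" ...`.
#' @param provenance Character scalar recording where the data came from
#'   (a file path or a generator-config hash).
#' @return An object of class `spectral_dataset`.
#' @export
#' @examples
#' ds <- spectral_dataset(matrix(runif(20), 4, 5), labels = c(0L, 0L, 1L, 1L))
#' ds
spectral_dataset <- function(spectra, labels,
                             wavelengths = NULL,
                             class_names = NULL,
                             provenance = "in-memory") {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != nrow(spectra)) {
    stop("length(labels) must equal nrow(spectra)", call. = FALSE)
  }
  check_finite(spectra, "spectra")
  if (any(labels < 0)) stop("labels must be >= 0", call. = FALSE)
  D <- ncol(spectra)
  if (is.null(wavelengths)) wavelengths <- seq(400, 1000, length.out = D)
  if (length(wavelengths) != D) {
    stop("length(wavelengths) must equal the number of bands", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  C <- max(labels) + 1L
  if (is.null(class_names)) class_names <- paste("class", seq_len(C) - 1L)
  if (length(class_names) < C) {
    stop("class_names shorter than the number of observed classes",
         call. = FALSE)
  }
  structure(list(spectra = spectra, labels = labels,
                 wavelengths = as.numeric(wavelengths),
                 class_names = class_names,
                 provenance = provenance),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d bands (%.0f-%.0f nm), %d classes\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavelengths), max(x$wavelengths),
              length(x$class_names)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of spectra / bands in a dataset
#' @param x A `spectral_dataset`.
#' @return Integer.
#' @export
n_spectra <- function(x) nrow(x$spectra)

#' @rdname n_spectra
#' @export
n_bands <- function(x) ncol(x$spectra)

#' Tidy view of a spectral dataset
#'
#' One row per (spectrum, band) pair: columns `.id`, `class`, `label`,
#' `wavelength`, `reflectance`. Convenient for dplyr/ggplot2 work.
#'
#' @param x A `spectral_dataset`.
#' @param ... Unused.
#' @return A tibble with `N * D` rows.
#' @method as_tibble spectral_dataset
#' @export
as_tibble.spectral_dataset <- function(x, ...) {
  N <- nrow(x$spectra); D <- ncol(x$spectra)
  tibble::tibble(
    .id = rep(seq_len(N), times = D),
    label = rep(x$labels, times = D),
    class = rep(factor(x$class_names[x$labels + 1L],
                       levels = x$class_names), times = D),
    wavelength = rep(x$wavelengths, each = N),
    reflectance = as.vector(x$spectra)
  )
}

#' Subset a spectral dataset by spectrum index
#' @param x A `spectral_dataset`.
#' @param i Integer or logical index over spectra.
#' @param ... Unused.
#' @return A `spectral_dataset` with the selected spectra.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$spectra[i, , drop = FALSE], x$labels[i],
                   wavelengths = x$wavelengths, class_names = x$class_names,
                   provenance = x$provenance)
}

#' Stable content hash of a dataset
#'
#' A short hexadecimal digest of the spectra, labels and wavelengths, used in
#' run manifests so results can be tied to their exact inputs. Implemented as
#' a simple 32-bit FNV-style hash over the serialized numeric content.
#'
#' @param x A `spectral_dataset`.
#' @return A character scalar like `"a83b0c1f"`.
#' @export
dataset_hash <- function(x) {
  stopifnot(inherits(x, "spectral_dataset"))
  bytes <- as.integer(c(writeBin(as.vector(x$spectra), raw()),
                        writeBin(as.integer(x$labels), raw()),
                        writeBin(as.vector(x$wavelengths), raw())))
  # order-sensitive weighted sum, vectorized in chunks small enough that the
  # partial sums stay exact in double precision
  p <- 2147483647
  w <- numeric(64)
  w[1] <- 1
  for (i in 2:64) w[i] <- (w[i - 1] * 31) %% p
  n <- length(bytes)
  h <- (n * 7919) %% p
  chunk <- 4096L
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    i <- start:end
    h <- (h * 33 + sum((bytes[i] + i %% 251) * w[(i - 1L) %% 64L + 1L])) %% p
  }
  sprintf("%08x", as.integer(h))
}
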