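#' Write a spectral dataset to CSV
#'
#' The canonical interchange format: one row per spectrum, one numeric column
#' per band named `wl_<wavelength>` (nm), and a final `label` column with the
#' 0-based class index. Band order is always ascending wavelength.
#'
#' @param dataset A [spectral_dataset].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  df <- as.data.frame(dataset$spectra)
  names(df) <- sprintf("wl_%g", dataset$wavelengths)
  df$label <- dataset$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectral dataset from CSV
#'
#' Expects a header row, `D` numeric reflectance columns and a `label`
#' column. Wavelengths are parsed from `wl_<nm>`-style headers when present,
#' otherwise inferred linearly over `wavelength_range`. Malformed input —
#' a missing label column, non-numeric reflectance, out-of-range labels —
#' raises a descriptive error (with row numbers where applicable) rather
#' than silently coercing.
#'
#' @param path CSV file path.
#' @param wavelength_range Length-2 numeric fallback range in nm when the
#'   headers carry no wavelengths.
#' @param class_names Optional class names (defaults to `"class 0" ...`).
#' @return A [spectral_dataset].
#' @export
read_csv_dataset <- function(path, wavelength_range = c(400, 1000),
                             class_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    stop(sprintf("no 'label' column in %s (found: %s)", path,
                 paste(head(names(df), 5), collapse = ", ")), call. = FALSE)
  }
  lab <- df[["label"]]
  spec_cols <- setdiff(names(df), "label")
  spec <- df[spec_cols]
  bad_col <- !vapply(spec, is.numeric, logical(1))
  if (any(bad_col)) {
    col <- spec_cols[which(bad_col)[1]]
    bad_row <- which(is.na(suppressWarnings(as.numeric(spec[[col]]))))[1]
    stop(sprintf("non-numeric reflectance in column '%s' (e.g. row %d)",
                 col, bad_row), call. = FALSE)
  }
  spec <- as.matrix(spec)
  if (anyNA(spec)) {
    bad <- which(rowSums(is.na(spec)) > 0)[1]
    stop(sprintf("missing/non-numeric reflectance values (e.g. row %d)", bad),
         call. = FALSE)
  }
  if (anyNA(lab) || any(lab != floor(lab)) || any(lab < 0)) {
    bad <- which(is.na(lab) | lab != floor(lab) | lab < 0)[1]
    stop(sprintf("labels must be non-negative integers (bad value at row %d)",
                 bad), call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(sub("^wl_", "", spec_cols)))
  if (anyNA(wl) || any(diff(wl) <= 0)) {
    wl <- seq(wavelength_range[1], wavelength_range[2], length.out = ncol(spec))
  }
  spectral_dataset(spec, as.integer(lab), wavelengths = wl,
                   class_names = class_names, provenance = path)
}

# ---- ENVI cube support -----------------------------------------------------

.envi_dtype <- function(code) {
  switch(as.character(code),
         "4" = list(what = "double", size = 4),  # float32
         "5" = list(what = "double", size = 8),  # float64
         stop("unsupported ENVI data type code: ", code, call. = FALSE))
}

.parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  get_field <- function(name) {
    m <- regmatches(joined,
                    regexpr(sprintf("(?mi)^%s\\s*=\\s*[^\\n{]*", name),
                            joined, perl = TRUE))
    if (length(m) == 0) return(NULL)
    trimws(sub(".*=", "", m))
  }
  get_block <- function(name) {
    m <- regmatches(joined,
                    regexpr(sprintf("(?si)%s\\s*=\\s*\\{[^}]*\\}", name),
                            joined, perl = TRUE))
    if (length(m) == 0) return(NULL)
    inner <- sub(".*\\{", "", sub("\\}.*", "", m))
    as.numeric(strsplit(inner, ",")[[1]])
  }
  list(samples = as.integer(get_field("samples")),
       lines = as.integer(get_field("lines")),
       bands = as.integer(get_field("bands")),
       data_type = as.integer(get_field("data type")),
       interleave = tolower(get_field("interleave")),
       wavelengths = get_block("wavelength"))
}

#' Write a dataset as a synthetic ENVI cube plus label raster
#'
#' Lays the `N` spectra out on a near-square pixel grid (padding with an
#' unlabeled sentinel where the grid exceeds `N`), and writes an ENVI-style
#' plain-text header + binary cube in the requested interleave, together
#' with a label raster (`int32`, `-1` = unlabeled) and its own header.
#'
#' @param dataset A [spectral_dataset].
#' @param base_path Path prefix: writes `<base>.hdr`, `<base>.dat`,
#'   `<base>_labels.hdr`, `<base>_labels.dat`.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @return The header path, invisibly.
#' @export
write_envi_dataset <- function(dataset, base_path,
                               interleave = c("bsq", "bil", "bip")) {
  interleave <- match.arg(interleave)
  N <- nrow(dataset$spectra); D <- ncol(dataset$spectra)
  ncols <- ceiling(sqrt(N))
  nrows <- ceiling(N / ncols)
  npix <- nrows * ncols
  # cube array indexed [sample(col), line(row), band]
  cube <- array(0, c(ncols, nrows, D))
  labels <- rep(-1L, npix)
  for (i in seq_len(N)) {
    col <- (i - 1L) %% ncols + 1L
    row <- (i - 1L) %/% ncols + 1L
    cube[col, row, ] <- dataset$spectra[i, ]
    labels[(row - 1L) * ncols + col] <- dataset$labels[i]
  }
  perm <- switch(interleave,
                 bip = c(3, 1, 2),  # band fastest
                 bil = c(1, 3, 2),  # sample, band, line
                 bsq = c(1, 2, 3))  # sample, line, band
  dat_path <- paste0(base_path, ".dat")
  writeBin(as.vector(aperm(cube, perm)), dat_path, size = 8,
           endian = "little")
  hdr <- c("ENVI",
           "description = { synthetic spectra cube }",
           sprintf("samples = %d", ncols),
           sprintf("lines = %d", nrows),
           sprintf("bands = %d", D),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength = { %s }",
                   paste(sprintf("%g", dataset$wavelengths), collapse = ", ")))
  writeLines(hdr, paste0(base_path, ".hdr"))
  writeBin(labels, paste0(base_path, "_labels.dat"), size = 4,
           endian = "little")
  writeLines(c("ENVI",
               sprintf("samples = %d", ncols),
               sprintf("lines = %d", nrows),
               "bands = 1", "header offset = 0", "data type = 3",
               "interleave = bsq", "byte order = 0"),
             paste0(base_path, "_labels.hdr"))
  invisible(paste0(base_path, ".hdr"))
}

#' Read an ENVI cube and label raster into a dataset
#'
#' Reads an ENVI header/binary pair (float32 or float64, BSQ/BIL/BIP,
#' little-endian) plus an `int32` label raster of the same spatial
#' dimensions, flattens the labeled pixels to an `[N x D]` table and drops
#' pixels carrying the unlabeled sentinel (`-1`), recording how many were
#' dropped in the provenance string. Wavelengths are taken from the header's
#' `wavelength` block when present.
#'
#' @param hdr_path Path to the cube's `.hdr` (binary assumed at the same
#'   path with `.dat`, or the header path minus `.hdr`).
#' @param label_raster_path Path to the label raster binary (`.dat`).
#' @param class_names Optional class names.
#' @return A [spectral_dataset] of the labeled pixels.
#' @export
read_envi_cube <- function(hdr_path, label_raster_path, class_names = NULL) {
  h <- .parse_envi_header(hdr_path)
  if (is.null(h$samples) || is.null(h$lines) || is.null(h$bands)) {
    stop("malformed ENVI header: ", hdr_path, call. = FALSE)
  }
  if (!h$interleave %in% c("bsq", "bil", "bip")) {
    stop("unsupported interleave: ", h$interleave, call. = FALSE)
  }
  dat_path <- sub("\\.hdr$", ".dat", hdr_path)
  if (!file.exists(dat_path)) {
    stop("cube binary not found next to header: ", dat_path, call. = FALSE)
  }
  dt <- .envi_dtype(h$data_type)
  n_vals <- h$samples * h$lines * h$bands
  raw_vals <- readBin(dat_path, what = dt$what, n = n_vals + 1, size = dt$size,
                      endian = "little")
  if (length(raw_vals) != n_vals) {
    stop(sprintf("cube size mismatch: header implies %d values, file has %d",
                 n_vals, length(raw_vals)), call. = FALSE)
  }
  dims <- switch(h$interleave,
                 bip = c(h$bands, h$samples, h$lines),
                 bil = c(h$samples, h$bands, h$lines),
                 bsq = c(h$samples, h$lines, h$bands))
  inv_perm <- switch(h$interleave,
                     bip = c(2, 3, 1),
                     bil = c(1, 3, 2),
                     bsq = c(1, 2, 3))
  cube <- aperm(array(raw_vals, dims), inv_perm)  # [sample, line, band]

  labels <- readBin(label_raster_path, what = "integer",
                    n = h$samples * h$lines + 1, size = 4, endian = "little")
  if (length(labels) != h$samples * h$lines) {
    stop(sprintf(paste0("label raster has %d pixels but the cube is %d x %d: ",
                        "dimension mismatch"),
                 length(labels), h$samples, h$lines), call. = FALSE)
  }
  # pixel order: row-major over (line, sample), matching the writer
  keep <- which(labels >= 0L)
  n_drop <- sum(labels < 0L)
  spec <- matrix(0, length(keep), h$bands)
  for (ii in seq_along(keep)) {
    p <- keep[ii] - 1L
    spec[ii, ] <- cube[p %% h$samples + 1L, p %/% h$samples + 1L, ]
  }
  if (!all(is.finite(spec))) {
    stop("non-finite reflectance values in cube (corrupt input): ", dat_path,
         call. = FALSE)
  }
  wl <- h$wavelengths
  if (is.null(wl) || length(wl) != h$bands) {
    wl <- seq(400, 1000, length.out = h$bands)
  }
  spectral_dataset(spec, labels[keep], wavelengths = wl,
                   class_names = class_names,
                   provenance = sprintf("%s (%d unlabeled pixels dropped)",
                                        hdr_path, n_drop))
}

# ---- checkpoints and manifests --------------------------------------------

#' Save / load a trained model checkpoint
#'
#' A checkpoint is a single archive holding every parameter array together
#' with the configs that produced them (network, training, scaler, class
#' names, wavelengths, package version). Loading a checkpoint whose band or
#' class count does not match `expect_bands` / `expect_classes` fails loudly.
#'
#' @param fit An `mbnet_fit`.
#' @param path Checkpoint file path (`.rds`).
#' @return `path` invisibly (save); the restored `mbnet_fit` (load).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mbnet_fit"))
  obj <- unclass(fit)
  obj$package_version <- as.character(packageVersion("specmamba"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_bands,expect_classes Optional integers; mismatches abort.
#' @export
load_checkpoint <- function(path, expect_bands = NULL, expect_classes = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$params) || is.null(obj$net_config)) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  if (!is.null(expect_bands) && obj$net_config$n_bands != expect_bands) {
    stop(sprintf("checkpoint was trained on %d bands, data has %d",
                 obj$net_config$n_bands, expect_bands), call. = FALSE)
  }
  if (!is.null(expect_classes) && obj$net_config$n_classes != expect_classes) {
    stop(sprintf("checkpoint has %d classes, expected %d",
                 obj$net_config$n_classes, expect_classes), call. = FALSE)
  }
  structure(obj, class = "mbnet_fit")
}

#' Write a run manifest
#'
#' Records everything needed to reconstruct a result: the configuration
#' objects, the run seed, the dataset hash and the package version, as JSON
#' next to the result files.
#'
#' @param path Output JSON path.
#' @param seed Run seed.
#' @param dataset Optional [spectral_dataset] (hashed into the manifest).
#' @param ... Further named config objects/values to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, dataset = NULL, ...) {
  doc <- list(seed = seed,
              package_version = as.character(packageVersion("specmamba")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              ...)
  if (!is.null(dataset)) doc$dataset_hash <- dataset_hash(dataset)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
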