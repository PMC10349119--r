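#' Labeled spectral dataset
#'
#' Container for a set of Raman spectra sharing one wavenumber axis. Rows of
#' `intensities` are spectra, columns are wavenumbers; `labels` is the binary
#' target, with 1 conventionally marking the first sample of a pairwise
#' comparison and 0 the second.
#'
#' @param wavenumbers Numeric vector of length `p`, strictly increasing, in
#'   cm^-1.
#' @param intensities Numeric `N x p` matrix of intensities (arbitrary counts).
#' @param labels Integer/numeric vector of length `N` with values in `{0, 1}`.
#' @param sample_names Character vector of length 2: name of the label-1
#'   sample, then the label-0 sample.
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavenumbers`, `intensities`, `labels`, `sample_names`.
#' @examples
#' ds <- spectral_dataset(c(100, 200, 300),
#'                        matrix(rnorm(6), nrow = 2),
#'                        labels = c(0, 1))
#' ds
#' @export
spectral_dataset <- function(wavenumbers, intensities, labels,
                             sample_names = c("sample1", "sample0")) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  labels <- as.integer(labels)
  if (ncol(intensities) != length(wavenumbers))
    stop("format error: intensity columns (", ncol(intensities),
         ") do not match wavenumber axis length (", length(wavenumbers), ")")
  if (nrow(intensities) != length(labels))
    stop("format error: intensity rows (", nrow(intensities),
         ") do not match number of labels (", length(labels), ")")
  if (length(wavenumbers) > 1 && any(diff(wavenumbers) <= 0))
    stop("format error: wavenumber axis must be strictly increasing (first violation at column ",
         which(diff(wavenumbers) <= 0)[1] + 1, ")")
  if (!all(labels %in% c(0L, 1L)))
    stop("format error: labels must be binary 0/1")
  if (any(!is.finite(wavenumbers)))
    stop("format error: non-finite wavenumber")
  dimnames(intensities) <- NULL
  structure(list(wavenumbers = wavenumbers,
                 intensities = intensities,
                 labels = labels,
                 sample_names = as.character(sample_names)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d points, %.2f-%.2f cm^-1\n",
              nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  labels: %d x '%s' (1), %d x '%s' (0)\n",
              sum(x$labels == 1L), x$sample_names[1],
              sum(x$labels == 0L), x$sample_names[2]))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Subset the rows (spectra) of a dataset
#'
#' @param ds A [spectral_dataset()].
#' @param i Row index vector (numeric or logical).
#' @return A `spectral_dataset` with the selected spectra.
#' @export
subset_rows <- function(ds, i) {
  stopifnot(inherits(ds, "spectral_dataset"))
  spectral_dataset(ds$wavenumbers, ds$intensities[i, , drop = FALSE],
                   ds$labels[i], ds$sample_names)
}

#' Spectral region
#'
#' A closed wavenumber interval `[lo, hi]`. The two regions the analysis
#' focuses on are the low-wavenumber window (DNA--nanowire interaction bands:
#' Ag--N stretch near 234 cm^-1, Si near 514 cm^-1) and the high-wavenumber
#' window (CH/CH3 stretching near 2934 cm^-1, sensitive to methylation).
#'
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`. Both ends inclusive.
#' @param name Optional short name ("LW", "HW", ...).
#' @return An object of class `spectral_region`.
#' @export
spectral_region <- function(lo, hi, name = sprintf("%g:%g", lo, hi)) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("invalid region: need lo < hi, got [", lo, ", ", hi, "]")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi),
                 name = as.character(name)),
            class = "spectral_region")
}

#' @rdname spectral_region
#' @export
region_lw <- function() spectral_region(125.25, 549.27, "LW")

#' @rdname spectral_region
#' @export
region_hw <- function() spectral_region(2303.16, 3399.83, "HW")

#' Restrict a dataset to a wavenumber region
#'
#' Keeps exactly the columns whose wavenumber lies in the closed interval
#' `[region$lo, region$hi]`; labels and row order are unchanged. On the default
#' synthetic axis (1700 points, 125.25-3399.83 cm^-1) the LW window keeps 221
#' points and the HW window 570.
#'
#' @param ds A [spectral_dataset()].
#' @param region A [spectral_region()], or a length-2 numeric `c(lo, hi)`.
#' @return A `spectral_dataset` on the restricted axis.
#' @export
select_region <- function(ds, region) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.numeric(region) && length(region) == 2)
    region <- spectral_region(region[1], region[2])
  stopifnot(inherits(region, "spectral_region"))
  keep <- ds$wavenumbers >= region$lo & ds$wavenumbers <= region$hi
  if (!any(keep))
    stop("empty region: no axis points inside [", region$lo, ", ", region$hi, "]")
  spectral_dataset(ds$wavenumbers[keep],
                   ds$intensities[, keep, drop = FALSE],
                   ds$labels, ds$sample_names)
}

#' Read / write a labeled spectral dataset as wide delimited text
#'
#' Wide layout: one header row carrying the wavenumbers, one row per spectrum.
#' The label travels in a reserved column (default `"label"`, first column).
#'
#' @param path File path.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param label_column Name of the label column (default `"label"`).
#' @param sample_names Passed to [spectral_dataset()].
#' @return `read_dataset` returns a [spectral_dataset()]; `write_dataset`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path, sep = ",", label_column = "label",
                         sample_names = c("sample1", "sample0")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stop("format error: no '", label_column, "' column in ", path)
  labels <- df[[label_column]]
  df[[label_column]] <- NULL
  wn <- suppressWarnings(as.numeric(names(df)))
  if (any(is.na(wn)))
    stop("format error: non-numeric wavenumber header at column ",
         which(is.na(wn))[1])
  x <- as.matrix(df)
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop("format error: non-numeric or missing intensity at row ", bad[1],
         ", column ", bad[2])
  }
  spectral_dataset(wn, x, labels, sample_names)
}

#' @rdname read_dataset
#' @param ds A [spectral_dataset()] to write.
#' @export
write_dataset <- function(ds, path, sep = ",", label_column = "label") {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(ds$labels, ds$intensities, check.names = FALSE)
  names(df) <- c(label_column, format(ds$wavenumbers, trim = TRUE, digits = 15))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
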