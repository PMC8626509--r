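#' Per-spectrum metadata for one titration point
#'
#' @param ph sample pH (0-14).
#' @param field_h1 spectrometer 1H Larmor frequency in MHz.
#' @param dims ordered nucleus identifiers of the spectrum dimensions,
#'   e.g. \code{c("N15", "H1")} for a 15N-HSQC, \code{"C13"} for 1-D
#'   carbonyl tracking.
#' @param experiment free-text experiment tag (HSQC, LR-HMQC, HCCO, ...).
#' @return a \code{spectrum_meta} object.
#' @examples
#' spectrum_meta(ph = 7.4, field_h1 = 600, dims = c("N15", "H1"))
#' @export
spectrum_meta <- function(ph, field_h1, dims, experiment = "HSQC") {
  stopifnot(is.numeric(ph), length(ph) == 1, ph >= 0, ph <= 14)
  stopifnot(is.numeric(field_h1), length(field_h1) == 1, field_h1 > 0)
  dims <- as.character(dims)
  if (length(dims) < 1) stop("at least one dimension required")
  bad <- setdiff(dims, KNOWN_NUCLEI)
  if (length(bad) > 0) stop("unknown nucleus in dims: ", paste(bad, collapse = ", "))
  structure(
    list(ph = ph, field_h1 = field_h1, dims = dims,
         experiment = as.character(experiment)[1],
         freqs = larmor_frequency(dims, field_h1)),
    class = "spectrum_meta"
  )
}

#' @export
print.spectrum_meta <- function(x, ...) {
  cat(sprintf("<spectrum_meta> pH %.2f | %s | %g MHz | dims: %s\n",
              x$ph, x$experiment, x$field_h1, paste(x$dims, collapse = "-")))
  invisible(x)
}

shift_cols <- function(ndim) paste0("w", seq_len(ndim))

validate_peaks <- function(peaks, ndim) {
  stopifnot(is.data.frame(peaks))
  cols <- shift_cols(ndim)
  missing_cols <- setdiff(c("label", cols), names(peaks))
  if (length(missing_cols) > 0) {
    stop("peak table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(peaks) > 0) {
    if (any(!nzchar(peaks$label))) stop("empty peak label")
    shifts <- as.matrix(peaks[cols])
    if (any(!is.finite(shifts))) stop("non-finite chemical shift")
  }
  invisible(peaks)
}

#' Read a Sparky-dialect peak list
#'
#' Parses a whitespace-separated assigned peak list of the kind exported by
#' Sparky/NMRFAM-Sparky: an optional \code{"Assignment w1 w2 ..."} header,
#' then one line per peak with the assignment label, one chemical-shift
#' column per dimension (ppm) and an optional height column.
#'
#' @param path path to the peak-list file.
#' @param meta \code{\link{spectrum_meta}} for the spectrum the list was
#'   picked from; its \code{dims} define the expected number of shift
#'   columns, in file column order.
#' @return a tibble with columns \code{label}, \code{w1..wk} (ppm) and
#'   \code{height} (NA when the file has no height column).
#' @export
read_peaklist <- function(path, meta) {
  stopifnot(inherits(meta, "spectrum_meta"))
  if (!file.exists(path)) stop("peak list not found: ", path)
  ndim <- length(meta$dims)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  is_header <- grepl("^\\s*Assignment\\b", lines)
  dat <- lines[!is_header]
  dat_no <- lineno[!is_header]
  if (length(dat) == 0) {
    warning("no peaks in ", path)
    out <- tibble::tibble(label = character())
    for (cc in shift_cols(ndim)) out[[cc]] <- numeric()
    out$height <- numeric()
    return(out)
  }
  toks <- strsplit(trimws(dat), "\\s+")
  nf <- lengths(toks)
  ok <- nf == ndim + 1 | nf == ndim + 2
  if (any(!ok)) {
    stop(sprintf("malformed peak line %d in %s: expected %d or %d fields, got %d",
                 dat_no[which(!ok)[1]], path, ndim + 1, ndim + 2, nf[which(!ok)[1]]))
  }
  label <- vapply(toks, `[[`, character(1), 1)
  shifts <- matrix(NA_real_, length(toks), ndim)
  for (d in seq_len(ndim)) {
    v <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), d + 1)))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric shift on line %d in %s", dat_no[which(is.na(v))[1]], path))
    }
    shifts[, d] <- v
  }
  height <- rep(NA_real_, length(toks))
  has_h <- nf == ndim + 2
  if (any(has_h)) {
    height[has_h] <- suppressWarnings(
      as.numeric(vapply(toks[has_h], function(t) t[[ndim + 2]], character(1))))
  }
  out <- tibble::tibble(label = label)
  for (d in seq_len(ndim)) out[[paste0("w", d)]] <- shifts[, d]
  out$height <- height
  validate_peaks(out, ndim)
  out
}

#' Write a Sparky-dialect peak list
#'
#' Emits the same dialect \code{\link{read_peaklist}} accepts, with an
#' \code{"Assignment w1 w2 ..."} header. Shifts are printed with 4 decimals
#' (0.0001 ppm, well below line widths).
#'
#' @param peaks peak tibble (\code{label}, \code{w1..wk}, optional
#'   \code{height}).
#' @param meta matching \code{\link{spectrum_meta}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_peaklist <- function(peaks, meta, path) {
  stopifnot(inherits(meta, "spectrum_meta"))
  ndim <- length(meta$dims)
  validate_peaks(peaks, ndim)
  cols <- shift_cols(ndim)
  has_h <- "height" %in% names(peaks) && any(is.finite(peaks$height))
  header <- paste(c("Assignment", cols, if (has_h) "Height"), collapse = "  ")
  body <- character(0)
  if (nrow(peaks) > 0) {
    fields <- lapply(cols, function(cc) sprintf("%.4f", peaks[[cc]]))
    body <- do.call(paste, c(list(format(peaks$label, width = 12)), fields,
                             if (has_h) list(sprintf("%.1f", peaks$height)),
                             sep = "  "))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Assemble a pH-ordered titration series
#'
#' @param points list of \code{list(meta = spectrum_meta, peaks = tibble)}
#'   entries, in any pH order.
#' @param reference index (after pH sorting) of the reference point that
#'   CSPs are measured against. Default: the highest-pH point.
#' @return a \code{titration_series}: points sorted by increasing pH.
#' @export
titration_series <- function(points, reference = NULL) {
  stopifnot(is.list(points), length(points) >= 1)
  for (p in points) {
    stopifnot(inherits(p$meta, "spectrum_meta"), is.data.frame(p$peaks))
    validate_peaks(p$peaks, length(p$meta$dims))
  }
  dims0 <- points[[1]]$meta$dims
  same <- vapply(points, function(p) identical(p$meta$dims, dims0), logical(1))
  if (!all(same)) stop("all titration points must share dimensionality and nucleus order")
  ph <- vapply(points, function(p) p$meta$ph, numeric(1))
  if (anyDuplicated(ph)) stop("pH values must be distinct within a series")
  ord <- order(ph)
  points <- points[ord]
  ph <- ph[ord]
  if (is.null(reference)) reference <- length(points)
  stopifnot(reference >= 1, reference <= length(points))
  structure(list(points = points, reference = reference),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  ph <- series_ph(x)
  cat(sprintf("<titration_series> %d points, pH %.2f-%.2f, reference pH %.2f (%s)\n",
              length(x$points), min(ph), max(ph), ph[x$reference],
              paste(x$points[[1]]$meta$dims, collapse = "-")))
  invisible(x)
}

series_ph <- function(series) {
  vapply(series$points, function(p) p$meta$ph, numeric(1))
}

series_ndim <- function(series) length(series$points[[1]]$meta$dims)

#' Read a titration series from a manifest file
#'
#' The manifest is a YAML file with an entry per titration point:
#' \preformatted{
#' points:
#'   - file: ph44.list
#'     ph: 4.4
#'     field_h1: 600
#'     dims: [N15, H1]
#'     experiment: HSQC
#' reference: 12     # optional, index after pH sorting
#' }
#' Relative file paths are resolved against the manifest directory.
#'
#' @param path manifest path.
#' @return a \code{\link{titration_series}}.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  if (is.null(man$points)) stop("manifest has no 'points' entry")
  base <- dirname(normalizePath(path))
  points <- lapply(man$points, function(p) {
    meta <- spectrum_meta(ph = p$ph, field_h1 = p$field_h1,
                          dims = unlist(p$dims),
                          experiment = if (is.null(p$experiment)) "HSQC" else p$experiment)
    f <- p$file
    if (!file.exists(f)) f <- file.path(base, p$file)
    list(meta = meta, peaks = read_peaklist(f, meta))
  })
  titration_series(points, reference = man$reference)
}

#' Parse a Sparky assignment label
#'
#' Labels follow \code{<residue><number><atom1>-<atom2>} (e.g.
#' \code{"E63N-H"}, \code{"H106ND1-HE1"}). Unparsable labels are kept
#' verbatim with NA residue fields; they remain trackable.
#'
#' @param label character vector of assignment labels.
#' @return tibble with \code{label}, \code{residue_type}, \code{seq_number},
#'   \code{atoms}.
#' @export
parse_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z])(\\d+)([A-Za-z0-9']+(?:-[A-Za-z0-9']+)*)$", label))
  res <- vapply(m, function(g) if (length(g)) g[2] else NA_character_, character(1))
  num <- vapply(m, function(g) if (length(g)) g[3] else NA_character_, character(1))
  atm <- vapply(m, function(g) if (length(g)) g[4] else NA_character_, character(1))
  tibble::tibble(label = label, residue_type = res,
                 seq_number = suppressWarnings(as.integer(num)), atoms = atm)
}
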