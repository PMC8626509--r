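#' Per-residue CSP-versus-pH curve
#'
#' Chemical shift perturbations are measured in Hz against the reference
#' titration point: for a multi-dimensional peak
#' \deqn{CSP(pH) = \sqrt{\sum_d (\Delta\delta_d f_d)^2}}
#' where \eqn{\Delta\delta_d} is the ppm change from the reference in
#' dimension \eqn{d} and \eqn{f_d} the Larmor frequency of that nucleus in
#' MHz, so each term is in Hz. For 1-D tracking (e.g. carboxyl 13CO)
#' this reduces to \eqn{|\Delta\delta_C| f_C}.
#'
#' @param x a \code{tracked_series} (from \code{\link{track_peaks}}), or a
#'   \code{titration_series} whose points are all fully assigned with
#'   shared labels.
#' @param residue assignment label of the peak to follow.
#' @param dims_use optional subset of dimension indices to include
#'   (e.g. \code{2} to use only the 1H dimension of an HSQC).
#' @return a \code{titration_curve}: tibble with columns \code{ph},
#'   \code{csp} (Hz) and \code{status}; lost/ambiguous points are recorded
#'   in \code{attr(, "omitted")} and excluded from the curve.
#' @export
compute_csp <- function(x, residue, dims_use = NULL) {
  stopifnot(inherits(x, "titration_series"))
  dims <- x$points[[1]]$meta$dims
  ndim <- length(dims)
  cols <- shift_cols(ndim)
  ph <- series_ph(x)
  ref <- x$reference

  if (inherits(x, "tracked_series")) {
    tr <- x$tracking[x$tracking$label == residue, , drop = FALSE]
    if (nrow(tr) == 0) stop("residue not tracked: ", residue)
    tr <- tr[order(tr$point), ]
    shifts <- as.matrix(tr[cols])
    status <- tr$status
  } else {
    shifts <- matrix(NA_real_, length(x$points), ndim)
    status <- rep("ok", length(x$points))
    for (k in seq_along(x$points)) {
      pk <- x$points[[k]]$peaks
      i <- which(pk$label == residue)
      if (length(i) == 0) {
        status[k] <- "lost"
      } else if (length(i) > 1) {
        status[k] <- "ambiguous"
      } else {
        shifts[k, ] <- as.numeric(pk[i, cols])
      }
    }
  }
  if (status[ref] != "ok") stop("residue not assigned at the reference point: ", residue)

  use <- seq_len(ndim)
  if (!is.null(dims_use)) {
    stopifnot(all(dims_use %in% use))
    use <- dims_use
  }
  freqs <- x$points[[1]]$meta$freqs[use]
  delta <- sweep(shifts[, use, drop = FALSE], 2,
                 as.numeric(shifts[ref, use]), "-")
  csp <- sqrt(rowSums(sweep(delta, 2, freqs, "*")^2))

  keep <- status == "ok"
  curve <- tibble::tibble(ph = ph[keep], csp = csp[keep], status = status[keep])
  omitted <- tibble::tibble(ph = ph[!keep], status = status[!keep])
  structure(curve,
            class = c("titration_curve", class(curve)),
            residue = residue,
            nuclei = dims[use],
            reference_ph = ph[ref],
            omitted = omitted)
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %s (%s), %d points, pH %.2f-%.2f, reference pH %.2f\n",
              attr(x, "residue"), paste(attr(x, "nuclei"), collapse = "-"),
              nrow(x), min(x$ph), max(x$ph), attr(x, "reference_ph")))
  om <- attr(x, "omitted")
  if (nrow(om) > 0) {
    cat(sprintf("  omitted: %s\n",
                paste(sprintf("pH %.2f (%s)", om$ph, om$status), collapse = ", ")))
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Build a titration curve directly from pH and CSP vectors
#'
#' Convenience constructor for curves obtained outside the peak-tracking
#' pipeline (e.g. digitised or externally computed CSPs).
#'
#' @param ph strictly increasing pH values.
#' @param csp non-negative CSPs in Hz.
#' @param residue label for reporting.
#' @return a \code{titration_curve}.
#' @export
titration_curve <- function(ph, csp, residue = "curve") {
  stopifnot(length(ph) == length(csp), !is.unsorted(ph, strictly = TRUE),
            all(is.finite(ph)), all(is.finite(csp)), all(csp >= -1e-9))
  structure(tibble::tibble(ph = ph, csp = csp, status = "ok"),
            class = c("titration_curve", "tbl_df", "tbl", "data.frame"),
            residue = residue, nuclei = NA_character_,
            reference_ph = ph[length(ph)],
            omitted = tibble::tibble(ph = numeric(), status = character()))
}

#' CSP curves for every tracked residue
#'
#' @param x a \code{tracked_series} or fully assigned
#'   \code{titration_series}.
#' @param dims_use optional dimension subset, as in
#'   \code{\link{compute_csp}}.
#' @return tibble with columns \code{residue}, \code{ph}, \code{csp},
#'   \code{status} (long format; omitted points carry NA csp).
#' @export
csp_table <- function(x, dims_use = NULL) {
  labels <- if (inherits(x, "tracked_series")) {
    unique(x$tracking$label)
  } else {
    x$points[[x$reference]]$peaks$label
  }
  out <- lapply(labels, function(l) {
    cv <- compute_csp(x, l, dims_use = dims_use)
    a <- tibble::tibble(residue = l, ph = cv$ph, csp = cv$csp, status = cv$status)
    om <- attr(cv, "omitted")
    if (nrow(om) > 0) {
      a <- dplyr::bind_rows(a, tibble::tibble(residue = l, ph = om$ph,
                                              csp = NA_real_, status = om$status))
    }
    a[order(a$ph), ]
  })
  dplyr::bind_rows(out)
}

#' Export CSP curves as TSV
#'
#' @param x output of \code{\link{csp_table}} (or a single curve).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_csp_table <- function(x, path) {
  if (inherits(x, "titration_curve")) {
    x <- tibble::tibble(residue = attr(x, "residue"), ph = x$ph,
                        csp = x$csp, status = x$status)
  }
  names(x)[names(x) == "csp"] <- "CSP_Hz"
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
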