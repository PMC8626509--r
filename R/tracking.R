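# Default per-nucleus matching tolerances in ppm, of the order of typical
# HSQC linewidths.
DEFAULT_TRACK_TOL <- c(H1 = 0.05, N15 = 0.5, C13 = 0.3)

#' Track assigned peaks across a titration series
#'
#' Propagates the reference-point assignments to all other titration
#' points, pairwise between pH-adjacent spectra (matching a sequential
#' buffer-exchange acquisition). At each step a peak is matched to its
#' nearest neighbour in tolerance-scaled shift space, and only if that
#' neighbour lies within \code{tol} in \emph{every} dimension and the
#' second-nearest candidate is at least \code{margin} times farther.
#' Peaks with no admissible match are flagged \code{"lost"} from that point
#' outward; two peaks claiming the same candidate are both flagged
#' \code{"ambiguous"}.
#'
#' @param series a \code{\link{titration_series}} whose reference point is
#'   fully assigned.
#' @param tol named per-nucleus tolerances in ppm; defaults
#'   \code{c(H1 = 0.05, N15 = 0.5, C13 = 0.3)}.
#' @param margin second-nearest distance margin factor (default 1.5).
#' @return a \code{tracked_series}: the input series plus a
#'   \code{$tracking} tibble with one row per (label, point) holding the
#'   matched shifts and a status flag (\code{"ok"}, \code{"lost"},
#'   \code{"ambiguous"}).
#' @export
track_peaks <- function(series, tol = DEFAULT_TRACK_TOL, margin = 1.5) {
  stopifnot(inherits(series, "titration_series"))
  dims <- series$points[[1]]$meta$dims
  ndim <- length(dims)
  if (is.null(names(tol))) {
    stopifnot(length(tol) == ndim)
    tolv <- as.numeric(tol)
  } else {
    missing_tol <- setdiff(dims, names(tol))
    if (length(missing_tol) > 0) {
      stop("no tolerance for nucleus: ", paste(missing_tol, collapse = ", "))
    }
    tolv <- as.numeric(tol[dims])
  }
  stopifnot(all(tolv > 0), margin >= 1)

  np <- length(series$points)
  ref <- series$reference
  cols <- shift_cols(ndim)
  ref_peaks <- series$points[[ref]]$peaks
  if (nrow(ref_peaks) == 0) stop("reference point has no assigned peaks")
  labels <- ref_peaks$label
  if (anyDuplicated(labels)) stop("duplicate labels at reference point")
  nl <- length(labels)

  # pos[l, d, k]: shift of label l, dimension d, point k; NA when not tracked
  pos <- array(NA_real_, dim = c(nl, ndim, np))
  status <- matrix("lost", nl, np)
  pos[, , ref] <- as.matrix(ref_peaks[cols])
  status[, ref] <- "ok"

  step <- function(from, to) {
    known <- which(status[, from] == "ok")
    if (length(known) == 0) return(invisible(NULL))
    cand <- as.matrix(series$points[[to]]$peaks[cols])
    if (nrow(cand) == 0) return(invisible(NULL))
    claim <- rep(NA_integer_, length(known))
    for (i in seq_along(known)) {
      l <- known[i]
      p <- pos[l, , from]
      dd <- sweep(cand, 2, p, "-")
      within <- apply(abs(dd), 1, function(r) all(r <= tolv))
      ds <- sqrt(rowSums(sweep(dd, 2, tolv, "/")^2))
      o <- order(ds)
      best <- o[1]
      ok <- within[best]
      if (ok && length(ds) > 1) ok <- ds[o[2]] >= margin * ds[best]
      if (ok) claim[i] <- best
    }
    dup <- claim[!is.na(claim)][duplicated(claim[!is.na(claim)])]
    for (i in seq_along(known)) {
      l <- known[i]
      if (is.na(claim[i])) {
        status[l, to] <<- "lost"
      } else if (claim[i] %in% dup) {
        status[l, to] <<- "ambiguous"
      } else {
        status[l, to] <<- "ok"
        pos[l, , to] <<- cand[claim[i], ]
      }
    }
    invisible(NULL)
  }

  if (ref > 1) for (k in seq(ref, 2)) step(k, k - 1)
  if (ref < np) for (k in seq(ref, np - 1)) step(k, k + 1)

  ph <- series_ph(series)
  rows <- vector("list", np)
  for (k in seq_len(np)) {
    tb <- tibble::tibble(label = labels, point = k, ph = ph[k],
                         status = status[, k])
    for (d in seq_len(ndim)) tb[[cols[d]]] <- pos[, d, k]
    rows[[k]] <- tb
  }
  out <- series
  tracking <- dplyr::bind_rows(rows)
  out$tracking <- tracking[order(tracking$label, tracking$point), ]
  class(out) <- c("tracked_series", class(series))
  out
}

#' @export
print.tracked_series <- function(x, ...) {
  NextMethod()
  tr <- x$tracking
  n_ok <- sum(tr$status == "ok")
  cat(sprintf("  tracking: %d labels; %d/%d (label, point) pairs matched; %d lost; %d ambiguous\n",
              length(unique(tr$label)), n_ok, nrow(tr),
              sum(tr$status == "lost"), sum(tr$status == "ambiguous")))
  invisible(x)
}
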