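# Default pH grid spanning a realistic multi-buffer titration series
# (acetate / MES / phosphate / CHES coverage of pH 4.4-9.1).
DEFAULT_PH_GRID <- c(4.4, 4.7, 5.1, 5.4, 5.8, 6.1, 6.5, 6.8, 7.2, 7.5, 7.9, 9.1)

# typical base-position windows and titration displacements (ppm) per nucleus
SYNTH_BASE_RANGE <- list(H1 = c(6.5, 10), N15 = c(105, 130), C13 = c(175, 186))
SYNTH_DISP_RANGE <- list(H1 = c(0.05, 0.20), N15 = c(0.5, 2.0), C13 = c(1.0, 3.0))
SYNTH_NOISE_SD <- c(H1 = 0.005, N15 = 0.05, C13 = 0.02)

#' Specification of one synthetic titrating residue
#'
#' @param label assignment label.
#' @param true_pka ground-truth pKa.
#' @param base per-dimension base (fully deprotonated-limit) position in
#'   ppm, at the high-pH end.
#' @param direction per-dimension unit vector of the shift trajectory in
#'   ppm space (normalised internally).
#' @param amplitude total ppm displacement along \code{direction} over
#'   the full titration.
#' @param noise_sd per-dimension Gaussian noise SD in ppm.
#' @param second optional list \code{(pka, direction, amplitude)} adding
#'   a second titration event, producing a curved (biphasic) trajectory.
#' @return one-row tibble with list-columns.
#' @export
synthetic_residue_spec <- function(label, true_pka, base, direction,
                                   amplitude, noise_sd, second = NULL) {
  stopifnot(nzchar(label), amplitude >= 0, all(noise_sd >= 0),
            length(base) == length(direction),
            length(noise_sd) == length(base))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero")
  direction <- direction / nrm
  if (!is.null(second)) {
    stopifnot(is.list(second), length(second$direction) == length(base),
              second$amplitude >= 0)
    second$direction <- second$direction / sqrt(sum(second$direction^2))
  }
  tibble::tibble(label = label, true_pka = true_pka,
                 base = list(base), direction = list(direction),
                 amplitude = amplitude, noise_sd = list(noise_sd),
                 second = list(second))
}

#' Random residue specifications for benchmark series
#'
#' Draws \code{n} titrating residues with pKa uniform in
#' \code{pka_range}, base positions uniform in the standard spectral
#' window of each nucleus, and per-dimension displacements uniform in
#' the typical titration-shift range, with random sign.
#'
#' @param n number of residues.
#' @param dims nucleus identifiers of the spectrum dimensions.
#' @param pka_range range of true pKa values (default 4.8-7.2, inside
#'   the default pH grid).
#' @param noise_sd named per-nucleus noise SD in ppm (defaults
#'   \code{c(H1 = 0.005, N15 = 0.05, C13 = 0.02)}).
#' @param seed RNG seed.
#' @return tibble of specs (one row per residue).
#' @export
random_residue_specs <- function(n, dims = c("N15", "H1"),
                                 pka_range = c(4.8, 7.2),
                                 noise_sd = SYNTH_NOISE_SD, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- length(dims)
  nsd <- unname(noise_sd[dims])
  specs <- lapply(seq_len(n), function(i) {
    base <- vapply(dims, function(d) runif(1, SYNTH_BASE_RANGE[[d]][1],
                                           SYNTH_BASE_RANGE[[d]][2]), numeric(1))
    disp <- vapply(dims, function(d) runif(1, SYNTH_DISP_RANGE[[d]][1],
                                           SYNTH_DISP_RANGE[[d]][2]) *
                     sample(c(-1, 1), 1), numeric(1))
    amp <- sqrt(sum(disp^2))
    synthetic_residue_spec(
      label = sprintf("R%dN-H", i),
      true_pka = runif(1, pka_range[1], pka_range[2]),
      base = unname(base), direction = disp / amp, amplitude = amp,
      noise_sd = nsd)
  })
  dplyr::bind_rows(specs)
}

#' Generate a ground-truth synthetic titration series
#'
#' Emulates a pH titration acquisition: each residue's peak moves along a
#' fixed direction in ppm space with amplitude following a single-site
#' titration curve (plus an optional second event for biphasic stress
#' cases), plus per-point Gaussian noise:
#' \deqn{w(x) = base + dir \cdot amp \cdot g(x, pK_a) + noise,\quad
#'       g(x, pK_a) = 1 - \frac{1}{1 + 10^{x - pK_a}}.}
#' Deterministic under a fixed seed.
#'
#' @param specs spec tibble (\code{\link{synthetic_residue_spec}} /
#'   \code{\link{random_residue_specs}}).
#' @param ph_grid strictly increasing pH values, >= 4 points.
#' @param field_h1 spectrometer 1H frequency in MHz.
#' @param dims nucleus identifiers (must match the specs' dimensions).
#' @param experiment experiment tag for the metadata.
#' @param seed RNG seed.
#' @param dropout optional data frame (\code{label}, \code{min_ph}):
#'   those peaks are absent below \code{min_ph}, emulating resonances
#'   that cannot be tracked at low pH.
#' @param assigned if FALSE, non-reference points carry anonymous labels
#'   in shuffled order (as from an un-propagated peak picker), leaving
#'   assignment to \code{\link{track_peaks}}.
#' @return list: \code{series} (a \code{\link{titration_series}}),
#'   \code{truth} (label, true pKa, amplitude, per-dimension
#'   displacement), \code{positions} (noise-free positions per point).
#' @export
generate_series <- function(specs, ph_grid = DEFAULT_PH_GRID, field_h1 = 600,
                            dims = c("N15", "H1"), experiment = "HSQC",
                            seed = NULL, dropout = NULL, assigned = TRUE) {
  stopifnot(!is.unsorted(ph_grid, strictly = TRUE), length(ph_grid) >= 4)
  nd <- length(dims)
  stopifnot(all(lengths(specs$base) == nd))
  if (!is.null(seed)) set.seed(seed)
  nres <- nrow(specs)

  base_m <- do.call(rbind, specs$base)
  noise_m <- do.call(rbind, specs$noise_sd)
  # overlap warning: base positions closer than 3x noise in every dimension
  if (nres > 1) {
    for (i in seq_len(nres - 1)) for (j in seq(i + 1, nres)) {
      sep <- abs(base_m[i, ] - base_m[j, ])
      lim <- 3 * pmax(noise_m[i, ], noise_m[j, ])
      if (all(sep < pmax(lim, 1e-12))) {
        warning(sprintf("base positions of %s and %s overlap within 3x noise",
                        specs$label[i], specs$label[j]))
      }
    }
  }

  true_pos <- function(i, x) {
    sp <- specs[i, ]
    p <- sp$base[[1]] + sp$direction[[1]] * sp$amplitude * hh_g(x, sp$true_pka)
    sec <- sp$second[[1]]
    if (!is.null(sec)) p <- p + sec$direction * sec$amplitude * hh_g(x, sec$pka)
    p
  }

  np <- length(ph_grid)
  ref_idx <- np
  points <- vector("list", np)
  pos_rows <- list()
  for (k in seq_len(np)) {
    x <- ph_grid[k]
    keep <- rep(TRUE, nres)
    if (!is.null(dropout)) {
      di <- match(specs$label, dropout$label)
      keep <- is.na(di) | x >= dropout$min_ph[di]
    }
    lab <- specs$label
    w <- matrix(NA_real_, nres, nd)
    for (i in seq_len(nres)) {
      tp <- true_pos(i, x)
      w[i, ] <- tp + rnorm(nd, 0, specs$noise_sd[[i]])
      pos_rows[[length(pos_rows) + 1]] <-
        tibble::tibble(label = lab[i], ph = x,
                       dim = seq_len(nd), true_ppm = tp, observed = keep[i])
    }
    pk <- tibble::tibble(label = lab)
    for (d in seq_len(nd)) pk[[paste0("w", d)]] <- w[, d]
    pk$height <- NA_real_
    pk <- pk[keep, , drop = FALSE]
    if (!assigned && k != ref_idx && nrow(pk) > 0) {
      pk <- pk[sample(nrow(pk)), , drop = FALSE]
      pk$label <- sprintf("?%d-?", seq_len(nrow(pk)))
    }
    meta <- spectrum_meta(ph = x, field_h1 = field_h1, dims = dims,
                          experiment = experiment)
    points[[k]] <- list(meta = meta, peaks = pk)
  }

  disp <- do.call(rbind, lapply(seq_len(nres), function(i)
    specs$direction[[i]] * specs$amplitude[i]))
  truth <- tibble::tibble(label = specs$label, true_pka = specs$true_pka,
                          amplitude = specs$amplitude)
  for (d in seq_len(nd)) truth[[paste0("disp_", dims[d])]] <- disp[, d]
  truth$biphasic <- !vapply(specs$second, is.null, logical(1))

  list(series = titration_series(points, reference = ref_idx),
       truth = truth,
       positions = dplyr::bind_rows(pos_rows))
}

#' Write a generated series to disk
#'
#' Emits one Sparky-dialect peak list per titration point, a YAML
#' manifest readable by \code{\link{read_series}}, and the ground-truth
#' table as TSV. Byte-identical output under a fixed generator seed.
#'
#' @param gen output of \code{\link{generate_series}}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_series <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- gen$series
  entries <- list()
  for (k in seq_along(series$points)) {
    p <- series$points[[k]]
    fname <- sprintf("ph%04.1f.list", p$meta$ph)
    write_peaklist(p$peaks, p$meta, file.path(dir, fname))
    entries[[k]] <- list(file = fname, ph = p$meta$ph,
                         field_h1 = p$meta$field_h1,
                         dims = as.list(p$meta$dims),
                         experiment = p$meta$experiment)
  }
  man <- list(points = entries, reference = series$reference)
  man_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, man_path)
  utils::write.table(gen$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(man_path)
}
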