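# Protonated variant names of the standard titratable residues, as used
# by PDB2PQR-style force-field naming.
PROTONATED_VARIANT <- c(ASP = "ASH", GLU = "GLH", HIS = "HIP")

#' Read a PQR coordinate file
#'
#' Parses the whitespace-separated PQR dialect (PDB2PQR output): ATOM /
#' HETATM records with atom serial, atom name, residue name, chain,
#' residue number, x/y/z coordinates in Angstrom, per-atom charge in
#' elementary units and radius in Angstrom. Non-atom records (REMARK,
#' TER, END) are skipped.
#'
#' @param path PQR file path.
#' @return tibble with columns \code{record}, \code{serial}, \code{name},
#'   \code{resname}, \code{chain}, \code{resnum}, \code{x}, \code{y},
#'   \code{z}, \code{charge}, \code{radius}.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("PQR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)\\b", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no ATOM records in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(toks)
  if (any(nf != 11)) {
    i <- which(nf != 11)[1]
    stop(sprintf("malformed PQR line %d in %s: expected 11 fields, got %d",
                 lineno[i], path, nf[i]))
  }
  m <- do.call(rbind, toks)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric %s on PQR line %d in %s",
                   what, lineno[which(is.na(v))[1]], path))
    }
    v
  }
  atoms <- tibble::tibble(
    record = m[, 1], serial = as.integer(num(2, "serial")), name = m[, 3],
    resname = m[, 4], chain = m[, 5], resnum = as.integer(num(6, "residue number")),
    x = num(7, "x"), y = num(8, "y"), z = num(9, "z"),
    charge = num(10, "charge"), radius = num(11, "radius"))
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  atoms
}

#' Write a PQR coordinate file
#'
#' Emits the whitespace-separated dialect \code{\link{read_pqr}} accepts.
#' Coordinates are printed with 3 decimals, charges and radii with 4
#' (PDB2PQR convention).
#'
#' @param atoms PQR atom tibble.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pqr <- function(atoms, path) {
  lines <- sprintf("%-6s %4d %-4s %-4s %s %4d %11.3f %11.3f %11.3f %8.4f %7.4f",
                   atoms$record, atoms$serial, atoms$name, atoms$resname,
                   atoms$chain, atoms$resnum, atoms$x, atoms$y, atoms$z,
                   atoms$charge, atoms$radius)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

pqr_res_key <- function(atoms) paste(atoms$chain, atoms$resnum)

#' Splice protonated residue templates into a PQR structure
#'
#' Replaces the atom records of selected residues with the corresponding
#' records of a donor structure carrying the protonated variants
#' (ASH/GLH/HIP), including their extra protons, names, charges and
#' coordinates. All other atoms are untouched; serials are renumbered
#' consecutively. Donor coordinates are trusted as-is (no proton
#' geometry building); frames are assumed identical, verified by
#' requiring the heavy-atom RMSD between donor and target residue to be
#' below 0.1 Angstrom (warning otherwise).
#'
#' @param target PQR atom tibble to edit.
#' @param donor PQR atom tibble providing protonated residues.
#' @param residues data frame with columns \code{chain}, \code{number},
#'   \code{new_name} listing residues to replace.
#' @return edited atom tibble; \code{attr(, "splice_manifest")} records,
#'   per residue, the old/new residue names and the charge difference,
#'   and \code{attr(, "net_charge_change")} their sum.
#' @export
splice_protonated <- function(target, donor, residues) {
  stopifnot(is.data.frame(residues),
            all(c("chain", "number", "new_name") %in% names(residues)))
  out_blocks <- list()
  manifest <- list()
  if (nrow(residues) > 0) {
    for (i in seq_len(nrow(residues))) {
      ch <- residues$chain[i]; no <- residues$number[i]
      nm <- residues$new_name[i]
      tgt <- target[target$chain == ch & target$resnum == no, , drop = FALSE]
      don <- donor[donor$chain == ch & donor$resnum == no, , drop = FALSE]
      if (nrow(tgt) == 0) stop(sprintf("residue %s %d absent from target", ch, no))
      if (nrow(don) == 0) stop(sprintf("residue %s %d absent from donor", ch, no))
      if (!all(don$resname == nm)) {
        stop(sprintf("donor residue %s %d is %s, expected %s",
                     ch, no, don$resname[1], nm))
      }
      base_of <- function(x) sub("^(ASH)$", "ASP", sub("^(GLH)$", "GLU",
                                 sub("^(HIP|HID|HIE)$", "HIS", x)))
      if (base_of(don$resname[1]) != base_of(tgt$resname[1])) {
        stop(sprintf("residue-type mismatch at %s %d: target %s vs donor %s",
                     ch, no, tgt$resname[1], don$resname[1]))
      }
      heavy <- intersect(tgt$name[!grepl("^H", tgt$name)],
                         don$name[!grepl("^H", don$name)])
      if (length(heavy) > 0) {
        a <- as.matrix(tgt[match(heavy, tgt$name), c("x", "y", "z")])
        b <- as.matrix(don[match(heavy, don$name), c("x", "y", "z")])
        rmsd <- sqrt(mean(rowSums((a - b)^2)))
        if (rmsd > 0.1) {
          warning(sprintf("heavy-atom RMSD %.2f A between target and donor at %s %d: frames may differ",
                          rmsd, ch, no))
        }
      }
      manifest[[i]] <- tibble::tibble(
        chain = ch, number = no, old_name = tgt$resname[1], new_name = nm,
        old_charge = sum(tgt$charge), new_charge = sum(don$charge),
        charge_change = sum(don$charge) - sum(tgt$charge))
    }
  }
  manifest <- if (length(manifest)) dplyr::bind_rows(manifest) else
    tibble::tibble(chain = character(), number = integer(),
                   old_name = character(), new_name = character(),
                   old_charge = numeric(), new_charge = numeric(),
                   charge_change = numeric())

  spliced_keys <- paste(residues$chain, residues$number)
  out <- list()
  for (key in unique(pqr_res_key(target))) {
    if (key %in% spliced_keys) {
      i <- match(key, spliced_keys)
      out[[key]] <- donor[donor$chain == residues$chain[i] &
                            donor$resnum == residues$number[i], , drop = FALSE]
    } else {
      out[[key]] <- target[pqr_res_key(target) == key, , drop = FALSE]
    }
  }
  res <- dplyr::bind_rows(out)
  res$serial <- seq_len(nrow(res))
  attr(res, "splice_manifest") <- manifest
  attr(res, "net_charge_change") <- sum(manifest$charge_change)
  res
}

#' Protonate a PQR structure according to measured pKa values
#'
#' Splices the protonated template of every residue whose dominant state
#' at the requested pH is protonated (per \code{\link{dominant_states}}
#' on the supplied pKa records), plus any explicit overrides. Acids
#' become ASH/GLH (neutralised), His becomes HIP (positive).
#'
#' @param target PQR atom tibble.
#' @param donor PQR atom tibble with protonated variants.
#' @param records pKa record tibble carrying \code{best_estimate} (see
#'   \code{\link{best_estimate}}).
#' @param ph the pH at which to assign states.
#' @param overrides named character vector of forced states, e.g.
#'   \code{c("H2B H106" = "protonated")}.
#' @param chain_map named vector mapping record chains to PQR chain ids,
#'   e.g. \code{c(H2A = "A", H2B = "B")}; by default record chain names
#'   are used verbatim.
#' @return edited atom tibble with the splice manifest attributes of
#'   \code{\link{splice_protonated}}.
#' @export
protonate_for_ph <- function(target, donor, records, ph, overrides = NULL,
                             chain_map = NULL) {
  st <- suppressWarnings(dominant_states(records, ph, overrides = overrides))
  prot <- st$residue[st$state == "protonated"]
  idx <- match(prot, records$residue)
  types <- records$type[idx]
  if (any(!types %in% names(PROTONATED_VARIANT))) {
    stop("no protonated template variant for type: ",
         paste(setdiff(types, names(PROTONATED_VARIANT)), collapse = ", "))
  }
  chains <- records$chain[idx]
  if (!is.null(chain_map)) chains <- unname(chain_map[chains])
  residues <- tibble::tibble(chain = chains, number = records$number[idx],
                             new_name = unname(PROTONATED_VARIANT[types]))
  splice_protonated(target, donor, residues)
}
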