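RESIDUE_ONE_LETTER <- c(ASP = "D", GLU = "E", HIS = "H", LYS = "K")
ACID_TYPES <- c("ASP", "GLU")
BASE_TYPES <- c("HIS", "LYS")

residue_id <- function(chain, type, number) {
  paste0(chain, " ", RESIDUE_ONE_LETTER[type], number)
}

#' Fraction of a titratable group carrying its proton at a given pH
#'
#' Henderson-Hasselbalch equilibrium fraction of the acid (protonated)
#' species, \eqn{f = 1/(1 + 10^{pH - pK_a})}, for any group whose pKa
#' refers to loss of that proton. At \code{ph == pka} the fraction is
#' exactly 0.5; it decreases strictly with pH.
#'
#' @param pka pKa value(s).
#' @param ph pH value(s).
#' @return protonated fraction in [0, 1]; vectorised over both arguments.
#' @examples
#' fraction_protonated(6.52, 7.4)  # ~0.12: a His ~12% protonated
#' @export
fraction_protonated <- function(pka, ph) {
  1 / (1 + 10^(ph - pka))
}

#' Mean charge of a titratable residue at a given pH
#'
#' Acids (Asp/Glu) are neutral when protonated and -1 when deprotonated:
#' charge \eqn{-(1 - f)}. His and Lys gain a positive charge when
#' protonated: charge \eqn{+f}. Here \eqn{f} is
#' \code{\link{fraction_protonated}}.
#'
#' @param type residue type, one of \code{"ASP"}, \code{"GLU"},
#'   \code{"HIS"}, \code{"LYS"} (vectorised).
#' @param pka pKa value(s).
#' @param ph pH value(s).
#' @return mean charge in elementary units.
#' @examples
#' residue_charge("HIS", 6.52, 6)   # +0.77
#' residue_charge("ASP", 5.3, 7.4)  # ~ -0.99
#' @export
residue_charge <- function(type, pka, ph) {
  bad <- setdiff(unique(type), c(ACID_TYPES, BASE_TYPES))
  if (length(bad) > 0) stop("unsupported residue type: ", paste(bad, collapse = ", "))
  f <- fraction_protonated(pka, ph)
  ifelse(type %in% ACID_TYPES, -(1 - f), +f)
}

#' Load the packaged H2A-H2B acidic-patch pKa ledger
#'
#' A per-residue ledger of pKa evidence for the titratable groups in and
#' around the nucleosome acidic patch of the Drosophila melanogaster
#' H2A-H2B dimer: structure-based predictions (dimer and nucleosome
#' context), side-chain titration values, and backbone-amide apparent
#' pKa values of reporter residues. Side chains whose titrations only
#' bound the pKa from above (transition not reached within the sampled
#' pH range) carry the bound in \code{sidechain_bound} with
#' \code{sidechain_pka = NA}.
#'
#' @return list with two tibbles: \code{residues} (one row per titratable
#'   residue) and \code{backbone} (one row per backbone reporter, with
#'   \code{relation} either \code{"hb"} for a hydrogen bond to the
#'   titratable group or \code{"proximity"}).
#' @export
h2a_h2b_pka <- function() {
  res <- read_pka_table(system.file("extdata", "h2a_h2b_pka.tsv",
                                    package = "pkafit", mustWork = TRUE))
  bb <- tibble::as_tibble(utils::read.delim(
    system.file("extdata", "h2a_h2b_backbone.tsv", package = "pkafit",
                mustWork = TRUE)))
  list(residues = res, backbone = bb)
}

#' Read a per-residue pKa table
#'
#' TSV with columns \code{chain}, \code{number}, \code{type},
#' \code{acidic_patch}, \code{predicted_dimer}, \code{predicted_nucleosome},
#' \code{sidechain_pka}, \code{sidechain_bound} (optional further columns
#' are kept). Adds a \code{residue} display id.
#'
#' @param path TSV path.
#' @return tibble of residue records.
#' @export
read_pka_table <- function(path) {
  res <- tibble::as_tibble(utils::read.delim(path))
  need <- c("chain", "number", "type")
  missing_cols <- setdiff(need, names(res))
  if (length(missing_cols) > 0) {
    stop("pKa table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  res$residue <- residue_id(res$chain, res$type, res$number)
  res
}

#' Best-estimate pKa aggregation
#'
#' Aggregates the evidence for each residue into one best-estimate pKa,
#' in decreasing order of directness:
#' \enumerate{
#'   \item a measured side-chain pKa, when available;
#'   \item otherwise the unweighted mean of backbone-amide apparent pKa
#'     values from reporters hydrogen-bonded to the titratable group;
#'   \item otherwise a side-chain upper bound, reported with qualifier
#'     \code{"<"};
#'   \item otherwise the structure-based prediction, under one of two
#'     policies: \code{"mean"} (mean of dimer and nucleosome-context
#'     predictions) or \code{"dimer"} (dimer value only).
#' }
#' Proximity-only backbone reporters are never aggregated: their apparent
#' pKa reflects a nearby group, not the residue's own side chain.
#'
#' @param records residue tibble (see \code{\link{read_pka_table}}).
#' @param backbone backbone-reporter tibble with columns \code{chain},
#'   \code{number}, \code{reporter}, \code{pka_app}, \code{relation}.
#' @param policy prediction fallback policy, \code{"mean"} or
#'   \code{"dimer"}.
#' @return \code{records} with columns \code{best_estimate} (full
#'   precision), \code{best_qualifier} (\code{""} or \code{"<"}),
#'   \code{best_source} and \code{best_display} (1 decimal,
#'   half-up, qualifier prepended).
#' @export
best_estimate <- function(records, backbone = NULL,
                          policy = c("mean", "dimer")) {
  policy <- match.arg(policy)
  n <- nrow(records)
  if (n == 0) stop("empty record table")
  value <- rep(NA_real_, n)
  qual <- rep("", n)
  src <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    bb <- if (is.null(backbone)) NULL else
      backbone[backbone$chain == r$chain & backbone$number == r$number &
                 backbone$relation == "hb", , drop = FALSE]
    if (!is.null(r$sidechain_pka) && is.finite(r$sidechain_pka)) {
      value[i] <- r$sidechain_pka; src[i] <- "sidechain"
    } else if (!is.null(bb) && nrow(bb) > 0) {
      value[i] <- mean(bb$pka_app); src[i] <- "backbone"
    } else if (!is.null(r$sidechain_bound) && is.finite(r$sidechain_bound)) {
      value[i] <- r$sidechain_bound; qual[i] <- "<"; src[i] <- "sidechain_bound"
    } else if (is.finite(r$predicted_dimer)) {
      value[i] <- switch(policy,
                         mean = mean(c(r$predicted_dimer, r$predicted_nucleosome),
                                     na.rm = TRUE),
                         dimer = r$predicted_dimer)
      src[i] <- paste0("predicted_", policy)
    } else {
      stop("no pKa evidence for residue ", r$residue)
    }
  }
  records$best_estimate <- value
  records$best_qualifier <- qual
  records$best_source <- src
  records$best_display <- paste0(
    qual,
    ifelse(qual == "<",
           vapply(value, function(v) format(v, trim = TRUE), character(1)),
           sprintf("%.1f", round_half_up(value, 1))))
  records
}

#' Dominant protonation state of each residue at a given pH
#'
#' A residue is \code{"protonated"} when its protonated fraction exceeds
#' one half, i.e. when \code{ph < best_estimate}; a tie
#' (\code{ph == pka}) is reported as \code{"deprotonated"} with a
#' warning. Explicit overrides force the state of selected residues, as
#' used when rendering alternative protonation scenarios.
#'
#' @param records output of \code{\link{best_estimate}} (must carry
#'   \code{best_estimate}).
#' @param ph the pH.
#' @param overrides named character vector mapping residue ids (e.g.
#'   \code{"H2B H106"}) to \code{"protonated"} / \code{"deprotonated"}.
#' @return tibble: \code{residue}, \code{type}, \code{pka}, \code{state},
#'   \code{overridden}.
#' @export
dominant_states <- function(records, ph, overrides = NULL) {
  stopifnot("best_estimate" %in% names(records))
  pka <- records$best_estimate
  tie <- which(pka == ph)
  if (length(tie) > 0) {
    warning("pH equals pKa for ", paste(records$residue[tie], collapse = ", "),
            "; reporting deprotonated")
  }
  uncertain <- records$best_qualifier == "<" & ph < pka
  if (any(uncertain)) {
    warning("only an upper pKa bound is known for ",
            paste(records$residue[uncertain], collapse = ", "),
            " and pH is below it; state is uncertain")
  }
  state <- ifelse(ph < pka, "protonated", "deprotonated")
  overridden <- rep(FALSE, nrow(records))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), records$residue)
    if (length(unknown) > 0) stop("override for unknown residue: ",
                                  paste(unknown, collapse = ", "))
    idx <- match(names(overrides), records$residue)
    state[idx] <- unname(overrides)
    overridden[idx] <- TRUE
  }
  tibble::tibble(residue = records$residue, type = records$type,
                 pka = pka, state = state, overridden = overridden)
}

#' Protonation report at a given pH
#'
#' Per-residue protonated fraction, mean charge and dominant state.
#' Percentages use half-up rounding, matching how titration fractions
#' are conventionally quoted.
#'
#' @param records output of \code{\link{best_estimate}}.
#' @param ph the pH (scalar).
#' @return tibble: \code{residue}, \code{type}, \code{pka}, \code{ph},
#'   \code{fraction}, \code{percent}, \code{charge}, \code{state}.
#' @export
protonation_report <- function(records, ph) {
  stopifnot("best_estimate" %in% names(records), length(ph) == 1)
  f <- fraction_protonated(records$best_estimate, ph)
  st <- suppressWarnings(dominant_states(records, ph))
  tibble::tibble(
    residue = records$residue, type = records$type,
    pka = records$best_estimate, ph = ph, fraction = f,
    percent = round_half_up(100 * f),
    charge = residue_charge(records$type, records$best_estimate, ph),
    state = st$state)
}
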