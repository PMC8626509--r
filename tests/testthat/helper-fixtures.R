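# shared fixtures built in code

STD_GRID <- c(4.4, 4.7, 5.1, 5.4, 5.8, 6.1, 6.5, 6.8, 7.2, 7.5, 7.9, 9.1)

std_meta <- function(ph, dims = c("N15", "H1"), field = 600) {
  spectrum_meta(ph = ph, field_h1 = field, dims = dims)
}

# noise-free low-pH-referenced curve (rising with pH)
model_curve <- function(pka = 6.5, a = 10, b = 200, ph = STD_GRID) {
  titration_curve(ph, hh_model(ph, pka, a, b))
}

# noisy curve around a model; clamped at 0 (CSPs are magnitudes)
noisy_curve <- function(pka = 6.0, a = 40, b = 150, noise = 4,
                        ph = STD_GRID) {
  titration_curve(ph, pmax(hh_model(ph, pka, a, b) + rnorm(length(ph), 0, noise), 0))
}

# small well-separated series for tracking tests: peaks on a coarse grid,
# displacements far below the inter-peak spacing
separated_specs <- function(n = 6, noise = 0, amp_n15 = 0.8, amp_h1 = 0.08) {
  specs <- lapply(seq_len(n), function(i) {
    synthetic_residue_spec(
      label = sprintf("T%dN-H", i),
      true_pka = 5 + 0.3 * i,
      base = c(108 + 4 * i, 7 + 0.5 * i),
      direction = c(amp_n15, amp_h1),
      amplitude = sqrt(amp_n15^2 + amp_h1^2),
      noise_sd = c(noise * 10, noise))
  })
  dplyr::bind_rows(specs)
}

ledger_best <- function(policy = "mean") {
  led <- h2a_h2b_pka()
  best_estimate(led$residues, led$backbone, policy = policy)
}

# plain data frame of atom records, without the splice bookkeeping attrs
strip_pqr <- function(x) {
  out <- as.data.frame(x)
  attr(out, "splice_manifest") <- NULL
  attr(out, "net_charge_change") <- NULL
  rownames(out) <- NULL
  out
}

pqr_fixture <- function(which = c("target", "donor")) {
  which <- match.arg(which)
  f <- if (which == "target") "synthetic_dimer.pqr" else "synthetic_dimer_protonated.pqr"
  read_pqr(system.file("extdata", f, package = "pkafit", mustWork = TRUE))
}
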