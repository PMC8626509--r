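test_that("PQR files round-trip losslessly through read/write", {
  tgt <- pqr_fixture("target")
  expect_equal(nrow(tgt), 48)
  f <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(tgt, f)
  back <- read_pqr(f)
  expect_equal(back, tgt)
  # charge column is signed decimal
  expect_lt(min(tgt$charge), 0)
  expect_gt(max(tgt$charge), 0)
})

test_that("malformed and empty PQR input is rejected with line numbers", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c("REMARK x", "ATOM 1 N ASP A 89 1.0 2.0 3.0 -0.3"), f)  # 10 fields
  expect_error(read_pqr(f), "line 2")
  writeLines(c("REMARK only", "TER", "END"), f)
  expect_error(read_pqr(f), "no ATOM")
  writeLines("ATOM 1 N ASP A 89 1.0 2.0 xx -0.3 1.5", f)
  expect_error(read_pqr(f), "non-numeric")
})

test_that("splicing HIP over HIS adds the ring proton and +1 charge", {
  tgt <- pqr_fixture("target")
  don <- pqr_fixture("donor")
  out <- splice_protonated(tgt, don,
                           data.frame(chain = "B", number = 106, new_name = "HIP"))
  man <- attr(out, "splice_manifest")
  expect_equal(man$charge_change, 1, tolerance = 1e-9)
  expect_equal(attr(out, "net_charge_change"), 1, tolerance = 1e-9)
  h106 <- out[out$chain == "B" & out$resnum == 106, ]
  expect_true("HD1" %in% h106$name)
  expect_true(all(h106$resname == "HIP"))
  expect_equal(nrow(h106), nrow(tgt[tgt$chain == "B" & tgt$resnum == 106, ]) + 1)
  # serials renumbered consecutively
  expect_equal(out$serial, seq_len(nrow(out)))
  # all non-spliced atoms bit-identical
  keep_cols <- c("name", "resname", "chain", "resnum", "x", "y", "z", "charge", "radius")
  untouched_before <- strip_pqr(tgt[!(tgt$chain == "B" & tgt$resnum == 106), keep_cols])
  untouched_after <- strip_pqr(out[!(out$chain == "B" & out$resnum == 106), keep_cols])
  expect_identical(untouched_before, untouched_after)
})

test_that("splice handles empty lists, missing residues and type mismatches", {
  tgt <- pqr_fixture("target")
  don <- pqr_fixture("donor")
  out <- splice_protonated(tgt, don, data.frame(chain = character(),
                                                number = integer(),
                                                new_name = character()))
  expect_equal(strip_pqr(out[names(tgt)]), strip_pqr(tgt))
  expect_error(splice_protonated(tgt, don,
                                 data.frame(chain = "A", number = 999, new_name = "ASH")),
               "absent from target")
  expect_error(splice_protonated(tgt, don,
                                 data.frame(chain = "A", number = 89, new_name = "GLH")),
               "is ASH, expected GLH")
})

test_that("net charge change equals the sum over spliced residues", {
  tgt <- pqr_fixture("target")
  don <- pqr_fixture("donor")
  res <- data.frame(chain = c("A", "A", "B"), number = c(89, 91, 106),
                    new_name = c("ASH", "GLH", "HIP"))
  out <- splice_protonated(tgt, don, res)
  man <- attr(out, "splice_manifest")
  per_res <- vapply(seq_len(nrow(res)), function(i) {
    d <- don[don$chain == res$chain[i] & don$resnum == res$number[i], ]
    t <- tgt[tgt$chain == res$chain[i] & tgt$resnum == res$number[i], ]
    sum(d$charge) - sum(t$charge)
  }, numeric(1))
  expect_equal(man$charge_change, per_res)
  expect_equal(attr(out, "net_charge_change"),
               sum(out$charge) - sum(tgt$charge), tolerance = 1e-9)
})

test_that("protonate_for_ph reproduces the three protonation scenarios", {
  tgt <- pqr_fixture("target")
  don <- pqr_fixture("donor")
  rec <- ledger_best("mean")
  rec <- rec[paste(rec$chain, rec$number) %in%
               c("H2A 89", "H2A 91", "H2B 46", "H2B 102", "H2B 106"), ]
  cmap <- c(H2A = "A", H2B = "B")
  # physiological pH: every residue dominant-deprotonated, nothing spliced
  out_a <- protonate_for_ph(tgt, don, rec, ph = 7.4, chain_map = cmap)
  expect_equal(nrow(attr(out_a, "splice_manifest")), 0)
  expect_equal(strip_pqr(out_a[names(tgt)]), strip_pqr(tgt))
  # single override: protonated H106 only
  out_b <- protonate_for_ph(tgt, don, rec, ph = 7.4,
                            overrides = c("H2B H106" = "protonated"),
                            chain_map = cmap)
  expect_equal(nrow(attr(out_b, "splice_manifest")), 1)
  expect_equal(attr(out_b, "net_charge_change"), 1, tolerance = 1e-9)
  # slightly acidic scenario: H106 protonated by pKa, H46 + D89 forced
  out_c <- protonate_for_ph(tgt, don, rec, ph = 6.0,
                            overrides = c("H2B H46" = "protonated",
                                          "H2A D89" = "protonated"),
                            chain_map = cmap)
  man_c <- attr(out_c, "splice_manifest")
  expect_equal(nrow(man_c), 3)
  expect_equal(attr(out_c, "net_charge_change"), 3, tolerance = 1e-9)
})

test_that("protonation editing is idempotent at a fixed pH", {
  tgt <- pqr_fixture("target")
  don <- pqr_fixture("donor")
  rec <- ledger_best("mean")
  rec <- rec[paste(rec$chain, rec$number) %in%
               c("H2A 89", "H2A 91", "H2B 46", "H2B 102", "H2B 106"), ]
  cmap <- c(H2A = "A", H2B = "B")
  once <- protonate_for_ph(tgt, don, rec, ph = 6.0, chain_map = cmap)
  twice <- protonate_for_ph(once, don, rec, ph = 6.0, chain_map = cmap)
  expect_equal(strip_pqr(twice), strip_pqr(once))
  expect_equal(attr(twice, "net_charge_change"), 0, tolerance = 1e-9)
})
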