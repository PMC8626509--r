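test_that("fraction_protonated has the closed-form midpoint and unit offsets", {
  expect_equal(fraction_protonated(6.5, 6.5), 0.5)
  expect_equal(fraction_protonated(6.5, 5.5), 10 / 11)
  expect_equal(fraction_protonated(6.5, 7.5), 1 / 11)
  ph <- seq(2, 12, by = 0.25)
  expect_true(all(diff(fraction_protonated(6, ph)) < 0))  # strictly decreasing
  f <- fraction_protonated(runif(20, 3, 9), runif(20, 3, 9))
  expect_true(all(f > 0 & f < 1))
})

test_that("measured His pKa values give the published protonation percentages", {
  expect_equal(round_half_up(100 * fraction_protonated(6.52, 7.4)), 12)
  expect_equal(round_half_up(100 * fraction_protonated(5.86, 7.4)), 3)
  expect_equal(round_half_up(100 * fraction_protonated(6.52, 6.0)), 77)
  expect_equal(round_half_up(100 * fraction_protonated(5.86, 6.0)), 42)
})

test_that("residue charges follow acid/base protonation semantics", {
  expect_equal(residue_charge("HIS", 6.52, 6), 0.77, tolerance = 0.005)
  expect_equal(residue_charge("GLU", 20, 7), 0, tolerance = 1e-10)   # fully protonated acid
  expect_equal(residue_charge("ASP", 5.265, 100), -1, tolerance = 1e-10)
  expect_equal(residue_charge("LYS", 10.5, 7.4), fraction_protonated(10.5, 7.4))
  expect_error(residue_charge("ARG", 12, 7), "unsupported")
  # ranges: acids in [-1, 0], bases in [0, 1]
  ph <- seq(0, 14, by = 0.5)
  expect_true(all(residue_charge("GLU", 4.5, ph) <= 0 &
                    residue_charge("GLU", 4.5, ph) >= -1))
  expect_true(all(residue_charge("HIS", 6.5, ph) >= 0 &
                    residue_charge("HIS", 6.5, ph) <= 1))
})

test_that("best-estimate aggregation prefers side chain, then H-bond backbone, then bounds, then predictions", {
  rec <- ledger_best("mean")
  get <- function(r, col) rec[[col]][rec$residue == r]
  # direct backbone average for D89: (5.51 + 5.02)/2 = 5.265 -> 5.3
  expect_equal(get("H2A D89", "best_estimate"), 5.265)
  expect_equal(get("H2A D89", "best_display"), "5.3")
  # measured side chain wins over proximity reporters
  expect_equal(get("H2B H46", "best_estimate"), 5.86)
  expect_equal(get("H2B H46", "best_display"), "5.9")
  # censored side-chain bound does not pre-empt an H-bond backbone estimate
  expect_equal(get("H2A E55", "best_display"), "4.3")
  expect_equal(get("H2A E55", "best_source"), "backbone")
  # prediction fallback
  expect_equal(get("H2B E102", "best_estimate"), mean(c(3.79, 3.59)))
  expect_error(best_estimate(rec[0, ]), "empty")
})

test_that("the full ledger reproduces every published best estimate under the mean policy", {
  rec <- ledger_best("mean")
  expected <- c("H2A E55" = "4.3", "H2A E60" = "<5", "H2A E63" = "<5",
                "H2A D89" = "5.3", "H2A E90" = "<5", "H2A E91" = "4.4",
                "H2B H46" = "5.9", "H2B E102" = "3.7", "H2B H106" = "6.5",
                "H2B E110" = "4.0")
  expect_equal(setNames(rec$best_display, rec$residue), expected)
  # the dimer-only policy is exposed and differs where only predictions exist
  rec_d <- ledger_best("dimer")
  expect_equal(rec_d$best_estimate[rec_d$residue == "H2B E102"], 3.79)
})

test_that("dominant states flip at pKa with ties reported deprotonated", {
  rec <- ledger_best("mean")
  st <- dominant_states(rec, 7.4)
  expect_equal(st$state[st$residue == "H2B H106"], "deprotonated")
  expect_true(all(st$state[st$residue %in% c("H2A D89", "H2B H46")] == "deprotonated"))
  st6 <- dominant_states(rec, 6.0)
  expect_equal(st6$state[st6$residue == "H2B H106"], "protonated")
  expect_equal(st6$state[st6$residue == "H2B H46"], "deprotonated")  # 5.86 < 6
  # tie rule
  one <- rec[rec$residue == "H2B H106", ]
  expect_warning(tie <- dominant_states(one, one$best_estimate), "pH equals pKa")
  expect_equal(tie$state, "deprotonated")
  # overrides
  ov <- dominant_states(rec, 6.0, overrides = c("H2B H46" = "protonated",
                                                "H2A D89" = "protonated"))
  expect_true(all(ov$state[ov$residue %in% c("H2B H46", "H2A D89")] == "protonated"))
  expect_true(all(ov$overridden[ov$residue %in% c("H2B H46", "H2A D89")]))
  expect_error(dominant_states(rec, 6, overrides = c("H2B H999" = "protonated")),
               "unknown residue")
})

test_that("protonation_report combines fractions, charges and states", {
  rec <- ledger_best("mean")
  rep6 <- protonation_report(rec, 6.0)
  expect_equal(rep6$percent[rep6$residue == "H2B H106"], 77)
  expect_equal(rep6$percent[rep6$residue == "H2B H46"], 42)
  expect_equal(rep6$percent[rep6$residue == "H2A D89"], 16)
  expect_equal(rep6$fraction + (1 - rep6$fraction), rep(1, nrow(rep6)))
  rep74 <- protonation_report(rec, 7.4)
  expect_equal(round_half_up(100 * rep74$fraction[rep74$residue == "H2A D89"], 1), 0.7)
})
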