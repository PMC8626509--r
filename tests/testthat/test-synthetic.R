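test_that("generated peaks follow the single-site titration model exactly at zero noise", {
  sp <- synthetic_residue_spec("XN-H", true_pka = 5.9, base = c(118, 8.2),
                               direction = c(1, 0.1), amplitude = 1.0,
                               noise_sd = c(0, 0))
  gen <- generate_series(sp, seed = 51)
  cv <- compute_csp(gen$series, "XN-H")
  f <- fit_curve(cv)
  expect_equal(f$pka, 5.9, tolerance = 1e-6)
})

test_that("generator output is byte-identical under a fixed seed", {
  specs <- separated_specs(4, noise = 0.003)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_series(generate_series(specs, seed = 52), d1)
  write_series(generate_series(specs, seed = 52), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and differs under another seed
  d3 <- withr::local_tempdir()
  write_series(generate_series(specs, seed = 53), d3)
  expect_false(identical(readLines(file.path(d1, "ph04.4.list")),
                         readLines(file.path(d3, "ph04.4.list"))))
})

test_that("truth table and emitted peak lists are mutually consistent", {
  specs <- separated_specs(5, noise = 0.002)
  gen <- generate_series(specs, seed = 54)
  s <- gen$series
  ref <- s$reference
  lo <- 1
  g_span <- hh_g(s$points[[ref]]$meta$ph, specs$true_pka) -
    hh_g(s$points[[lo]]$meta$ph, specs$true_pka)
  for (i in seq_len(nrow(specs))) {
    lab <- specs$label[i]
    p_ref <- s$points[[ref]]$peaks
    p_lo <- s$points[[lo]]$peaks
    d <- c(p_ref$w1[p_ref$label == lab] - p_lo$w1[p_lo$label == lab],
           p_ref$w2[p_ref$label == lab] - p_lo$w2[p_lo$label == lab])
    expected <- c(gen$truth$disp_N15[i], gen$truth$disp_H1[i]) * g_span[i]
    # a difference of two noisy points has SD sqrt(2) * noise_sd per dim
    noise <- sqrt(2) * c(0.02, 0.002)
    expect_true(all(abs(d - expected) < 5 * noise), label = lab)
  }
})

test_that("increasing noise degrades median pKa recovery", {
  err <- vapply(c(0.002, 0.04), function(noise) {
    med <- vapply(1:3, function(s) {
      specs <- random_residue_specs(12, noise_sd = c(H1 = noise, N15 = 10 * noise),
                                    seed = 60 + s)
      gen <- generate_series(specs, seed = 70 + s)
      res <- fit_series(gen$series, n_mc = 0)
      cmp <- merge(res, gen$truth, by.x = "residue", by.y = "label")
      median(abs(cmp$pka - cmp$true_pka), na.rm = TRUE)
    }, numeric(1))
    mean(med)
  }, numeric(1))
  expect_gt(err[2], err[1])
})

test_that("overlapping base positions trigger the tracking-stress warning", {
  sp1 <- synthetic_residue_spec("AN-H", 6, base = c(120, 8), direction = c(1, 0.1),
                                amplitude = 1, noise_sd = c(0.05, 0.005))
  sp2 <- synthetic_residue_spec("BN-H", 6.5, base = c(120.01, 8.001),
                                direction = c(1, 0.1), amplitude = 1,
                                noise_sd = c(0.05, 0.005))
  expect_warning(generate_series(dplyr::bind_rows(sp1, sp2), seed = 55),
                 "overlap")
})

test_that("biphasic specs produce curved trajectories", {
  mono <- synthetic_residue_spec("MN-H", 5.5, base = c(115, 7.5),
                                 direction = c(1, 0.05), amplitude = 1.2,
                                 noise_sd = c(0, 0))
  bi <- synthetic_residue_spec("BN-H", 5.5, base = c(125, 9),
                               direction = c(1, 0.05), amplitude = 1.2,
                               noise_sd = c(0, 0),
                               second = list(pka = 7.0, direction = c(-0.2, 1),
                                             amplitude = 0.8))
  gen <- generate_series(dplyr::bind_rows(mono, bi), seed = 56)
  expect_equal(gen$truth$biphasic, c(FALSE, TRUE))
  traj <- function(lab) {
    t(vapply(gen$series$points, function(p) {
      i <- which(p$peaks$label == lab)
      c(p$peaks$w1[i], p$peaks$w2[i])
    }, numeric(2)))
  }
  curvature <- function(m) {
    # residual of the best straight line through the trajectory
    d <- sweep(m, 2, colMeans(m))
    sv <- svd(d)$d
    sv[2] / sv[1]
  }
  expect_lt(curvature(traj("MN-H")), 1e-8)   # single event: perfectly linear
  expect_gt(curvature(traj("BN-H")), 0.05)   # two events: visibly curved
})

test_that("spec validation rejects bad inputs", {
  expect_error(synthetic_residue_spec("X", 6, base = c(1, 2), direction = c(0, 0),
                                      amplitude = 1, noise_sd = c(0, 0)),
               "non-zero")
  expect_error(synthetic_residue_spec("X", 6, base = c(1, 2), direction = c(1, 0),
                                      amplitude = -1, noise_sd = c(0, 0)))
  expect_error(generate_series(separated_specs(2), ph_grid = c(5, 4, 6)))
})
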