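# Thermodynamic conversions, correlation, pose statistics and masked RMSD.

test_that("free energy converts to Ki by e^(dG/RT)", {
  expect_equal(dg_to_ki(0), 1.0)
  rt <- 0.0019872036 * 310
  expect_equal(dg_to_ki(rt), exp(1))
  expect_equal(dg_to_ki(-12.28), 2.20e-9, tolerance = 5e-3)
  # temperature matters
  expect_equal(dg_to_ki(-5, thermo_constants(298)),
               exp(-5 / (0.0019872036 * 298)))
})

test_that("nanomolar Ki converts to pKi on the molar scale", {
  expect_equal(round(ki_to_pki(0.65), 2), 9.19)
  expect_equal(ki_to_pki(1.0), 9.00)
  expect_equal(round(ki_to_pki(1850.00), 2), 5.73)
  expect_error(ki_to_pki(0), "positive")
  expect_error(ki_to_pki(-2), "positive")
})

test_that("dG converts to pKi and inverts algebraically", {
  expect_equal(dg_to_pki(0), 0)
  expect_equal(round(dg_to_pki(-12.28), 2), 8.66)
  for (temp in c(280, 298, 310, 350)) {
    const <- thermo_constants(temp)
    dg <- const$R * const$T * log(1e-9)
    expect_equal(dg_to_pki(dg, const), 9.0, tolerance = 1e-12)
  }
  # strictly decreasing, and the nM round trip recovers pKi
  dgs <- seq(-14, -2, by = 0.5)
  pki <- dg_to_pki(dgs)
  expect_true(all(diff(pki) < 0))
  expect_equal(ki_to_pki(dg_to_ki(dgs) * 1e9), pki, tolerance = 1e-12)
})

test_that("regression reproduces trivial and degenerate cases", {
  x <- c(1, 2, 3, 5)
  fit <- pki_regression(x, x)
  expect_equal(fit$r2, 1.0)
  expect_equal(fit$slope, 1.0)
  expect_equal(fit$intercept, 0.0)
  expect_equal(fit$n, 4)
  expect_error(pki_regression(1:3, 1:4), "equal length")
  expect_error(pki_regression(1:2, 1:2), "n < 3")
  expect_error(pki_regression(c(2, 2, 2), 1:3), "zero variance")
})

test_that("r2 is invariant under positive affine transforms", {
  set.seed(99)
  x <- stats::rnorm(12, 7, 1)
  y <- 0.8 * x + stats::rnorm(12, 0, 0.4)
  r0 <- pki_regression(x, y)$r2
  expect_equal(pki_regression(2.5 * x + 3, y)$r2, r0, tolerance = 1e-12)
  expect_equal(pki_regression(x, 0.1 * y - 7)$r2, r0, tolerance = 1e-12)
})

test_that("averaging R2 values behaves arithmetically", {
  expect_equal(round(average_r2(c(0.76, 0.82, 0.81)), 2), 0.80)
  expect_equal(round(average_r2(c(0.58, 0.69, 0.75)), 2), 0.67)
  expect_equal(average_r2(0.5), 0.5)
  expect_error(average_r2(numeric()), "no R2")
})

test_that("pose accuracy is the rank-1 fraction in percent", {
  expect_equal(pose_accuracy(pose_tally(c(`1` = 26))), 100.0)
  expect_equal(pose_accuracy(pose_tally(c(`1` = 20, `2` = 6))), 76.9)
  expect_equal(pose_accuracy(pose_tally(c(`1` = 25, `2` = 1))), 96.2)
  expect_equal(pose_accuracy(pose_tally(c(`2` = 3, absent = 2))), 0)
  expect_error(pose_tally(c(`1` = 2), total = 5), "sum to total")
  expect_error(pose_tally(c(`9` = 2)), "tally names")
})

test_that("relative improvement compares against the baseline", {
  expect_equal(relative_improvement(96.2, 76.9), 25.1)
  expect_equal(relative_improvement(50, 50), 0.0)
  expect_error(relative_improvement(50, 0), "baseline")
})

test_that("masked RMSD reproduces analytic cases without superposition", {
  s <- toy_ligand()
  expect_equal(masked_rmsd(s, s), 0.0)
  moved <- s
  moved$atoms$x <- moved$atoms$x + 3
  expect_equal(masked_rmsd(s, moved), 3.0, tolerance = 1e-12)
  # one of four atoms displaced by 1 A: sqrt(1/4)
  one <- s
  one$atoms$z[2] <- one$atoms$z[2] + 1
  expect_equal(masked_rmsd(s, one), 0.5, tolerance = 1e-12)
})

test_that("masked RMSD is symmetric and order-independent", {
  a <- toy_ligand()
  b <- a
  set.seed(5)
  b$atoms$x <- b$atoms$x + stats::rnorm(nrow(b$atoms), 0, 0.5)
  expect_equal(masked_rmsd(a, b), masked_rmsd(b, a))
  shuffled <- b
  shuffled$atoms <- shuffled$atoms[sample(nrow(shuffled$atoms)), ]
  expect_equal(masked_rmsd(a, shuffled), masked_rmsd(a, b))
})

test_that("name mismatches are reported and exclusions repair them", {
  a <- toy_ligand()
  b <- a
  b$atoms$name[1] <- "OXT"
  orig <- a$atoms$name[1]
  expect_error(masked_rmsd(a, b), paste0("unmatched atoms.*", orig))
  expect_equal(masked_rmsd(a, b, exclude = c(orig, "OXT")), 0.0)
  expect_error(masked_rmsd(a, a, exclude = a$atoms$name), "no atom pairs")
})

test_that("hydrogens are ignored in the pairing", {
  a <- toy_ligand()
  withH <- a
  withH$atoms <- rbind(withH$atoms,
                       data.frame(serial = 99L, name = "H1", element = "H",
                                  resname = "LIG", resid = 1L, chain = "A",
                                  x = 0, y = 0, z = 0))
  expect_equal(masked_rmsd(a, withH), 0.0)
})

test_that("duplicated atom names are rejected as ambiguous", {
  a <- toy_ligand()
  a$atoms$name[2] <- a$atoms$name[1]
  expect_error(masked_rmsd(a, a), "duplicated atom names")
})

test_that("optional superposition removes a pure rigid motion", {
  set.seed(61)
  a <- toy_ligand()
  b <- transform_structure(a, random_rotation(), stats::rnorm(3, 0, 10))
  expect_gt(masked_rmsd(a, b), 1)
  expect_equal(masked_rmsd(a, b, superpose = TRUE), 0.0, tolerance = 1e-9)
})
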