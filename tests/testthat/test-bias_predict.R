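# Coordination model, vacant-axis prediction, bias-site placement and BPF I/O.

test_that("coordination model normalizes directions and sums the resultant", {
  s <- site_from_offsets(rbind(c(2.1, 0, 0), c(0, 2.1, 0)))
  m <- coordination_model(first_site(s))
  expect_equal(m$unit_dirs, rbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-9)
  expect_equal(m$resultant, c(1, 1, 0), tolerance = 1e-9)
  expect_equal(m$origin, c(10, 10, 10))

  fix <- make_zinc_site(seed = 3)
  m3 <- coordination_model(first_site(parse_structure(fix$pdb)))
  expect_equal(unname(sqrt(rowSums(m3$unit_dirs^2))), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(m3$resultant, colSums(m3$unit_dirs))
})

test_that("under-coordinated sites are rejected", {
  s <- site_from_offsets(rbind(c(2.1, 0, 0)))
  expect_error(coordination_model(first_site(s)),
               "insufficient coordination sphere")
})

test_that("vacant axis is the negated normalized resultant", {
  s <- site_from_offsets(2.1 * rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  v <- vacant_axis(coordination_model(first_site(s)))
  expect_equal(v, -c(1, 1, 1) / sqrt(3), tolerance = 1e-9)
})

test_that("three tetrahedral vertices complete to the fourth", {
  occ <- tetrahedral_dirs()[1:3, ]
  s <- site_from_offsets(2.1 * occ)
  v <- vacant_axis(coordination_model(first_site(s)))
  expect_equal(v, c(-1, -1, 1) / sqrt(3), tolerance = 1e-9)
  # 109.471 degrees with every occupied direction (cosine -1/3)
  for (i in 1:3)
    expect_equal(vec_angle(v, occ[i, ]), 109.4712206, tolerance = 1e-6)
})

test_that("a balanced trans pair has no defined vacancy", {
  s <- site_from_offsets(rbind(c(2.1, 0, 0), c(-2.1, 0, 0)))
  expect_error(vacant_axis(coordination_model(first_site(s))),
               "degenerate coordination")
})

test_that("monodentate placement sits at bond_length along the vacant axis", {
  s <- site_from_offsets(2.1 * rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                         zn = c(0, 0, 0))
  b <- place_bias_sites(first_site(s), mode = "monodentate")
  expect_equal(nrow(b), 1)
  expect_equal(as.numeric(b[1, c("x", "y", "z")]),
               2.1 * (-c(1, 1, 1) / sqrt(3)), tolerance = 1e-9)
  expect_equal(sqrt(sum(b[1, c("x", "y", "z")]^2)), 2.1, tolerance = 1e-9)
  expect_equal(b$kind, "acceptor")
})

test_that("bidentate placement honours bond length, bite angle and symmetry", {
  fix <- make_zinc_site(seed = 2)
  site <- first_site(parse_structure(fix$pdb))
  zn <- as.numeric(site$zinc[, c("x", "y", "z")])
  b <- place_bias_sites(site)    # defaults: bidentate, 2.1 A, 76 deg
  expect_equal(nrow(b), 2)
  p1 <- as.numeric(b[1, c("x", "y", "z")]) - zn
  p2 <- as.numeric(b[2, c("x", "y", "z")]) - zn
  expect_equal(sqrt(sum(p1^2)), 2.1, tolerance = 1e-9)
  expect_equal(sqrt(sum(p2^2)), 2.1, tolerance = 1e-9)
  expect_equal(vec_angle(p1, p2), 76, tolerance = 1e-6)
  # chord length 2 L sin(bite/2)
  expect_equal(sqrt(sum((p1 - p2)^2)), 2 * 2.1 * sin(38 * pi / 180),
               tolerance = 1e-9)
  # the pair is symmetric about the vacant axis
  v <- vacant_axis(coordination_model(site))
  expect_equal(sum((p1 - p2) * v), 0, tolerance = 1e-9)
  expect_equal(unit(p1 + p2), v, tolerance = 1e-9)
})

test_that("bias placement is equivariant under rigid motions", {
  set.seed(404)
  fix <- make_zinc_site(angular_jitter = 5, seed = 12)
  s <- parse_structure(fix$pdb)
  for (mode in c("monodentate", "bidentate")) {
    b0 <- as.matrix(place_bias_sites(first_site(s),
                                     mode = mode)[, c("x", "y", "z")])
    for (k in 1:4) {
      R <- random_rotation(); tr <- stats::rnorm(3, 0, 15)
      b1 <- as.matrix(place_bias_sites(first_site(transform_structure(s, R, tr)),
                                       mode = mode)[, c("x", "y", "z")])
      expected <- sweep(b0 %*% t(R), 2, tr, `+`)
      expect_equal(unname(b1), unname(expected), tolerance = 1e-6)
    }
  }
})

test_that("bite angle outside (0, 180) is rejected", {
  fix <- make_zinc_site(seed = 2)
  site <- first_site(parse_structure(fix$pdb))
  expect_error(place_bias_sites(site, bite_angle = 0), "bite_angle")
  expect_error(place_bias_sites(site, bite_angle = 180), "bite_angle")
})

test_that("resultant rule agrees with a brute-force max-min-angle search
           for nearly ideal tetrahedral spheres", {
  # The two functionals coincide exactly at ideal tetrahedral geometry (in
  # any orientation) and drift apart at about 1.2x the shape distortion, so
  # tight agreement is only expected while the donor set stays close to the
  # ideal shape.
  set.seed(505)
  ideal <- tetrahedral_dirs()[1:3, ]
  for (rep in 1:6) {
    R <- random_rotation()
    occ <- t(apply(ideal %*% t(R), 1, perturb_dir, max_deg = 1))
    r <- colSums(occ)
    if (sqrt(sum(r^2)) <= 0.3) next
    s <- site_from_offsets(2.1 * occ)
    v <- vacant_axis(coordination_model(first_site(s)))
    oracle <- brute_force_vacant(occ, n_dirs = 1e5)
    expect_lt(vec_angle(v, oracle), 2.0)
  }
})

test_that("BPF writing matches the documented line format", {
  sites <- data.frame(x = 1.234, y = 5.0, z = -2.1, energy = -2.0,
                      radius = 0.8, kind = "acceptor")
  txt <- write_bpf(sites)
  expect_equal(strsplit(txt, "\n")[[1]],
               c("#x y z Vset r type", "1.234 5.000 -2.100 -2.00 0.80 acc"))
  expect_equal(write_bpf(sites[0, ]), "#x y z Vset r type")
  expect_error(write_bpf(transform(sites, x = NaN)), "non-finite")
})

test_that("BPF write/read round trip is field-exact at printed precision", {
  fix <- make_zinc_site(angular_jitter = 2, seed = 9)
  b <- place_bias_sites(first_site(parse_structure(fix$pdb)))
  b2 <- rbind(b, data.frame(x = 0.5, y = -3, z = 7, energy = -1.5,
                            radius = 1.2, kind = "donor"))
  got <- read_bpf(write_bpf(b2))
  expect_equal(got$x, round(b2$x, 3))
  expect_equal(got$y, round(b2$y, 3))
  expect_equal(got$z, round(b2$z, 3))
  expect_equal(got$energy, round(b2$energy, 2))
  expect_equal(got$radius, round(b2$radius, 2))
  expect_equal(got$kind, b2$kind)
})

test_that("BPF reader rejects malformed lines and accepts blank input", {
  expect_error(read_bpf("1 2 3 -2.0 0.8 xyz"), "line 1.*unknown type")
  expect_error(read_bpf("1 2 3 -2.0 0.8"), "expected 6 fields")
  expect_error(read_bpf("1 2 three -2.0 0.8 acc"), "unparseable numeric")
  expect_equal(nrow(read_bpf("")), 0)
  expect_equal(nrow(read_bpf("# only a comment")), 0)
})
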