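test_that("isolated-sphere SASA matches the closed form within quadrature error", {
  s <- gen_toy_structure("single_atom")
  expect_equal(sasa(s), 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
})

test_that("two-sphere SASA matches the spherical-cap closed form within 2%", {
  R <- 1.70 + 1.4
  for (d in c(1.5, 2.5, 3.5, 5.0)) {
    s <- gen_toy_structure("two_spheres", d = d)
    a <- sasa(s)
    analytic <- if (d < 2 * R) 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
                else 4 * pi * R^2
    expect_equal(a[1], analytic, tolerance = 0.02)
    expect_equal(a[2], analytic, tolerance = 0.02)
  }
  # beyond contact distance there is no occlusion at all
  far <- sasa(gen_toy_structure("two_spheres", d = 2 * R + 0.01))
  expect_equal(far, rep(4 * pi * R^2, 2), tolerance = 1e-9)
})

test_that("a fully enclosed atom has zero accessible area", {
  s <- gen_toy_structure("shell_buried")
  expect_equal(sasa(s)[1], 0)
})

test_that("quadrature converges and is rigid-motion stable", {
  s <- gen_toy_structure("gly_ala_gly")
  a960 <- sasa(s, n_points = 960)
  a3840 <- sasa(s, n_points = 3840)
  expect_equal(sum(a960), sum(a3840), tolerance = 0.01)

  # translation moves the quadrature points rigidly: exactly invariant
  shifted <- s
  shifted$atoms$x <- s$atoms$x + 11.3
  shifted$atoms$z <- s$atoms$z - 4.2
  expect_identical(sasa(shifted), a960)

  # rotation re-samples the fixed point set: total area stable to the
  # quadrature anisotropy (well under 0.5% at 960 points)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% rot
  rotated$atoms$x <- xyz[, 1]; rotated$atoms$y <- xyz[, 2]
  rotated$atoms$z <- xyz[, 3]
  expect_equal(sum(sasa(rotated)), sum(a960), tolerance = 0.005)
})

test_that("side-chain exposure is definitional and self-consistent", {
  gag <- gen_toy_structure("gly_ala_gly")
  prof <- side_chain_exposure(gag, 2)
  expect_equal(prof$exposure_ratio, prof$side_chain_sasa / prof$coil_ref)
  # the coil reference is defined on exactly this construct
  expect_equal(prof$exposure_ratio, 1, tolerance = 0.15)
  # glycine has no heavy side chain
  g <- side_chain_exposure(gag, 1)
  expect_equal(g$side_chain_sasa, 0)
  expect_equal(g$exposure_ratio, 0)
})

test_that("a residue buried under a dummy shell has ratio zero", {
  shell <- pyrescore:::sphere_points(200) * 3.0
  atoms <- rbind(
    data.frame(atom = "CB", element = "C", resno = 1, resname = "ALA",
               chain = "A", x = 0, y = 0, z = 0),
    data.frame(atom = paste0("C", 1:200), element = "C", resno = 2,
               resname = "DUM", chain = "A",
               x = shell[, 1], y = shell[, 2], z = shell[, 3]))
  s <- atom_structure(atoms)
  prof <- side_chain_exposure(s, 1)
  expect_equal(prof$side_chain_sasa, 0)
  expect_equal(prof$exposure_ratio, 0)
})

test_that("residues with missing side-chain atoms are flagged", {
  atoms <- data.frame(atom = c("N", "CA", "C", "O", "CB"), element =
                        c("N", "C", "C", "O", "C"), resno = 1,
                      resname = "PHE", chain = "A",
                      x = c(0, 1.5, 2.2, 3.1, 1.9), y = c(0, 0, 1.2, 1.1, -1.4),
                      z = 0)
  s <- atom_structure(atoms)
  expect_warning(prof <- side_chain_exposure(s, 1), "1/7 side-chain atoms")
  expect_true(prof$incomplete)
})

test_that("embedded classification uses a strict 15% threshold", {
  hd <- helix_definition()
  pos <- helix_positions(hd)
  prof <- data.frame(position = pos, exposure_ratio = 1.0)
  expect_length(embedded_positions(prof), 0)

  prof$exposure_ratio <- ifelse(pos %in% c(71, 75, 78, 134, 138, 141),
                                0.14, 0.5)
  expect_equal(embedded_positions(prof), c(71L, 75L, 78L, 134L, 138L, 141L))

  prof$exposure_ratio <- rep(0.15, 27)  # exactly at threshold: not embedded
  expect_length(embedded_positions(prof), 0)

  # with no structure-derived profile the packaged mask is authoritative
  expect_equal(embedded_positions(), c(71L, 75L, 78L, 134L, 138L, 141L))
})

test_that("unknown elements are reported with the offending atoms", {
  s <- gen_toy_structure("single_atom")
  s$atoms$element <- "ZZ"
  expect_error(sasa(s), "ZZ")
})

test_that("PDB round-trip preserves atoms and coordinates", {
  s <- gen_toy_structure("gly_ala_gly")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_structure(s, f)
  s2 <- read_pdb_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$atom, s$atoms$atom)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(exposure_profile(s2, positions = 2)$exposure_ratio,
               exposure_profile(s, positions = 2)$exposure_ratio,
               tolerance = 1e-3)
})
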