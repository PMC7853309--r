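test_that("generated slices land within 0.5 of their drawn targets", {
  sims <- gen_helix_slices(15, mean = -24, sd = 2.5, seed = 5)
  for (s in sims) {
    got <- helix_hydrophobicity(s$slice)$score
    expect_lt(abs(got - s$target), 0.5 + 1e-9)
    expect_equal(helix_hydrophobicity(s$slice)$n_scored, 21L)
  }
  # sd = 0 at the Ala ceiling forces an all-Ala scored window
  ala <- gen_helix_slices(1, mean = 21 * 1.8, sd = 0, seed = 1)[[1]]
  unmasked <- !helix_positions(helix_definition()) %in%
    helix_definition()$embedded
  expect_true(all(ala$slice$symbols[unmasked] == "A"))
  expect_equal(helix_hydrophobicity(ala$slice)$score, 37.8)

  near_zero <- gen_helix_slices(5, mean = 0, sd = 0, seed = 2)
  for (s in near_zero) {
    expect_lt(abs(helix_hydrophobicity(s$slice)$score), 0.5 + 1e-9)
  }
  expect_error(gen_helix_slices(1, mean = 200, sd = 1), "achievable")
})

test_that("generators are byte-identical under a fixed seed", {
  a <- gen_helix_slices(5, -24, 2, seed = 9)
  b <- gen_helix_slices(5, -24, 2, seed = 9)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(lapply(a, `[[`, "record"), f1)
  write_fasta(lapply(b, `[[`, "record"), f2)
  expect_identical(readLines(f1), readLines(f2))

  t1 <- gen_trait_tree(8, 2, seed = 4)
  t2 <- gen_trait_tree(8, 2, seed = 4)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$traits, t2$traits)
})

test_that("error-free clone sets recover the true sequences exactly", {
  truth <- list(seq_record("p1", strrep("ACGT", 20), kind = "nucleotide"),
                seq_record("p2", strrep("GATT", 20), kind = "nucleotide"))
  cs <- gen_clone_set(truth, n_clones = 3, error_rate = 0, seed = 1)
  kept <- consensus_filter(cs, 2)
  expect_setequal(kept$sequence, vapply(truth, `[[`, "", "symbols"))
  expect_equal(kept$support, c(3L, 3L))

  single <- gen_clone_set(truth[1], n_clones = 1, error_rate = 0, seed = 1)
  expect_equal(nrow(consensus_filter(single, 2)), 0L)
})

test_that("errored clones are usually rescued by the consensus rule", {
  # with a 0.3% per-base error over 307 bp, P(clone error-free) ~ 0.398;
  # 8 clones give >= 2 error-free copies with probability ~ 0.89 per locus
  set.seed(60)
  truth <- seq_record("p1", paste(sample(c("A", "C", "G", "T"), 307,
                                         replace = TRUE), collapse = ""),
                      kind = "nucleotide")
  hits <- 0L
  for (rep in 1:100) {
    cs <- gen_clone_set(list(truth), n_clones = 8, error_rate = 0.003,
                        seed = rep)
    kept <- consensus_filter(cs, 2)
    if (truth$symbols %in% kept$sequence) hits <- hits + 1L
  }
  expect_gte(hits, 80L)
})

test_that("planted loss counts equal the brute-force parsimony minimum", {
  expect_equal(unname(gen_trait_tree(6, 0, seed = 2)$traits),
               rep("present", 6))
  for (seed in 1:10) {
    n_tips <- sample(4:8, 1)
    n_losses <- sample(0:floor(n_tips / 2), 1)
    tt <- gen_trait_tree(n_tips, n_losses, seed = seed)
    expect_equal(oracle_min_changes(tt$tree, tt$traits), n_losses)
    expect_equal(fitch_min_changes(tt$tree, tt$traits), n_losses)
  }
  expect_error(gen_trait_tree(4, 3, seed = 1), "cannot plant")
})

test_that("toy structures serialize and carry the advertised geometry", {
  expect_error(gen_toy_structure("hexagon"), "arg")
  s <- gen_toy_structure("two_spheres", d = 4.2)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[2], 4.2)
  gag <- gen_toy_structure("gly_ala_gly")
  expect_equal(unique(gag$atoms$resname), c("GLY", "ALA"))
  expect_equal(sum(gag$atoms$resname == "ALA"), 5L)  # N CA C O CB
  # peptide-bond C-N distances near 1.33 A
  for (r in 1:2) {
    C <- gag$atoms[gag$atoms$resno == r & gag$atoms$atom == "C", ]
    N <- gag$atoms[gag$atoms$resno == r + 1 & gag$atoms$atom == "N", ]
    expect_equal(sqrt((C$x - N$x)^2 + (C$y - N$y)^2 + (C$z - N$z)^2),
                 1.329, tolerance = 1e-6)
  }
})
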