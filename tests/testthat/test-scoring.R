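# Interface scoring: contacts, fnat, superposition, iRMSD, LRMSD, clashes,
# the combined score and its orchestration.

cst <- scoring_constants()

test_that("find_contacts honors the cutoff at the threshold", {
  a <- mk_ca_chain("A", matrix(c(0, 0, 0), 1))
  b <- mk_ca_chain("B", matrix(c(4.9, 0, 0), 1))
  expect_equal(nrow(find_contacts(a, b, 5.0)), 1L)
  expect_equal(nrow(find_contacts(a, b, 4.0)), 0L)   # peptide cutoff
})

test_that("contacts and interface sets equal brute force on a dimer", {
  fx <- make_complex(fixture_spec("A2", chain_length = 22))  # PROTEIN chains
  a <- fx$reference$chains$A
  b <- fx$reference$chains$B
  expect_equal(find_contacts(a, b, 5.0), oracle_contacts(a, b, 5.0))
  got <- define_interface_residues(a, b, cst)
  oc <- oracle_contacts(a, b, 10.0)
  expect_equal(got$res_a, sort(unique(oc$res_a)))
  expect_equal(got$res_b, sort(unique(oc$res_b)))
})

test_that("interface residue rules: 9.9 A in, peptide Cb 8.2 A out", {
  a <- mk_ca_chain("A", matrix(c(0, 0, 0), 1), class = "PROTEIN")
  b <- mk_ca_chain("B", matrix(c(9.9, 0, 0), 1), class = "PROTEIN")
  iface <- define_interface_residues(a, b, cst)
  expect_equal(iface$res_a, 1L)
  expect_equal(iface$res_b, 1L)
  # peptide chains: Cb-Cb rule (Ca substitutes when Cb absent) at 8 A
  ap <- mk_ca_chain("A", matrix(c(0, 0, 0), 1))    # classifies as PEPTIDE
  b2 <- mk_ca_chain("B", matrix(c(8.2, 0, 0), 1))
  iface2 <- define_interface_residues(ap, b2, cst)
  expect_length(iface2$res_a, 0L)
  b3 <- mk_ca_chain("B", matrix(c(7.9, 0, 0), 1))
  expect_equal(define_interface_residues(ap, b3, cst)$res_a, 1L)
})

test_that("fnat set arithmetic on a constructed fixture", {
  native <- data.frame(res_a = c(1, 2, 3, 4, 5, 6), res_b = c(1, 2, 3, 4, 5, 6))
  model <- data.frame(res_a = c(1, 2, 3, 9), res_b = c(1, 2, 3, 9))
  r <- compute_fnat(model, native, identity_corr(10), identity_corr(10))
  expect_equal(r$fnat, 0.5)
  expect_equal(r$fnonnat, 0.25)

  ident <- compute_fnat(native, native, identity_corr(10), identity_corr(10))
  expect_equal(ident$fnat, 1)
  expect_equal(ident$fnonnat, 0)

  empty_model <- data.frame(res_a = integer(0), res_b = integer(0))
  expect_equal(compute_fnat(empty_model, native, identity_corr(10),
                            identity_corr(10))$fnat, 0)
  expect_error(compute_fnat(model, empty_model, identity_corr(10),
                            identity_corr(10)), "no native contacts")
})

test_that("model contacts over unmapped residues count as non-native", {
  native <- data.frame(res_a = 1, res_b = 1)
  model <- data.frame(res_a = c(1, 8), res_b = c(1, 8))
  corr <- identity_corr(5)  # residues 6..10 unmapped
  r <- compute_fnat(model, native, corr, corr)
  expect_equal(r$fnat, 1)
  expect_equal(r$fnonnat, 0.5)
})

test_that("superposition matches the quaternion oracle", {
  set.seed(42)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-9)
  # rigid invariance
  tr <- random_rigid()
  moved <- sweep(x %*% tr$rotation, 2, tr$translation, "+")
  expect_lt(superpose(x, moved)$rmsd, 1e-6)
  # perturbed copies, several cases
  for (k in 1:5) {
    y <- matrix(rnorm(15), 5, 3)
    z <- y + matrix(rnorm(15, sd = 0.5), 5, 3)
    fit <- superpose(y, z)
    expect_equal(fit$rmsd, oracle_superpose_rmsd(y, z), tolerance = 1e-6)
    # applying the transform reproduces the reported rmsd
    refit <- sweep(z %*% fit$rotation, 2, fit$translation, "+")
    expect_equal(sqrt(mean(rowSums((refit - y)^2))), fit$rmsd,
                 tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  expect_error(superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("iRMSD: identity is zero, translations match the oracle", {
  fx <- make_complex(fixture_spec("A2", chain_length = 12))
  a <- fx$reference$chains$A; b <- fx$reference$chains$B
  ca <- map_residues(a, a); cb <- map_residues(b, b)
  expect_equal(compute_irmsd(a, b, a, b, ca, cb, cst)$irmsd, 0,
               tolerance = 1e-9)
  # translate model chain B by 2 A
  b2 <- b
  b2$atoms$x <- b2$atoms$x + 2
  got <- compute_irmsd(a, b2, a, b, ca, cb, cst)$irmsd
  # oracle: same selection, quaternion superposition
  iface <- define_interface_residues(a, b, cst)
  pa <- complexqa:::paired_backbone_coords(a, a, ca, iface$res_a,
                                           cst$protein_backbone)
  pb <- complexqa:::paired_backbone_coords(b2, b, cb, iface$res_b,
                                           cst$protein_backbone)
  expect_equal(got, oracle_superpose_rmsd(rbind(pa$ref, pb$ref),
                                          rbind(pa$model, pb$model)),
               tolerance = 1e-6)
  expect_gt(got, 0)
})

test_that("iRMSD skips missing backbone atoms with a warning", {
  fx <- make_complex(fixture_spec("A2", chain_length = 12))
  a <- fx$reference$chains$A; b <- fx$reference$chains$B
  b_no_o <- b
  keep <- b_no_o$atoms$name != "O"
  b_no_o$atoms <- b_no_o$atoms[keep, ]
  ca <- map_residues(a, a); cb <- map_residues(b_no_o, b)
  expect_warning(r <- compute_irmsd(a, b_no_o, a, b, ca, cb, cst), "skipped")
  expect_equal(r$irmsd, 0, tolerance = 1e-9)
  expect_gt(r$skipped_atoms, 0)
})

test_that("LRMSD: receptor rule and oracle agreement", {
  fx <- make_complex(fixture_spec("A2", chain_length = 12))
  a <- fx$reference$chains$A; b <- fx$reference$chains$B
  ca <- map_residues(a, a); cb <- map_residues(b, b)
  r0 <- compute_lrmsd(a, b, a, b, ca, cb, cst)
  expect_equal(r0$lrmsd, 0, tolerance = 1e-9)
  # equal-size chains: the first reference chain is the receptor
  expect_equal(r0$receptor_chain, "A")
  expect_equal(r0$ligand_chain, "B")
  # larger chain wins otherwise
  fx2 <- make_complex(fixture_spec("A1B1", chain_length = 12))
  big_b <- make_complex(fixture_spec("B1", chain_length = 20))$reference$chains$A
  big_b$chain_id <- "B"
  r1 <- compute_lrmsd(a, big_b, a, big_b, ca, map_residues(big_b, big_b), cst)
  expect_equal(r1$receptor_chain, "B")

  # rotate the model ligand chain 180 degrees about x through the origin
  rot <- complexqa:::rotation_about_axis(c(1, 0, 0), pi)
  b_rot <- b
  co <- complexqa:::chain_coords(b) %*% rot
  b_rot$atoms$x <- co[, 1]; b_rot$atoms$y <- co[, 2]; b_rot$atoms$z <- co[, 3]
  got <- compute_lrmsd(a, b_rot, a, b, ca, cb, cst)$lrmsd
  # oracle: the model receptor equals the reference receptor, so the optimal
  # superposition is the identity and the LRMSD is the direct rmsd between
  # the rotated and original ligand backbones
  bb <- function(ch) as.matrix(ch$atoms[ch$atoms$name %in% cst$protein_backbone,
                                        c("x", "y", "z")])
  expect_equal(got, sqrt(mean(rowSums((bb(b_rot) - bb(b))^2))),
               tolerance = 1e-6)
  expect_gt(got, 1)
})

test_that("clash counting equals brute force on constructed fixtures", {
  far_a <- mk_ca_chain("A", matrix(c(0, 0, 0, 0, 3, 0), 2, byrow = TRUE))
  far_b <- mk_ca_chain("B", matrix(c(10, 0, 0), 1))
  expect_equal(count_clashes(far_a, far_b, 2.0), 0L)
  onto <- mk_ca_chain("B", matrix(c(0, 0, 0), 1))
  expect_gte(count_clashes(far_a, onto, 2.0), 1L)
  # exactly 3 sub-cutoff pairs by construction
  a3 <- mk_ca_chain("A", matrix(c(0, 0, 0,  5, 0, 0,  10, 0, 0), 3, byrow = TRUE))
  b3 <- mk_ca_chain("B", matrix(c(0.5, 0, 0,  5.5, 0, 0,  10.5, 0, 0), 3,
                                byrow = TRUE))
  expect_equal(count_clashes(a3, b3, 2.0), 3L)
  expect_equal(count_clashes(a3, b3, 2.0), oracle_clashes(a3, b3, 2.0))
})

test_that("the combined score has the printed fixed points and monotonicity", {
  expect_identical(compute_dockq(1, 0, 0), 1)
  expect_identical(compute_dockq(0.5, 1.5, 8.5), 0.5)
  # incorrect-model limit: the LRMSD term alone is 1/(1+(1000/8.5)^2)/3,
  # about 2.4e-5, which bounds the score
  expect_lt(compute_dockq(0, 1000, 1000), 1e-4)
  expect_gt(compute_dockq(0.6, 2, 6), compute_dockq(0.5, 2, 6))
  expect_gt(compute_dockq(0.5, 1, 6), compute_dockq(0.5, 2, 6))
  expect_gt(compute_dockq(0.5, 2, 5), compute_dockq(0.5, 2, 6))
})

test_that("CAPRI classes use the documented half-open boundaries", {
  expect_equal(classify_capri(0), "Incorrect")
  expect_equal(classify_capri(0.229), "Incorrect")
  expect_equal(classify_capri(0.23), "Acceptable")
  expect_equal(classify_capri(0.49), "Medium")
  expect_equal(classify_capri(0.5), "Medium")
  expect_equal(classify_capri(0.80), "High")
  expect_equal(classify_capri(1), "High")
})

test_that("score_interface: identity, graded degradation, dissociation", {
  fx <- make_complex(fixture_spec("A2", chain_length = 12))
  a <- fx$reference$chains$A; b <- fx$reference$chains$B
  ca <- map_residues(a, a); cb <- map_residues(b, b)
  perfect <- score_interface(a, b, a, b, ca, cb, cst)
  expect_equal(perfect$dockq, 1, tolerance = 1e-9)
  expect_equal(perfect$fnat, 1)
  expect_equal(perfect$clashes, 0L)
  expect_equal(perfect$capri_class, "High")

  shift <- function(d) {
    b2 <- b; b2$atoms$x <- b2$atoms$x + d
    score_interface(a, b2, a, b, ca, cb, cst)
  }
  s1 <- shift(1); s5 <- shift(5)
  expect_lt(s1$dockq, 1)
  expect_gt(s1$dockq, s5$dockq)

  s100 <- shift(100)
  expect_equal(s100$fnat, 0)
  expect_lt(s100$dockq, 0.05)
  # evaluate the formula on oracle-computed components
  b100 <- b; b100$atoms$x <- b100$atoms$x + 100
  iface <- define_interface_residues(a, b, cst)
  pa <- complexqa:::paired_backbone_coords(a, a, ca, iface$res_a,
                                           cst$protein_backbone)
  pb <- complexqa:::paired_backbone_coords(b100, b, cb, iface$res_b,
                                           cst$protein_backbone)
  o_irmsd <- oracle_superpose_rmsd(rbind(pa$ref, pb$ref),
                                   rbind(pa$model, pb$model))
  expect_equal(s100$dockq, compute_dockq(0, o_irmsd, s100$lrmsd, cst),
               tolerance = 1e-9)
})

test_that("all score components are invariant under global rigid motion", {
  set.seed(7)
  fx <- make_complex(fixture_spec("A2", chain_length = 12,
                                  noise = c(B = 0.4)))
  ref <- fx$reference
  model <- fx$model
  ca <- map_residues(model$chains$A, ref$chains$A)
  cb <- map_residues(model$chains$B, ref$chains$B)
  base <- score_interface(model$chains$A, model$chains$B,
                          ref$chains$A, ref$chains$B, ca, cb, cst)
  for (k in 1:3) {
    moved <- transform_structure(model, random_rigid())
    got <- score_interface(moved$chains$A, moved$chains$B,
                           ref$chains$A, ref$chains$B, ca, cb, cst)
    for (f in c("fnat", "fnonnat", "irmsd", "lrmsd", "dockq")) {
      expect_equal(got[[f]], base[[f]], tolerance = 1e-6, info = f)
    }
    expect_equal(got$clashes, base$clashes)
  }
})
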