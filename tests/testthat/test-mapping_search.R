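# Chain-mapping combinatorics, GlobalDockQ and the exhaustive search.

cst <- scoring_constants()

homo_groups <- function(k) {
  list(list(member_chain_ids = LETTERS[seq_len(k)],
            representative = "AEKLDWRVFG", molecule_class = "PROTEIN"))
}

test_that("count_mappings: k! for homomers, products for mixtures", {
  for (k in 1:8) {
    expect_equal(count_mappings(homo_groups(k), homo_groups(k), cst),
                 factorial(k), info = paste0("A", k))
  }
  # A2B1: 2! * 1! by direct reasoning
  fx <- make_complex(fixture_spec("A2B1"))
  g <- group_equivalent_chains(fx$reference)
  expect_equal(count_mappings(g, g, cst), 2)
})

test_that("enumerate_mappings yields each mapping exactly once", {
  m2 <- enumerate_mappings(homo_groups(2), homo_groups(2), constants = cst)
  expect_length(m2, 2L)
  keys <- vapply(m2, function(m) paste(names(m), m, sep = ":", collapse = ","),
                 character(1))
  expect_setequal(keys, c("A:A,B:B", "A:B,B:A"))

  m3 <- enumerate_mappings(homo_groups(3), homo_groups(3), constants = cst)
  expect_length(m3, 6L)
  keys3 <- vapply(m3, function(m) paste(m[LETTERS[1:3]], collapse = ""),
                  character(1))
  expect_setequal(keys3, c("ABC", "ACB", "BAC", "BCA", "CAB", "CBA"))

  het <- make_complex(fixture_spec("A1B1"))
  g <- group_equivalent_chains(het$reference)
  expect_length(enumerate_mappings(g, g, constants = cst), 1L)
})

test_that("global_dockq: identity mapping on self-comparison scores 1", {
  fx <- make_complex(fixture_spec("A2"))
  ids <- names(fx$reference$chains)
  res <- global_dockq(fx$reference, fx$reference, setNames(ids, ids))
  expect_equal(res$global_dockq, 1, tolerance = 1e-9)
})

test_that("relabeled asymmetric homodimer: swap mapping beats identity", {
  # a ring homodimer is C2-symmetric, so identity and swap mappings tie by
  # construction; rotate chain B about its own centroid to break the
  # assembly symmetry while keeping the two sequences identical
  fx <- make_complex(fixture_spec("A2"))
  ref <- fx$reference
  b <- ref$chains$B
  co <- complexqa:::chain_coords(b)
  cen <- colMeans(co)
  rot <- complexqa:::rotation_about_axis(c(1, 1, 0), 1.0)
  co2 <- sweep(sweep(co, 2, cen) %*% rot, 2, cen, "+")
  b$atoms$x <- co2[, 1]; b$atoms$y <- co2[, 2]; b$atoms$z <- co2[, 3]
  ref <- complexqa:::new_structure(list(ref$chains$A, b), "<fixture>", "PDB")
  expect_gte(nrow(find_contacts(ref$chains$A, ref$chains$B, 5)), 1L)
  # model: same geometry with the chain ids swapped
  ma <- ref$chains$B; ma$chain_id <- "A"
  mb <- ref$chains$A; mb$chain_id <- "B"
  model <- complexqa:::new_structure(list(ma, mb), "<fixture>", "PDB")
  res_swap <- global_dockq(model, ref, c(A = "B", B = "A"))
  res_ident <- global_dockq(model, ref, c(A = "A", B = "B"))
  expect_equal(res_swap$global_dockq, 1, tolerance = 1e-9)
  expect_lt(res_ident$global_dockq, 1)
  best <- find_optimal_mapping(model, ref, n_workers = 1)
  expect_equal(best$mapping[order(names(best$mapping))], c(A = "B", B = "A"))
})

test_that("missing model chain: unmapped reference interfaces score 0", {
  fx <- make_complex(fixture_spec("A3"))
  ref <- fx$reference
  n_iface <- length(complexqa:::reference_interfaces(ref, cst))
  model2 <- complexqa:::new_structure(fx$model$chains[c("A", "B")],
                                      "<fixture>", "PDB")
  res <- find_optimal_mapping(model2, ref, n_workers = 1)
  # hand-computed mean: one mapped perfect interface, the rest 0
  mapped <- sum(vapply(res$per_interface,
                       function(r) is.null(r$unmapped), logical(1)))
  expect_equal(res$global_dockq, mapped / n_iface, tolerance = 1e-9)
  expect_equal(mapped, 1L)
  expect_equal(n_iface, 3L)
})

test_that("A4 cyclic relabel is recovered exhaustively and reproducibly", {
  fx <- make_complex(fixture_spec("A4", relabel = c(A = "B", B = "C",
                                                    C = "D", D = "A")))
  res1 <- find_optimal_mapping(fx$model, fx$reference, n_workers = 1)
  expect_equal(res1$n_evaluated, 24L)
  expect_equal(res1$global_dockq, 1, tolerance = 1e-9)
  # worker-count invariance
  res4 <- find_optimal_mapping(fx$model, fx$reference, n_workers = 4)
  expect_identical(res1$mapping, res4$mapping)
  expect_equal(res1$global_dockq, res4$global_dockq, tolerance = 1e-12)
})

test_that("search equals a naive scan over all mappings (oracle)", {
  set.seed(9)
  fx <- make_complex(fixture_spec("A3", noise = c(A = 0.2, B = 0.35, C = 0.5),
                                  relabel = c(A = "C", B = "A", C = "B")))
  best <- find_optimal_mapping(fx$model, fx$reference, n_workers = 1)
  # naive: score every candidate with a fresh cache
  g_m <- group_equivalent_chains(fx$model)
  g_r <- group_equivalent_chains(fx$reference)
  cands <- enumerate_mappings(g_m, g_r, constants = cst)
  expect_length(cands, 6L)
  scores <- vapply(cands, function(m)
    global_dockq(fx$model, fx$reference, m)$global_dockq, numeric(1))
  expect_equal(best$global_dockq, max(scores), tolerance = 1e-9)
  # cache soundness: recomputing the best mapping fresh gives the same value
  expect_equal(global_dockq(fx$model, fx$reference, best$mapping)$global_dockq,
               best$global_dockq, tolerance = 1e-12)
})

test_that("equivalent ligand copies are assigned optimally via the search", {
  fx <- make_complex(fixture_spec("A2", chain_length = 22,
                                  ligand = "co2", n_ligands = 2))
  ref <- fx$reference
  lig_ids <- names(ref$chains)[3:4]
  # swap the two ligand copies in the model
  model <- fx$model
  swapped <- model$chains
  tmp <- swapped[[lig_ids[1]]]$chain_id
  swapped[[lig_ids[1]]]$chain_id <- swapped[[lig_ids[2]]]$chain_id
  swapped[[lig_ids[2]]]$chain_id <- tmp
  model <- complexqa:::new_structure(swapped, "<fixture>", "PDB")
  res <- find_optimal_mapping(model, ref, n_workers = 1)
  # the swap must be undone: every ligand interface back at LRMSD 0
  for (rec in res$per_interface) {
    if (!is.null(rec$kind) && identical(rec$kind, "small_molecule") &&
        is.null(rec$unmapped))
      expect_equal(rec$lrmsd, 0, tolerance = 1e-6)
  }
  expect_equal(res$global_dockq, 1, tolerance = 1e-9)
})

test_that("incompatible fixed constraints are rejected", {
  fx <- make_complex(fixture_spec("A2B1"))
  g <- group_equivalent_chains(fx$reference)
  # chain C is the B-type subunit: assigning it to an A-type slot must fail
  expect_error(
    enumerate_mappings(g, g, fixed = c(C = "A"), constants = cst),
    "groups")
})
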