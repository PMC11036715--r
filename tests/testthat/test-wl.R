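test_that("WL refinement starts from atomic symbols and refines monotonically", {
  g <- mol_to_graph("CCOCC")
  col <- wl_refine(g, 0)
  expect_equal(length(col$partition),
               length(unique(g$atom_symbols)))
  # partition at t+1 refines the one at t: same-label atoms at t+1 share
  # labels at t
  col3 <- wl_refine(g, 3)
  for (t in 1:3) {
    lab_prev <- col3$labels[[t]]
    lab_next <- col3$labels[[t + 1]]
    for (cl in split(seq_along(lab_next), lab_next)) {
      expect_length(unique(lab_prev[cl]), 1)
    }
  }
})

test_that("hand-refined colorings match on small path graphs", {
  g <- mol_to_graph("CCCCC")
  # one round separates the chain ends; the second distinguishes the
  # center from its neighbors (its neighbors' labels differ only then)
  part1 <- wl_refine(g, 1)$partition
  expect_equal(part1[order(vapply(part1, min, integer(1)))],
               list(c(1L, 5L), c(2L, 3L, 4L)))
  part2 <- wl_refine(g, 2)$partition
  expect_equal(part2[order(vapply(part2, min, integer(1)))],
               list(c(1L, 5L), c(2L, 4L), 3L))
  # benzene: vertex-transitive, one class at any depth
  benz <- mol_to_graph("c1ccccc1")
  for (it in c(0, 1, 5)) {
    expect_length(wl_refine(benz, it)$partition, 1)
  }
})

test_that("equivalence classes partition the atoms and respect element symbols", {
  set.seed(77)
  for (rep in 1:20) {
    g <- random_connected_graph(sample(4:12, 1))
    part <- equivalence_classes(g)
    idx <- sort(unlist(part$classes))
    expect_equal(idx, seq_len(g$atom_count))
    expect_true(all(lengths(part$classes) >= 1))
    for (cl in part$classes) {
      expect_length(unique(g$atom_symbols[cl]), 1)
    }
  }
  # single atom: one singleton class
  expect_equal(equivalence_classes(mol_to_graph("O"))$classes, list(1L))
})

test_that("refining an already-stable coloring changes nothing", {
  g <- mol_to_graph("CC(C)CC(C)C")
  p_stable <- equivalence_classes(g, iterations = 8)
  p_more <- equivalence_classes(g, iterations = 12)
  expect_equal(p_stable$class_of, p_more$class_of)
})

test_that("WL classes are equivariant under atom relabeling", {
  set.seed(13)
  for (rep in 1:10) {
    g <- random_connected_graph(8)
    perm <- sample.int(8)
    pg <- atommatch:::.permute_graph(g, perm)
    cls_g <- equivalence_classes(g)$class_of
    cls_p <- equivalence_classes(pg)$class_of
    # same partition after mapping indices through the permutation
    expect_equal(outer(cls_p[perm], cls_p[perm], "=="),
                 outer(cls_g, cls_g, "=="))
  }
})

test_that("automorphism orbits are always contained in WL classes", {
  set.seed(2024)
  for (rep in 1:40) {
    g <- random_connected_graph(sample(4:12, 1), extra_edges = sample(0:3, 1))
    orbits <- automorphism_orbits(g)
    wl <- equivalence_classes(g)$class_of
    for (orb in orbits) {
      expect_length(unique(wl[orb]), 1)
    }
  }
})

test_that("orbit oracle agrees with brute-force permutation search on tiny graphs", {
  set.seed(5)
  for (rep in 1:5) {
    g <- random_connected_graph(sample(4:6, 1), extra_edges = 1L)
    auts <- brute_force_automorphisms(g)
    # orbit of atom 1 under brute-force automorphisms
    orb1 <- sort(unique(auts[, 1]))
    oracle <- automorphism_orbits(g)
    containing <- oracle[[which(vapply(oracle, function(o) 1L %in% o,
                                       logical(1)))]]
    expect_equal(sort(containing), orb1)
  }
})

test_that("bond-order-aware labels refine the default partition", {
  g <- mol_to_graph("C=CC")  # propene: without bond orders, C1/C3 can merge
  plain <- equivalence_classes(g, use_bond_order = FALSE)
  strict <- equivalence_classes(g, use_bond_order = TRUE)
  expect_gte(length(strict$classes), length(plain$classes))
  for (cl in strict$classes) {
    expect_length(unique(plain$class_of[cl]), 1)
  }
})

test_that("symmetric mapping enumeration matches automorphism structure", {
  # two independent equivalent pairs: exactly 4 mappings incl. identity
  # and the double swap
  rxn <- two_pair_reaction()
  maps <- enumerate_symmetric_mappings(rxn)
  expect_length(maps, 4)
  for (m in maps) {
    expect_true(all(rowSums(m) == 1) && all(colSums(m) == 1))
  }
  perms <- vapply(maps, function(m) paste(apply(m, 1, which.max),
                                          collapse = ","), "")
  n <- rxn$reactants$atom_count
  expect_true(paste(seq_len(n), collapse = ",") %in% perms)  # identity
  swapped <- seq_len(n); swapped[c(1, 3)] <- c(3, 1); swapped[c(5, 6)] <- c(6, 5)
  expect_true(paste(swapped, collapse = ",") %in% perms)     # double swap

  # asymmetric reactant: single mapping
  asym <- identity_reaction("CC(N)C(=O)OCl")
  expect_length(enumerate_symmetric_mappings(asym), 1)

  # benzene identity reaction: |Aut(C6)| = 12, cross-checked against the
  # independent automorphism oracle
  benz <- identity_reaction("c1ccccc1")
  maps_b <- enumerate_symmetric_mappings(benz)
  n_aut <- nrow(brute_force_automorphisms(benz$reactants))
  expect_equal(n_aut, 12)
  expect_length(maps_b, 12)
})

test_that("enumeration aborts above the combinatorial cap", {
  rxn <- identity_reaction("c1ccccc1")
  expect_error(enumerate_symmetric_mappings(rxn, cap = 10), "cap")
})
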