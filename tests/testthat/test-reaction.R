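test_that("reaction records parse, validate and reject dangling references", {
  rec <- parse_reaction_record("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH2:2][OH:3]\t\t\t\t")
  expect_length(rec$edits$lost_h, 0)
  expect_equal(nrow(rec$edits$deleted_bonds), 0)

  line <- "[CH3:1][CH2:2][OH:3]>>[CH3:1][CH2:2][OH:3]\t\t2;3\t2-3\t1-3-single"
  rec <- parse_reaction_record(line)
  expect_equal(rec$edits$gained_h, c(2L, 3L))
  expect_equal(rec$edits$deleted_bonds$i, 2L)
  expect_equal(rec$edits$added_bonds$order, "single")

  expect_error(
    parse_reaction_record("[CH3:1][OH:2]>>[CH3:1][OH:2]\t\t\t\t1-9", 4),
    "9.*line 4")
  expect_error(reaction_edits(deleted_bonds = data.frame(i = 1, j = 2),
                              added_bonds = data.frame(i = 2, j = 1,
                                                       order = "single")),
               "both deleted and added")
})

test_that("empty edits give an identity reaction", {
  rxn <- reaction_from_record("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH2:2][OH:3]\t\t\t\t")
  expect_equal(rxn$gt_matrix, diag(3), ignore_attr = TRUE)
  expect_equal(rxn$products$adjacency, rxn$reactants$adjacency)
})

test_that("applying edits changes exactly the listed structure", {
  gr <- parse_smiles("[CH3:1][CH2:2][CH2:3][OH:4]")
  edits <- reaction_edits(gained_h = c(3L, 4L),
                          deleted_bonds = data.frame(i = 3L, j = 4L))
  gp <- apply_edits(gr, edits)
  expect_equal(gp$adjacency[3, 4], 0L)
  expect_equal(gp$n_h[c(3, 4)], gr$n_h[c(3, 4)] + 1L)
  # inverse edits restore the original adjacency and hydrogens
  inverse <- reaction_edits(lost_h = c(3L, 4L),
                            added_bonds = data.frame(i = 3L, j = 4L,
                                                     order = "single"))
  back <- apply_edits(gp, inverse)
  expect_equal(back$adjacency, gr$adjacency)
  expect_equal(back$n_h, gr$n_h)
  expect_equal(back$atom_features, gr$atom_features)
})

test_that("illegal edits are rejected", {
  gr <- parse_smiles("[CH3:1][O:2][CH3:3]")
  expect_error(apply_edits(gr, reaction_edits(lost_h = 2L)),
               "hydrogen.*none")
  expect_error(apply_edits(gr, reaction_edits(
    added_bonds = data.frame(i = 1L, j = 2L, order = "single"))),
    "duplicates")
  expect_error(apply_edits(gr, reaction_edits(
    deleted_bonds = data.frame(i = 1L, j = 3L))), "not present")
  expect_error(apply_edits(gr, reaction_edits(lost_h = 9L)), "9")
})

test_that("product adjacency equals reactant adjacency XOR the edit set", {
  cfg <- generator_config(n_reactions = 10L, seed = 55L)
  set.seed(55)
  for (rep in 1:15) {
    out <- generate_reaction(cfg, remap_seed = rep)
    rxn <- out$reaction
    # map product atoms back onto reactant order via the gt permutation
    perm <- apply(rxn$gt_matrix, 1, which.max)
    ar <- rxn$reactants$adjacency
    ap <- rxn$products$adjacency[perm, perm]
    diff_pairs <- which(ar != ap & upper.tri(ar), arr.ind = TRUE)
    edit_keys <- character(0)
    maps <- rxn$reactants$map
    del <- rxn$edits$deleted_bonds; add <- rxn$edits$added_bonds
    if (nrow(del)) edit_keys <- c(edit_keys, paste(pmin(del$i, del$j),
                                                   pmax(del$i, del$j)))
    if (nrow(add)) edit_keys <- c(edit_keys, paste(pmin(add$i, add$j),
                                                   pmax(add$i, add$j)))
    got_keys <- paste(pmin(maps[diff_pairs[, 1]], maps[diff_pairs[, 2]]),
                      pmax(maps[diff_pairs[, 1]], maps[diff_pairs[, 2]]))
    expect_setequal(got_keys, edit_keys)
  }
})

test_that("valence validation flags overloaded atoms only", {
  bad <- molgraph(symbols = c("C", rep("O", 5)),
                  bonds = data.frame(i = 1L, j = 2:6, order = "single"))
  res <- validate_product(bad)
  expect_false(res$ok)
  expect_match(res$reasons, "valence", all = FALSE)
  water_like <- mol_to_graph("CO")  # single C-O with filled hydrogens
  expect_true(validate_product(water_like)$ok)
})

test_that("remapping is seeded, composable and preserves correspondence", {
  rxn <- two_pair_reaction()
  r1 <- remap_reaction(rxn, 99L)
  r2 <- remap_reaction(rxn, 99L)
  expect_equal(r1$reactants$atom_symbols, r2$reactants$atom_symbols)
  expect_equal(r1$gt_matrix, r2$gt_matrix)
  # still a permutation matrix and chemically the same correspondence
  expect_true(all(rowSums(r1$gt_matrix) == 1) &&
              all(colSums(r1$gt_matrix) == 1))
  pairs <- which(r1$gt_matrix == 1L, arr.ind = TRUE)
  expect_equal(r1$reactants$map[pairs[, 1]], r1$products$map[pairs[, 2]])
  # adjacency is preserved under the mapping wherever no edit applies
  perm <- apply(r1$gt_matrix, 1, which.max)
  ar <- r1$reactants$adjacency
  ap <- r1$products$adjacency[perm, perm]
  touched <- unique(unlist(r1$edits[c("deleted_bonds", "added_bonds")]))
  untouched <- which(!(r1$reactants$map %in% touched))
  expect_equal(ar[untouched, untouched], ap[untouched, untouched])
})

test_that("double remap equals the composed permutation", {
  rxn <- two_pair_reaction()
  ra <- remap_reaction(rxn, 3L)
  rab <- remap_reaction(ra, 4L)
  # explicit composition oracle on the reactant side: follow map numbers
  p1 <- match(rxn$reactants$map, ra$reactants$map)    # orig idx -> idx in ra
  p2 <- match(ra$reactants$map, rab$reactants$map)
  expect_equal(match(rxn$reactants$map, rab$reactants$map), p2[p1])
  expect_equal(rab$reactants$atom_symbols[p2[p1]], rxn$reactants$atom_symbols)
})

test_that("seeded 70/10/20 splits are exact, disjoint and reproducible", {
  sp <- split_dataset(100L, 7L)
  expect_equal(lengths(sp), c(train = 70L, val = 10L, test = 20L))
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
  expect_identical(split_dataset(100L, 7L), sp)
  expect_false(identical(split_dataset(100L, 8L), sp))
  sp2 <- split_dataset(57L, 1L)
  expect_equal(sum(lengths(sp2)), 57L)
})
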