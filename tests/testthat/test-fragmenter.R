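bond_between <- function(g, el1, el2) {
  # first bond whose endpoint elements match (order-free)
  for (b in seq_len(nrow(g$bonds))) {
    e <- sort(c(g$atoms$element[g$bonds$a1[b]],
                g$atoms$element[g$bonds$a2[b]]))
    if (identical(e, sort(c(el1, el2)))) return(b)
  }
  NA_integer_
}

test_that("breakable-bond rules follow the fragmentation grammar", {
  tol <- parse_smiles("Cc1ccccc1")
  expect_true(is_breakable(tol, bond_between(tol, "C", "C")))  # ring-nonring
  eth <- parse_smiles("CC")
  expect_false(is_breakable(eth, 1L))                          # plain C-C
  ace <- parse_smiles("CC(=O)C")
  cc <- which(ace$bonds$order == 1L)
  expect_true(all(vapply(cc, function(b) is_breakable(ace, b), TRUE)))
  expect_false(is_breakable(ace, which(ace$bonds$order == 2L)))  # C=O itself
  benz <- parse_smiles("c1ccccc1")
  expect_false(any(vapply(seq_len(nrow(benz$bonds)),
                          function(b) is_breakable(benz, b), TRUE)))
  # carbon-heteroatom
  eth_ol <- parse_smiles("CCO")
  expect_true(is_breakable(eth_ol, bond_between(eth_ol, "C", "O")))
  # biphenyl bond joins two rings: no rule fires
  biph <- parse_smiles("c1ccc(-c2ccccc2)cc1")
  nonring <- which(!biph$bonds$ring)
  expect_false(any(vapply(nonring, function(b) is_breakable(biph, b), TRUE)))
  # heteroatom-heteroatom only under the optional switch
  hyd <- parse_smiles("CNNC")
  nn <- bond_between(hyd, "N", "N")
  expect_false(is_breakable(hyd, nn))
  expect_true(is_breakable(hyd, nn, cut_hetero_hetero = TRUE))
})

test_that("hand-worked extractions give the expected occurrences", {
  tol <- extract_substituents("Cc1ccccc1", "tol")
  expect_equal(nrow(tol), 2L)
  expect_same_multiset(tol$smiles, canonical_smiles(c("[*]C",
                                                      "[*]c1ccccc1")))
  expect_equal(tol$att_category[tol$heavy_atoms == 1], "c")
  expect_equal(tol$att_category[tol$heavy_atoms == 6], "C")

  ani <- extract_substituents("COc1ccccc1", "ani")
  expect_equal(nrow(ani), 4L)
  want <- canonical_smiles(c("[*]C", "[*]Oc1ccccc1", "[*]OC",
                             "[*]c1ccccc1"))
  expect_same_multiset(ani$smiles, want)
  expect_equal(ani$att_category[match(want, ani$smiles)],
               c("O", "C", "c", "O"))

  acp <- extract_substituents("CC(=O)c1ccccc1", "acp")
  expect_equal(nrow(acp), 4L)
  want <- canonical_smiles(c("[*]C", "[*]C(=O)C", "[*]C(=O)c1ccccc1",
                             "[*]c1ccccc1"))
  expect_same_multiset(acp$smiles, want)
  expect_equal(acp$att_category[match(want, acp$smiles)],
               c("C(=O)*", "c", "C", "C(=O)*"))

  expect_equal(nrow(extract_substituents("CC", "eth")), 0L)
})

test_that("size cap and symmetry govern which sides are kept", {
  # dodecyl side exceeds the default cap: only the small side remains
  long <- paste0("C", strrep("C", 12), "c1ccccc1")  # 13-carbon chain
  occ <- extract_substituents(long, "m")
  expect_true(all(occ$heavy_atoms <= 12))
  # with a tighter cap both sides of toluene's cut disappear except methyl
  occ2 <- extract_substituents("Cc1ccccc1", "m", max_heavy = 3L)
  expect_equal(occ2$smiles, canonical_smiles("[*]C"))
  # output ordering is canonical
  occ3 <- extract_substituents("CC(=O)c1ccccc1", "m")
  expect_equal(occ3$smiles, sort(occ3$smiles))
})

test_that("corpus aggregation counts molecules and occurrences separately", {
  mols <- c(t1 = "Cc1ccccc1", t2 = "Cc1ccccc1", t3 = "Cc1ccccc1")
  catalog <- fragment_corpus(mols, min_molecule_freq = 2L)
  expect_equal(sort(catalog$smiles),
               sort(canonical_smiles(c("[*]C", "[*]c1ccccc1"))))
  expect_equal(catalog$molecule_frequency, c(3L, 3L))

  # para-xylene: methyl occurs twice in one molecule
  xy <- fragment_corpus(c(x = "Cc1ccc(C)cc1"), min_molecule_freq = 1L)
  me <- xy[xy$smiles == canonical_smiles("[*]C"), ]
  expect_equal(me$molecule_frequency, 1L)
  expect_equal(me$occurrence_count, 2L)
  tolyl <- xy[xy$heavy_atoms == 7L, ]
  expect_equal(tolyl$occurrence_count, 2L)

  empty <- fragment_corpus(character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("corpus catalog equals the union of per-molecule extractions", {
  corp <- generate_corpus(corpus_config(seed = 11, n_molecules = 60))
  catalog <- fragment_corpus(corp, min_molecule_freq = 1L)
  occ <- do.call(rbind, lapply(seq_len(nrow(corp)), function(i)
    extract_substituents(corp$smiles[i], corp$id[i])))
  per_mol <- unique(occ[, c("smiles", "source_id")])
  freq <- table(per_mol$smiles)
  expect_equal(sort(catalog$smiles), sort(names(freq)))
  expect_equal(catalog$molecule_frequency[match(names(freq),
                                                catalog$smiles)],
               as.integer(freq))
  expect_equal(sum(catalog$occurrence_count), nrow(occ))
})

test_that("the common view thresholds without touching raw statistics", {
  mols <- c(a = "Cc1ccccc1", b = "Cc1ccccc1", c = "CCO")
  catalog <- fragment_corpus(mols, min_molecule_freq = 2L)
  common <- common_substituents(catalog)
  expect_true(all(common$molecule_frequency >= 2L))
  expect_gt(nrow(catalog), nrow(common))
  expect_equal(attr(common, "corpus_size"), attr(catalog, "corpus_size"))
})

test_that("bioactive filtering happens upstream of extraction", {
  mols <- data.frame(id = c("a", "b"),
                     smiles = c("Cc1ccccc1", "CCOc1ccccc1"),
                     bioactive = c(TRUE, FALSE))
  catalog <- fragment_corpus(mols, min_molecule_freq = 1L,
                             bioactive_only = TRUE)
  expect_true(all(catalog$smiles %in%
                    extract_substituents("Cc1ccccc1", "a")$smiles))
  expect_error(fragment_corpus(mols[, 1:2], bioactive_only = TRUE),
               "bioactive")
})
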