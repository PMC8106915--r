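test_that("reaction and network constructors enforce their invariants", {
  expect_error(reaction("", "a", "b"), "nonempty")
  expect_error(reaction("r1", character(), character()), "participants")
  r <- reaction("r1", c("b", "a", "a"), "c")
  expect_identical(r$reactants, c("a", "b"))
  expect_false(r$reversible)
  expect_error(
    metabolic_network("n", list(reaction("r1", "a", "b"),
                                reaction("r1", "c", "d"))),
    "duplicate")
  net <- metabolic_network("n", list(reaction("r2", "x", "y"),
                                     reaction("r1", "a", "b")))
  expect_identical(names(net$reactions), c("r1", "r2"))
  expect_identical(compounds(net), c("a", "b", "x", "y"))
})

test_that("seed files are deduplicated and dialect-tolerant", {
  lf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a", "b", "a"), lf)
  expect_identical(read_seeds(lf), c("a", "b"))
  crlf <- withr::local_tempfile(fileext = ".txt")
  writeChar("a\r\nb\r\na\r\n", crlf, eos = NULL)
  expect_identical(read_seeds(crlf), read_seeds(lf))
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_error(read_seeds(empty), "empty medium")
})

test_that("an SBML species list can serve as the seed set", {
  f <- withr::local_tempfile(fileext = ".sbml")
  net <- metabolic_network("medium", list(reaction("r1", "s1", "s2")))
  write_sbml(net, f)
  expect_identical(read_seeds(f), c("s1", "s2"))
})

test_that("SBML read maps reactions, reversibility and annotations", {
  f <- withr::local_tempfile(fileext = ".sbml")
  net <- metabolic_network("toy", list(
    reaction("r1", "a", "b", reversible = FALSE, genes = c("g1", "g2"),
             ec = "1.1.1.1"),
    reaction("r2", "b", "c", reversible = TRUE)))
  write_sbml(net, f)
  back <- read_sbml(f)
  expect_identical(names(back$reactions), c("r1", "r2"))
  expect_identical(compounds(back), c("a", "b", "c"))
  expect_false(back$reactions$r1$reversible)
  expect_true(back$reactions$r2$reversible)
  expect_identical(back$reactions$r1$genes, c("g1", "g2"))
  expect_identical(back$reactions$r1$ec, "1.1.1.1")
  expect_identical(back$reactions$r2$genes, character(0))
})

test_that("fbc gene products are read when no notes line is present", {
  f <- withr::local_tempfile(fileext = ".sbml")
  doc <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1"><model id="m"><listOfSpecies>',
    '<species id="a"/><species id="b"/></listOfSpecies><listOfReactions>',
    '<reaction id="r1" reversible="false">',
    '<fbc:geneProductAssociation><fbc:geneProductRef fbc:geneProduct="gX"/>',
    '</fbc:geneProductAssociation>',
    '<listOfReactants><speciesReference species="a"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>')
  writeLines(doc, f)
  net <- read_sbml(f)
  expect_identical(net$reactions$r1$genes, "gX")
})

test_that("SBML errors name the offending reaction or parse location", {
  f <- withr::local_tempfile(fileext = ".sbml")
  writeLines('<sbml><model><listOfReactions><reaction id="bad"/></listOfReactions></model></sbml>', f)
  expect_error(read_sbml(f), "bad")
  g <- withr::local_tempfile(fileext = ".sbml")
  writeLines("<sbml><model>", g)
  expect_error(read_sbml(g))
  empty_net <- metabolic_network("e", list())
  expect_error(write_sbml(empty_net, f), "nothing to serialize")
})

test_that("SBML and TSV round-trips preserve network content", {
  withr::local_seed(421)
  for (i in 1:50) {
    net <- random_network(sprintf("rt%02d", i), n_rxn = sample(3:30, 1),
                          n_cpd = sample(5:15, 1), gene_prob = 0.8)
    f <- tempfile(fileext = ".sbml")
    write_sbml(net, f)
    back <- read_sbml(f)
    expect_identical(names(back$reactions), names(net$reactions))
    for (id in names(net$reactions)) {
      a <- net$reactions[[id]]; b <- back$reactions[[id]]
      expect_identical(b$reactants, a$reactants)
      expect_identical(b$products, a$products)
      expect_identical(b$reversible, a$reversible)
      expect_identical(b$genes, a$genes)
      expect_identical(b$ec, a$ec)
    }
    unlink(f)
  }
  net <- random_network("tsv", n_rxn = 12, gene_prob = 0.7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, f)
  back <- read_network_tsv(f, id = "tsv")
  expect_equal(back$reactions, net$reactions)
})

test_that("gene-association filtering keeps exactly supported reactions", {
  net <- metabolic_network("n", list(
    reaction("r1", "a", "b", genes = "g1"),
    reaction("r2", "b", "c"),
    reaction("r3", "c", "d", genes = c("g2", "g3"))))
  flt <- filter_gene_associated(net)
  expect_identical(names(flt$reactions), c("r1", "r3"))
  expect_identical(compounds(flt), c("a", "b", "c", "d"))
  expect_equal(filter_gene_associated(flt), flt)   # idempotent
  allg <- metabolic_network("n", list(reaction("r1", "a", "b", genes = "g")))
  expect_equal(filter_gene_associated(allg), allg) # identity case
  none <- metabolic_network("n", list(reaction("r1", "a", "b")))
  expect_warning(out <- filter_gene_associated(none), "no reaction")
  expect_length(out$reactions, 0)
})

test_that("filtering is monotone on random networks", {
  withr::local_seed(99)
  for (i in 1:20) {
    net <- random_network("f", n_rxn = 15, gene_prob = 0.5)
    flt <- suppressWarnings(filter_gene_associated(net))
    expect_true(all(names(flt$reactions) %in% names(net$reactions)))
  }
})

test_that("network merging follows union-by-id semantics", {
  a <- metabolic_network("A", list(reaction("r1", "a", "b", genes = "g1"),
                                   reaction("r2", "b", "c")))
  b <- metabolic_network("B", list(
    reaction("r2", "b", "c", reversible = TRUE, genes = "g9"),
    reaction("r3", "c", "d")))
  m <- merge_networks(list(a, b))
  expect_identical(names(m$reactions), c("r1", "r2", "r3"))
  expect_true(m$reactions$r2$reversible)      # OR rule
  expect_identical(m$reactions$r2$genes, "g9")
  expect_equal(merge_networks(list(a, a))$reactions, a$reactions) # idempotent
  m2 <- merge_networks(list(b, a))
  expect_equal(m2$reactions, m$reactions)     # commutative up to OR rule
  conflict <- metabolic_network("C", list(reaction("r1", "x", "y")))
  expect_error(merge_networks(list(a, conflict)), "r1")
})

test_that("merged reaction counts obey set algebra on random pairs", {
  withr::local_seed(7)
  for (i in 1:25) {
    a <- random_network("A", n_rxn = sample(3:12, 1))
    fresh <- random_network("B", n_rxn = sample(3:12, 1))
    shared <- sample(a$reactions, sample(0:length(a$reactions), 1))
    b <- metabolic_network("B", c(unname(shared), unname(fresh$reactions)))
    m <- merge_networks(list(a, b))
    expect_length(m$reactions,
                  length(names(a$reactions)) + length(names(b$reactions)) -
                    length(intersect(names(a$reactions),
                                     names(b$reactions))))
  }
})

test_that("presence matrix rows mirror each network's reaction set", {
  a <- random_network("A", n_rxn = 8, pipeline = "p1")
  b <- random_network("B", n_rxn = 5, pipeline = "p1")
  b2 <- metabolic_network("B", unname(b$reactions), "p2")
  pm <- reaction_presence_matrix(list(a, b, b2))
  expect_identical(rownames(pm), c("A|p1", "B|p1", "B|p2"))
  expect_identical(colnames(pm), sort(colnames(pm)))
  expect_equal(unname(rowSums(pm)),
               c(length(a$reactions), length(b$reactions),
                 length(b2$reactions)))
  expect_identical(unname(pm["B|p1", ]), unname(pm["B|p2", ]))
  single <- reaction_presence_matrix(list(a))
  expect_true(all(single))
  expect_error(reaction_presence_matrix(list(a, a)), "duplicate")
})
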