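sn2 <- "[CH3:1][Br:2].[OH-:3]>>[CH3:1][OH:3].[Br-:2]"

test_that("reaction SMILES parsing handles well-formed input and rejects bad input", {
  rx <- parse_reaction(sn2)
  expect_s3_class(rx, "reaction")
  expect_length(rx$reactants, 2L)
  expect_length(rx$products, 2L)
  expect_equal(sum(vapply(rx$reactants, function(m) nrow(m$atoms), integer(1))), 3L)

  # agents field is ignored
  rx2 <- parse_reaction("[CH3:1][Br:2].[OH-:3]>O>[CH3:1][OH:3].[Br-:2]")
  expect_equal(signature_set(rx2), signature_set(rx))

  expect_error(parse_reaction(""), "parse error")
  expect_error(parse_reaction("[CH3:1][Br:2]>>[CH3:1][OH:3].[Br-:2]"),
               "mapping error.*3")
  expect_error(parse_reaction("[CH3:1][CH3:1]>>[CH3:1][CH3:1]"),
               "mapping error")
  expect_error(parse_reaction("[CH3:1][Br:2].[OH-]>>[CH3:1][OH:3].[Br-:2]"),
               "unmapped")
  expect_error(parse_reaction("c1ccc1x>>c1ccc1x"), "parse error")
})

test_that("CGR superposition records before/after bond orders and charges", {
  g <- build_cgr(sn2)
  b <- g$bonds
  cbr <- b[b$a1 == 1 & b$a2 == 2, ]
  expect_equal(cbr$order_before, "single")
  expect_equal(cbr$order_after, "none")
  co <- b[b$a1 == 1 & b$a2 == 3, ]
  expect_equal(co$order_before, "none")
  expect_equal(co$order_after, "single")
  a <- g$atoms
  expect_equal(a$charge_before[a$map == 3], -1L)
  expect_equal(a$charge_after[a$map == 3], 0L)
  expect_equal(a$charge_before[a$map == 2], 0L)
  expect_equal(a$charge_after[a$map == 2], -1L)
  expect_true(all(a$dynamic))

  id <- build_cgr("[CH4:1]>>[CH4:1]")
  expect_equal(sum(id$atoms$dynamic), 0L)
  expect_equal(sum(id$bonds$dynamic), 0L)

  expect_error(build_cgr("[CH3:1][Br:2].[OH-:3]>>[CH3:1][OH:2].[Br-:3]"),
               "inconsistent mapping")
})

test_that("zwitterion-type tautomerism gives dynamic atoms but no dynamic bonds", {
  z <- build_cgr(paste0("[NH3+:1][CH2:2][C:3](=[O:4])[O-:5]>>",
                        "[NH2:1][CH2:2][C:3](=[O:4])[OH:5]"))
  expect_equal(sum(z$bonds$dynamic), 0L)
  expect_equal(sort(z$atoms$map[z$atoms$dynamic]), c(1L, 5L))
  expect_length(find_reaction_centers(z), 2L)
})

test_that("reaction centers are connected components of the dynamic subgraph", {
  ct <- find_reaction_centers(build_cgr(sn2))
  expect_length(ct, 1L)
  expect_equal(ct[[1]]$atoms, c(1L, 2L, 3L))

  expect_length(find_reaction_centers(build_cgr("[CH4:1]>>[CH4:1]")), 0L)

  double <- paste0("[CH3:1][Cl:2].[CH3:4][Cl:5].[OH-:3].[OH-:6]>>",
                   "[CH3:1][OH:3].[Cl-:2].[CH3:4][OH:6].[Cl-:5]")
  ct2 <- find_reaction_centers(build_cgr(double))
  expect_length(ct2, 2L)
  # centers sorted by smallest contained map; atom union = dynamic atoms
  expect_equal(ct2[[1]]$atoms, c(1L, 2L, 3L))
  expect_equal(ct2[[2]]$atoms, c(4L, 5L, 6L))
})

test_that("hybridization perception distinguishes sp3/sp2/sp/aromatic", {
  ethene <- parse_reaction("[CH2:1]=[CH2:2]>>[CH2:1]=[CH2:2]")$reactants[[1]]
  expect_equal(perceive_hybridization(ethene), c("sp2", "sp2"))
  benz <- parse_reaction(paste0("[cH:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1>>",
                                "[cH:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1"))
  expect_equal(unique(perceive_hybridization(benz$reactants[[1]])), "aromatic")
  allene <- parse_reaction("[CH2:1]=[C:2]=[CH2:3]>>[CH2:1]=[C:2]=[CH2:3]")
  expect_equal(perceive_hybridization(allene$reactants[[1]])[2], "sp")
  alkyne <- parse_reaction("[CH:1]#[CH:2]>>[CH:1]#[CH:2]")
  expect_equal(perceive_hybridization(alkyne$reactants[[1]]), c("sp", "sp"))
})

test_that("signatures are invariant to atom-map relabelling", {
  set.seed(11)
  suites <- builtin_suites()
  examples <- unlist(lapply(names(suites), function(nm)
    generate_reactions(suites[[nm]], n = 4, seed = 20)$reaction))
  for (smi in examples) {
    ref <- signature_set(smi, radius = 1)
    for (rep in 1:20) {
      expect_identical(signature_set(shuffle_maps(smi), radius = 1), ref)
    }
  }
})

test_that("radius-R neighbourhoods nest and R=0 depends only on the center", {
  smi <- "[CH3:9][CH2:4][CH2:1][Br:2].[OH-:3]>>[CH3:9][CH2:4][CH2:1][OH:3].[Br-:2]"
  g <- build_cgr(smi)
  ct <- find_reaction_centers(g)[[1]]
  prev <- NULL
  for (r in 0:4) {
    nb <- reactAD:::neighborhood_maps(g, ct$atoms, r)
    if (!is.null(prev)) expect_true(all(prev %in% nb))
    prev <- nb
  }
  # ethyl vs propyl substrate: identical center environment at R = 0,
  # different first shell at R = 1
  ethyl <- "[CH3:4][CH2:1][Br:2].[OH-:3]>>[CH3:4][CH2:1][OH:3].[Br-:2]"
  expect_identical(signature_set(ethyl, 0), signature_set(smi, 0))
  expect_false(identical(signature_set(ethyl, 1), signature_set(smi, 1)))
  # chloride vs bromide leaving group differ at any radius
  chl <- "[CH3:4][CH2:1][Cl:2].[OH-:3]>>[CH3:4][CH2:1][OH:3].[Cl-:2]"
  for (r in 0:2)
    expect_false(identical(signature_set(chl, r), signature_set(ethyl, r)))
})

test_that("the union of center atoms equals the set of dynamic atoms", {
  suites <- builtin_suites()
  for (nm in names(suites)) {
    for (smi in generate_reactions(suites[[nm]], n = 5, seed = 3)$reaction) {
      g <- build_cgr(smi)
      ct <- find_reaction_centers(g)
      expect_equal(sort(unique(unlist(lapply(ct, `[[`, "atoms")))),
                   sort(g$atoms$map[g$atoms$dynamic]))
    }
  }
})

test_that("signature sets have one signature per center", {
  expect_length(signature_set(sn2, 1), 1L)
  expect_length(signature_set("[CH4:1]>>[CH4:1]"), 0L)
  double <- paste0("[CH3:1][Cl:2].[CH3:4][Cl:5].[OH-:3].[OH-:6]>>",
                   "[CH3:1][OH:3].[Cl-:2].[CH3:4][OH:6].[Cl-:5]")
  # two isomorphic centers collapse to one unique string; a mixed-halide
  # variant keeps two
  expect_length(signature_set(double, 1), 1L)
  mixed <- paste0("[CH3:1][Cl:2].[CH3:4][Br:5].[OH-:3].[OH-:6]>>",
                  "[CH3:1][OH:3].[Cl-:2].[CH3:4][OH:6].[Br-:5]")
  expect_length(signature_set(mixed, 1), 2L)
})

test_that("canonical string equality agrees with brute-force graph isomorphism", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    g <- random_labeled_graph(n)
    perm <- sample(n)
    gp <- permute_graph(g, perm)
    expect_true(iso_oracle(g, gp))
    expect_identical(graph_string(g), graph_string(gp))
    # mutate one atom label; strings must differ iff not isomorphic
    g2 <- g
    g2$labels[1] <- if (g$labels[1] == "A") "B" else "A"
    expect_equal(graph_string(g) == graph_string(g2), iso_oracle(g, g2))
  }
})
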