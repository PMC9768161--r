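test_that("parsing the 3-reaction toy recovers every field", {
  m <- parse_metatool(toy3_text())
  expect_identical(m$reaction_ids, c("r2", "r1", "r3"))
  expect_identical(m$reversible, c(TRUE, FALSE, FALSE))
  expect_identical(m$metabolite_ids, c("A", "B", "Sext", "Pext"))
  expect_identical(m$is_internal, c(TRUE, TRUE, FALSE, FALSE))
  S <- stoich_matrix(m)
  expect_equal(S["A", "r1"], 1)
  expect_equal(S["Sext", "r1"], -1)
  expect_equal(S["A", "r2"], -1)
  expect_equal(S["B", "r2"], 1)
  expect_equal(S["Pext", "r3"], 1)
  expect_equal(sum(S != 0), 6)
  # internal submatrix dimensions
  expect_identical(dim(stoich_matrix(m, internal_only = TRUE)), c(2L, 3L))
})

test_that("all five headers with empty bodies give a valid degenerate model", {
  m <- parse_metatool(empty_metatool_text())
  expect_length(m$reaction_ids, 0)
  expect_length(m$metabolite_ids, 0)
})

test_that("parsing is insensitive to section order, blanks, comments and spelling", {
  base <- parse_metatool(toy3_text())
  shuffled <- c("-CAT", "r1 : Sext = A", "r2 : A = B", "r3 : B = Pext",
                "  ", "-METEXT", "Sext Pext", "-ENZIRREV", "r1 r3",
                "# comment", "-METINT", "A B", "-ENZREV", "r2   ")
  m <- parse_metatool(shuffled)
  expect_identical(m$stoich_num[m$metabolite_ids, m$reaction_ids],
                   base$stoich_num[base$metabolite_ids, base$reaction_ids])
  # coefficient spellings: "2 A", "2A", fraction, decimal
  spellings <- c("-ENZREV", "", "-ENZIRREV", "r1", "-METINT", "A B",
                 "-METEXT", "X", "-CAT", "r1 : 2A + 3/2 B = 0.5 X .")
  m2 <- parse_metatool(spellings)
  expect_equal(m2$stoich_num["A", "r1"] / m2$stoich_den["A", "r1"], -2)
  expect_equal(m2$stoich_num["B", "r1"] / m2$stoich_den["B", "r1"], -1.5)
  expect_equal(m2$stoich_num["X", "r1"] / m2$stoich_den["X", "r1"], 0.5)
  # decimals are stored as exact rationals
  expect_equal(unname(m2$stoich_num["X", "r1"]), 1)
  expect_equal(unname(m2$stoich_den["X", "r1"]), 2)
})

test_that("parse errors name the offending line or entity", {
  bad_met <- c(toy3_text(), "r9 : A = B")
  expect_error(parse_metatool(sub("r3 : B = Pext", "r3 : B = Qext",
                                  toy3_text())), "Qext")
  expect_error(parse_metatool(c("-ENZREV", "r1", "-ENZIRREV", "r1",
                                "-METINT", "-METEXT", "A", "-CAT",
                                "r1 : = A")), "duplicate reaction")
  expect_error(parse_metatool(toy3_text()[-1:-2][-1]), "missing section")
  expect_error(parse_metatool(bad_met), "r9")
})

test_that("write/parse is the identity on models, including fractions", {
  m <- parse_metatool(toy3_text())
  m2 <- parse_metatool(write_metatool(m))
  expect_identical(m2$reaction_ids, m$reaction_ids)
  expect_identical(m2$reversible, m$reversible)
  expect_identical(m2$stoich_num, m$stoich_num)
  expect_identical(m2$stoich_den, m$stoich_den)
  # property: random generated models round-trip exactly
  for (seed in 1:15) {
    toy <- make_toy_network("random_sparse", n = 4, n_extra = 4,
                            rev_fraction = 0.4, seed = seed)$model
    rt <- parse_metatool(write_metatool(toy))
    expect_identical(rt$stoich_num, toy$stoich_num)
    expect_identical(rt$stoich_den, toy$stoich_den)
    expect_identical(rt$reversible, toy$reversible)
    expect_identical(rt$is_internal, toy$is_internal)
  }
  # fractional coefficients survive the round trip as exact rationals
  frac <- parse_metatool(c("-ENZREV", "", "-ENZIRREV", "r1 r2", "-METINT",
                           "A", "-METEXT", "S P", "-CAT",
                           "r1 : S = 3/2 A", "r2 : A = 0.25 P"))
  rt <- parse_metatool(write_metatool(frac))
  expect_identical(rt$stoich_num, frac$stoich_num)
  expect_identical(rt$stoich_den, frac$stoich_den)
})

test_that("validate_model reports dead ends, empty reactions and bad substrates", {
  clean <- parse_metatool(toy3_text())
  expect_identical(nrow(validate_model(clean)), 0L)

  # internal metabolite only produced, never consumed
  dead <- parse_metatool(c("-ENZREV", "", "-ENZIRREV", "r1 r2", "-METINT",
                           "A D", "-METEXT", "S P", "-CAT",
                           "r1 : S = A + D", "r2 : A = P"))
  rep <- validate_model(dead)
  expect_true("D" %in% rep$item[rep$type == "dead_end_metabolite"])

  # substrate MW on an exchange reaction that only produces (never consumes)
  # an external metabolite: constructible, but flagged as a non-uptake
  m <- make_toy_network("diamond")$model
  m2 <- apply_sidecar(m, list(substrates = c(b_out = 100),
                              exchange_map = m$exchange_map))
  rep2 <- validate_model(m2)
  expect_true("b_out" %in% rep2$item[rep2$type == "substrate_not_uptake"])
  # a substrate on a purely internal reaction is rejected outright
  expect_error(apply_sidecar(m, list(substrates = c(ab = 100))),
               "no external metabolite")

  # declared reaction absent from CAT has all-zero stoichiometry
  empty_rxn <- parse_metatool(c("-ENZREV", "", "-ENZIRREV", "r1 r2 ghost",
                                "-METINT", "A", "-METEXT", "S P", "-CAT",
                                "r1 : S = A", "r2 : A = P"))
  expect_true("ghost" %in% validate_model(empty_rxn)$item)
})

test_that("reversible splitting doubles reversible reactions and recombines signs", {
  m <- parse_metatool(toy3_text())       # 1 reversible + 2 irreversible
  sp <- split_reversible(m)
  expect_length(sp$model$reaction_ids, 4)
  expect_false(any(sp$model$reversible))
  j <- match("r2", m$reaction_ids)
  expect_identical(sp$model$stoich_num[, sp$backward[j]],
                   -m$stoich_num[, j])
  # internal stoichiometric rank is preserved
  expect_identical(qr(stoich_matrix(m, internal_only = TRUE))$rank,
                   qr(stoich_matrix(sp$model, internal_only = TRUE))$rank)

  v <- numeric(4); v[sp$forward[j]] <- 2
  expect_equal(unname(recombine_fluxes(v, sp)[["r2"]]), 2)
  v <- numeric(4); v[sp$backward[j]] <- 3
  expect_equal(unname(recombine_fluxes(v, sp)[["r2"]]), -3)
  v[sp$forward[j]] <- 1
  expect_error(recombine_fluxes(v, sp), "both directions")

  # no reversible reactions: identical model, identity mapping
  irr <- make_toy_network("chain", n = 3)$model
  sp2 <- split_reversible(irr)
  expect_identical(sp2$model$stoich_num, irr$stoich_num)
  expect_true(all(is.na(sp2$backward)))
})

test_that("sidecar and gene-map files round-trip through their readers", {
  dir <- withr::local_tempdir()
  side_path <- file.path(dir, "side.yaml")
  yaml::write_yaml(list(substrates = list(up = 100),
                        exchange_map = list(up = "S", b_out = "B")),
                   side_path)
  side <- read_sidecar(side_path)
  expect_equal(side$substrates, c(up = 100))
  expect_equal(side$exchange_map, c(up = "S", b_out = "B"))
  m <- apply_sidecar(make_toy_network("diamond")$model, side)
  expect_equal(m$substrates, c(up = 100))

  gm_path <- file.path(dir, "genes.tsv")
  writeLines(c("reaction\tgene", "ab\tShmt2", "ab\tAmt", "ac\tAcly"), gm_path)
  gm <- read_gene_map(gm_path)
  expect_identical(gm$ab, c("Shmt2", "Amt"))
  m2 <- set_gene_map(m, gm)
  expect_identical(m2$gene_map$ac, "Acly")
  # unknown reaction in the map is rejected
  expect_error(set_gene_map(m, list(zz = "Shmt2")), "undeclared reaction")
})

test_that("model invariants are enforced by the constructor", {
  expect_error(metabolic_model(c("r1", "r1"), c(FALSE, FALSE), "A", TRUE,
                               matrix(0, 1, 2)), "duplicate reaction")
  expect_error(metabolic_model("r1", FALSE, c("A", "A"), c(TRUE, TRUE),
                               matrix(0, 2, 1)), "duplicate metabolite")
  expect_error(metabolic_model("r1", FALSE, "A", TRUE, matrix(0, 2, 1)),
               "metabolites")
  expect_error(metabolic_model("r1", FALSE, "A", FALSE,
                               matrix(-1, 1, 1), substrates = c(r1 = -5)),
               "> 0")
})
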