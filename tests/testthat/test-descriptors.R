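# frozen panel descriptor values, derived by manual path enumeration on the
# assembled structures and cross-checked below against a BFS oracle
dis_backbone <- as.integer(c(25, 25, 30, 30, 30, 28, 28, 28, 28, 28, 28, 21,
                             28, 30, 30, 26, 28, 27, 30, 29, 26, 26, 23))
dis_shortest <- as.integer(c(24, 24, 28, 28, 28, 27, 27, 27, 27, 27, 27, 20,
                             25, 28, 28, 24, 26, 25, 28, 27, 24, 24, 21))
trl2_expected <- as.integer(c(0, 0, 1, 1, 1, 0, 0, 0, 0, 1, 1, 0, 1, 1, 1, 1,
                              1, 1, 1, 1, 1, 1, 1))
am2n_expected <- as.integer(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 1, 0,
                              1, 1, 0, 0, 0, 0, 0))

test_that("guanidine anchors: exactly two, oriented arm-to-anchor, cap-invariant", {
  g <- assemble_graph("Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg")
  anch <- guanidine_anchors(g)
  expect_match(anch[["n_side"]], "^t1\\.b:")   # homoarginine branch
  expect_match(anch[["c_side"]], "^t4:CZ$")    # C-terminal arginine
  gf <- assemble_graph("Lys(Fmoc-Har)-GlyΨ[Trl]GlyΨ[Trl]Arg")
  expect_identical(unname(guanidine_anchors(gf)), unname(anch))
  expect_error(guanidine_anchors(assemble_graph("Arg")), "exactly 2 guanidine")
  expect_error(guanidine_anchors(assemble_graph("Lys-Arg")), "exactly 2 guanidine")
})

test_that("panel distances match frozen values under both ring conventions", {
  panel <- panel_fixture()
  for (i in seq_len(nrow(panel))) {
    g <- assemble_graph(panel$sequence[i])
    expect_identical(dis_guanidine(g, "backbone"), dis_backbone[i],
                     info = panel$sequence[i])
    expect_identical(dis_guanidine(g, "shortest"), dis_shortest[i],
                     info = panel$sequence[i])
  }
})

test_that("distances agree with an all-pairs BFS oracle on every panel graph", {
  panel <- panel_fixture()
  for (i in seq_len(nrow(panel))) {
    g <- assemble_graph(panel$sequence[i])
    anch <- guanidine_anchors(g)
    # shortest convention on the full graph
    expect_identical(
      topological_distance(g, anch[1], anch[2], "shortest", "bonds"),
      as.integer(bfs_bonds(g$bonds, anch[[1]], anch[[2]])))
    # backbone convention = BFS on the graph without ring C5 atoms
    g2 <- drop_ring_c5(g)
    expect_identical(
      topological_distance(g, anch[1], anch[2], "backbone", "bonds"),
      as.integer(bfs_bonds(g2$bonds, anch[[1]], anch[[2]])))
  }
  # full all-pairs check on a representative graph
  g <- assemble_graph("Lys(Fmoc-Har)-GlyΨ[Trl]GlyΨ[Trl]Arg")
  ids <- g$atoms$id
  for (a in ids[seq(1, length(ids), by = 7)]) {
    oracle <- bfs_all_from(g$bonds, a)
    for (b in ids) {
      expect_identical(
        topological_distance(g, a, b, "shortest", "bonds"),
        as.integer(oracle[[b]]))
    }
  }
})

test_that("distance is symmetric, zero on the diagonal, and validates input", {
  g <- assemble_graph("Har-GlyΨ[Trl]Arg")
  a <- "t1:CZ2"; b <- "t3:CZ"
  expect_identical(topological_distance(g, a, b),
                   topological_distance(g, b, a))
  expect_identical(topological_distance(g, a, a), 0L)
  expect_error(topological_distance(g, a, "nope:X"), "not present")
})

test_that("adding a triazole unit strictly increases the guanidine distance", {
  shorter <- assemble_graph("Lys(Har)-GlyΨ[Trl]Arg")
  longer <- assemble_graph("Lys(Har)-GlyΨ[Trl]GlyΨ[Trl]Arg")
  for (conv in c("backbone", "shortest")) {
    d1 <- dis_guanidine(shorter, conv)
    d2 <- dis_guanidine(longer, conv)
    expect_true(d2 > d1)
  }
  # insertion arithmetic: 4 atoms (CH2, C4, C5, N1) on the short walk,
  expect_identical(dis_guanidine(longer, "shortest"),
                   dis_guanidine(shorter, "shortest") + 4L)  # 5 on the long walk
  expect_identical(dis_guanidine(longer, "backbone"),
                   dis_guanidine(shorter, "backbone") + 5L)
})

test_that("binary indicators reproduce the panel assignment structurally", {
  panel <- panel_fixture()
  for (i in seq_len(nrow(panel))) {
    seq <- parse_sequence(panel$sequence[i])
    expect_identical(indicator_trl2_cn(seq), trl2_expected[i],
                     info = panel$sequence[i])
    expect_identical(indicator_am2n(seq), am2n_expected[i],
                     info = panel$sequence[i])
  }
  expect_identical(indicator_trl2_cn("Lys-Ala-Gly-Arg"), 0L)  # pure peptide
  expect_error(indicator_trl2_cn("Lys-Arg"), "fewer than 2")
  # fully capped arm with no other amine
  expect_identical(indicator_am2n("Fmoc-Har-Gly-GlyΨ[Trl]Arg"), 0L)
})

test_that("descriptor matrix: normalisation, ordering and overrides", {
  panel <- panel_fixture()
  d <- build_descriptor_matrix(panel[, c("id", "sequence")])
  expect_identical(nrow(d), 23L)
  expect_equal(min(d$dis_N_C_norm), 0)
  expect_equal(max(d$dis_N_C_norm), 1)
  expect_true(all(d$Trl2_CN %in% 0:1) && all(d$am_2N %in% 0:1))
  expect_identical(attr(d, "norm_range"), range(dis_backbone))

  # permuting compound order leaves per-compound values unchanged
  perm <- rev(seq_len(23))
  dp <- build_descriptor_matrix(panel[perm, c("id", "sequence")])
  expect_equal(dp[order(as.integer(dp$id)), ],
               d[order(as.integer(d$id)), ], ignore_attr = TRUE)

  # override column
  dov <- build_descriptor_matrix(panel[, c("id", "sequence")],
                                 am_2N_override = c(`14` = 0, `15` = 0))
  expect_identical(dov$am_2N[dov$id %in% c("14", "15")], c(0L, 0L))
  expect_identical(dov$am_2N[dov$id == "3"], 1L)

  # degenerate normalisation: single compound
  d1 <- build_descriptor_matrix(panel[3, c("id", "sequence")])
  expect_identical(d1$dis_N_C_norm, 0)
  expect_true(attr(d1, "degenerate_norm"))

  # a compound without two guanidines is reported, not dropped
  bad <- data.frame(id = c("3", "x"),
                    sequence = c(panel$sequence[3], "Lys-Gly-Arg"))
  expect_error(build_descriptor_matrix(bad), "x:.*guanidine")
})

test_that("min-max normalisation is invariant to the atoms-vs-bonds counting convention", {
  panel <- panel_fixture()
  d_between <- build_descriptor_matrix(panel[, c("id", "sequence")],
                                       count = "between")
  d_bonds <- build_descriptor_matrix(panel[, c("id", "sequence")],
                                     count = "bonds")
  expect_identical(d_bonds$dis_N_C, d_between$dis_N_C + 1L)
  expect_equal(d_bonds$dis_N_C_norm, d_between$dis_N_C_norm, tolerance = 1e-12)
})
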