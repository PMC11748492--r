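test_that("RED endpoints and the 4-leaf hand recursion are exact", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
  red <- red_values(tr)
  expect_equal(unname(red[c("A", "B", "C", "D")]), rep(1, 4))
  # the root is the first internal node in ape numbering
  expect_equal(unname(red["node_1"]), 0)
  # internal nodes: d = 1 to the root, mean node-to-tip distance u = 1
  expect_equal(unname(red[c("node_2", "node_3")]), c(0.5, 0.5))
})

test_that("RED is monotone along paths and invariant to leaf order", {
  set.seed(5)
  tr <- ape::rcoal(20)
  red <- red_values(tr)
  parent <- integer(20 + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  ids <- c(tr$tip.label, paste0("node_", seq_len(tr$Nnode)))
  for (child in tr$edge[, 2])
    expect_gte(red[[ids[child]]], red[[ids[parent[child]]]])
  expect_true(all(red >= 0 & red <= 1))
  # rewrite the newick with rotated clades: same RED per tip/clade set
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  red2 <- red_values(tr2)
  expect_equal(sort(unname(red2)), sort(unname(red)))

  expect_error(red_values(ape::unroot(tr)), "rooted")
  trneg <- tr; trneg$edge.length[1] <- -0.1
  expect_error(red_values(trneg), "negative")
})

test_that("clade delimitation respects the boundary rule and long branches", {
  # clade node: red 2/2.5 = 0.8; its parent is the root (red 0)
  tr <- ape::read.tree(
    text = "(out:3,(A:0.5,B:0.5,C:0.5,D:0.5)cl:2)r;")
  red <- red_values(tr)
  cl <- define_clades(tr, red, threshold = 0.65)
  expect_equal(length(cl$clades), 1L)
  expect_setequal(cl$clades[[1]], c("A", "B", "C", "D"))
  # the long-branch leaf belongs to no clade
  expect_equal(cl$unassessed, "out")
  # threshold 0: one clade holding every leaf
  cl0 <- define_clades(tr, red, threshold = 0)
  expect_equal(length(cl0$clades), 1L)
  expect_setequal(cl0$clades[[1]], tr$tip.label)
  expect_equal(cl0$unassessed, character())
})

test_that("clade core genes use the strict majority and modal copies", {
  og <- rbind(
    data.frame(genome_id = sprintf("g%02d", 1:6), og_id = "OG1",
               copy_count = c(1L, 1L, 1L, 2L, 2L, 1L)),   # 6/10 genomes
    data.frame(genome_id = sprintf("g%02d", 1:5), og_id = "OG2",
               copy_count = 1L),                           # 5/10: not core
    data.frame(genome_id = sprintf("g%02d", 1:10), og_id = "OG3",
               copy_count = rep(c(1L, 2L), 5)))            # tied mode
  clade <- clade_core(og, sprintf("g%02d", 1:10))
  expect_setequal(clade$core_ogs, c("OG1", "OG3"))
  expect_equal(unname(clade$mode_copy["OG1"]), 1L)
  # tie in the mode breaks to the smaller copy number
  expect_equal(unname(clade$mode_copy["OG3"]), 1L)
  expect_error(clade_core(og, character()), "empty")
  expect_error(clade_core(og, "g01"), "2 members")
})

test_that("consistency and redundancy ratios match hand arithmetic", {
  members <- sprintf("g%02d", 1:4)
  og <- do.call(rbind, lapply(members, function(g)
    data.frame(genome_id = g, og_id = sprintf("OG%02d", 1:12),
               copy_count = 1L)))
  clade <- clade_core(og, members)
  expect_equal(length(clade$core_ogs), 12L)
  # full modal genome: (1, 0)
  s <- score_mag("g01", og, clade)
  expect_equal(s$consistency, 1)
  expect_equal(s$redundancy, 0)
  # genome with 10 of 12 core OGs, all modal: 0.8333, 0
  og2 <- rbind(og, data.frame(genome_id = "g05",
                              og_id = sprintf("OG%02d", 1:10),
                              copy_count = 1L))
  s2 <- score_mag("g05", og2, clade)
  expect_equal(s2$consistency, 10 / 12, tolerance = 1e-9)
  expect_equal(s2$redundancy, 0)
  # one OG at 3 copies against mode 1: redundancy (3-1)/10
  og3 <- og2
  og3$copy_count[og3$genome_id == "g05" & og3$og_id == "OG01"] <- 3L
  s3 <- score_mag("g05", og3, clade)
  expect_equal(s3$redundancy, 0.2)
  expect_error(score_mag("missing", og, clade), "absent")
})

test_that("scores are invariant to OG-table row order", {
  fx <- sim_clade_fixture(n_genomes = 8, n_core = 12, dropout = 0.25,
                          dup_rate = 0.2, seed = 13)
  pa1 <- pima_assess(fx$tree, fx$og_table)
  set.seed(4)
  shuf <- fx$og_table[sample(nrow(fx$og_table)), ]
  pa2 <- pima_assess(fx$tree, shuf)
  o1 <- pa1$scores[order(pa1$scores$genome_id), ]
  o2 <- pa2$scores[order(pa2$scores$genome_id), ]
  expect_equal(o1$consistency, o2$consistency)
  expect_equal(o1$redundancy, o2$redundancy)
})

test_that("planted dropout is recovered as mean consistency", {
  # a genome clade built solely from copies of itself scores (1, 0)
  fx0 <- sim_clade_fixture(n_genomes = 6, n_core = 15, dropout = 0,
                           dup_rate = 0, seed = 21)
  pa0 <- pima_assess(fx0$tree, fx0$og_table)
  expect_equal(pa0$scores$consistency, rep(1, 6))
  expect_equal(pa0$scores$redundancy, rep(0, 6))
  expect_true("outgroup" %in% pa0$unassessed)
  # dropout shifts mean consistency to 1 - d; a clade large enough that
  # no core OG loses its strict majority
  fx <- sim_clade_fixture(n_genomes = 40, n_core = 12, dropout = 2 / 12,
                          dup_rate = 0, seed = 22)
  pa <- pima_assess(fx$tree, fx$og_table)
  expect_equal(mean(pa$scores$consistency), 1 - 2 / 12, tolerance = 0.02)
})
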