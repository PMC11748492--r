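# A small deterministic bin for rule-level tests.
make_bin <- function(scores, coverages = NULL, lengths = NULL,
                     markers = NULL, species = NULL, tetra = NULL,
                     bin_id = "b1") {
  n <- length(scores)
  if (is.null(coverages)) coverages <- rep(10, n)
  if (is.null(lengths)) lengths <- rep(10000L, n)
  contigs <- data.frame(contig_id = sprintf("c%02d", seq_len(n)),
                        length = lengths, coverage = coverages,
                        char_score = as.integer(scores),
                        stringsAsFactors = FALSE)
  if (!is.null(species)) contigs$species <- species
  if (!is.null(tetra)) rownames(tetra) <- contigs$contig_id
  gv_bin(bin_id, contigs, tetra = tetra, markers = markers)
}

uniform_tetra <- function(n, jitter = 0) {
  m <- matrix(1 / 136, n, 136)
  if (jitter > 0) {
    set.seed(11)
    m <- m * exp(matrix(rnorm(n * 136, 0, jitter), n, 136))
    m <- m / rowSums(m)
  }
  m
}

test_that("characteristic score adds tool votes and the HMM point", {
  expect_equal(characteristic_score(rep("target_lineage", 3), TRUE), 4L)
  expect_equal(characteristic_score(rep("none", 3), FALSE), 0L)
  expect_equal(characteristic_score(c("target_lineage", "other", "none"),
                                    TRUE), 2L)
  expect_error(characteristic_score(rep("target_lineage", 4), TRUE),
               "three")
  v <- data.frame(contig_id = c("c1", "c1", "c2"),
                  tool_name = c("t1", "t2", "t1"),
                  verdict = c("target_lineage", "target_lineage", "none"))
  sc <- characteristic_scores(c("c1", "c2", "c3"), v, "c2")
  expect_equal(unname(sc), c(2L, 1L, 0L))
})

test_that("bin removal requires both no-hallmark and >90% score-0", {
  mk <- data.frame(contig_id = "c01", marker_id = "MCP", copy_count = 1L)
  b_hall <- make_bin(rep(0L, 20), markers = mk)
  b_95 <- make_bin(c(rep(0L, 19), 4L))                 # 95% score 0
  b_85 <- make_bin(c(rep(0L, 17), 2L, 3L, 4L))         # 85% score 0
  b_90 <- make_bin(c(rep(0L, 18), 1L, 1L))             # exactly 90%
  out <- remove_non_gv_bins(list(b_hall, b_95, b_85, b_90))
  removed_ids <- vapply(out$removed, function(b) b$bin_id, "")
  expect_equal(length(out$removed), 1L)
  expect_equal(out$audit$removed, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("score-0 stripping keeps exactly the scored contigs", {
  b <- make_bin(c(0L, 1L, 4L))
  out <- strip_zero_contigs(b)
  expect_equal(out$contigs$contig_id, c("c02", "c03"))
  expect_equal(genome_size(out), 20000L)
  expect_equal(attr(out, "audit")$reason, "char_score_0")

  b_clean <- make_bin(c(2L, 3L))
  expect_equal(strip_zero_contigs(b_clean)$contigs,
               b_clean$contigs, ignore_attr = TRUE)

  b_all0 <- make_bin(c(0L, 0L))
  out0 <- strip_zero_contigs(b_all0)
  expect_true(is_dropped(out0))
  expect_true("bin_dropped" %in% attr(out0, "audit")$action)
})

test_that("outlier decontamination removes only score-1 outliers", {
  covs <- c(rep(10, 9), 100)         # last contig at 10x the median
  b <- make_bin(c(rep(4L, 9), 1L), coverages = covs,
                tetra = uniform_tetra(10, jitter = 0.01))
  out <- outlier_decontaminate(b)
  expect_false("c10" %in% out$contigs$contig_id)
  expect_equal(nrow(out$contigs), 9L)

  # same outlier but score 3: evidence of viral origin protects it
  b3 <- make_bin(c(rep(4L, 9), 3L), coverages = covs,
                 tetra = uniform_tetra(10, jitter = 0.01))
  expect_equal(nrow(outlier_decontaminate(b3)$contigs), 10L)

  # homogeneous bin passes unchanged
  bh <- make_bin(rep(2L, 8), coverages = rep(12, 8),
                 tetra = uniform_tetra(8, jitter = 0.01))
  expect_equal(nrow(outlier_decontaminate(bh)$contigs), 8L)

  # too-small bins pass through with a flag
  bs <- make_bin(c(1L, 1L, 1L), coverages = c(1, 1, 100))
  out_s <- outlier_decontaminate(bs)
  expect_equal(nrow(out_s$contigs), 3L)
  expect_equal(attr(out_s, "audit")$reason, "too_small_for_outlier_test")
})

test_that("chimera flagging needs high CV and duplicated single-copy genes", {
  mk2 <- data.frame(contig_id = c("c01", "c08"),
                    marker_id = c("PolB", "PolB"), copy_count = c(1L, 1L))
  covs_mixed <- c(rep(10, 7), rep(200, 3))
  b_both <- make_bin(rep(4L, 10), coverages = covs_mixed, markers = mk2)
  expect_gt(cov_cv(b_both), 1)
  expect_true(detect_chimera(b_both))

  b_lowcv <- make_bin(rep(4L, 10), coverages = rep(10, 10), markers = mk2)
  expect_false(detect_chimera(b_lowcv))

  mk1 <- data.frame(contig_id = "c01", marker_id = "PolB", copy_count = 1L)
  b_single <- make_bin(rep(4L, 10), coverages = covs_mixed, markers = mk1)
  expect_false(detect_chimera(b_single))

  b_zero <- make_bin(c(1L, 1L), coverages = c(0, 0))
  expect_error(cov_cv(b_zero), "zero mean")
})

test_that("chimera splitting recovers the planted partition", {
  com <- sim_community(n_viral = 0, n_cellular = 0, n_chimera = 1,
                       seed = 42)
  b <- community_bins(com)[["chimera_01"]]
  expect_true(detect_chimera(b))
  sp <- split_chimera(b)
  expect_equal(sp$action, "split")
  truth <- ifelse(grepl("_a", names(sp$assignment)), 1L, 2L)
  # Rand index of the 2-partition against the planted halves
  pairs <- combn(length(truth), 2)
  agree <- mean((truth[pairs[1, ]] == truth[pairs[2, ]]) ==
                  (sp$assignment[pairs[1, ]] == sp$assignment[pairs[2, ]]))
  expect_gte(agree, 0.95)
  expect_equal(sort(vapply(sp$clusters, genome_size, integer(1))),
               sort(c(sum(b$contigs$length[truth == 1]),
                      sum(b$contigs$length[truth == 2]))))
})

test_that("splits violating any of the four cluster criteria are refused", {
  com <- sim_community(n_viral = 0, n_cellular = 0, n_chimera = 1,
                       seed = 42)
  b <- community_bins(com)[["chimera_01"]]

  # shrink one half below 40 kb
  b_small <- b
  b_small$contigs$length[grepl("_b", b_small$contigs$contig_id)] <- 8000L
  sp <- split_chimera(b_small)
  expect_equal(sp$action, "flagged_chimera_unsplit")
  expect_true("min-length" %in% unlist(sp$reasons))

  # depress characteristic scores of one half below the 50% rule
  b_low <- b
  bsel <- grepl("_b", b_low$contigs$contig_id)
  b_low$contigs$char_score[bsel][1:3] <- 2L   # 1 of 4 contigs scores 4
  sp2 <- split_chimera(b_low)
  expect_equal(sp2$action, "flagged_chimera_unsplit")
  expect_true("score-fraction" %in% unlist(sp2$reasons))

  # mixed species labels in one half
  b_mix <- b
  b_mix$contigs$species[bsel] <- c("spX", "spY", "spX", "spY")
  sp3 <- split_chimera(b_mix)
  expect_equal(sp3$action, "flagged_chimera_unsplit")
  expect_true("taxonomy-inconsistent" %in% unlist(sp3$reasons))
})

test_that("the cascade conserves contigs and is order-invariant", {
  com <- sim_community(n_viral = 3, n_cellular = 2,
                       contaminant_frac = 0.15, seed = 7)
  bins <- community_bins(com)
  ref <- refine_bins(bins)
  kept <- unlist(lapply(ref$bins, function(b) b$contigs$contig_id))
  removed <- ref$audit$item[ref$audit$action == "contig_removed"]
  all_in <- unlist(lapply(bins, function(b) b$contigs$contig_id))
  expect_setequal(c(kept, removed), all_in)
  expect_equal(length(kept) + length(removed), length(all_in))

  # shuffling contig order within bins changes no decision
  bins_shuf <- lapply(bins, function(b) {
    set.seed(3)
    ord <- sample(nrow(b$contigs))
    gv_bin(b$bin_id, b$contigs[ord, ],
           tetra = b$tetra[ord, , drop = FALSE], markers = b$markers)
  })
  ref2 <- refine_bins(bins_shuf)
  kept2 <- unlist(lapply(ref2$bins, function(b) b$contigs$contig_id))
  expect_setequal(kept, kept2)
})
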