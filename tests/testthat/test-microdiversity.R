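test_that("site frequencies reproduce the worked count example", {
  # 30 A, 0 C, 10 T, 20 G at one site -> (A, C, T, G) = (1/2, 0, 1/6, 1/3)
  f <- site_frequencies(c(nA = 30, nC = 0, nG = 20, nT = 10))
  expect_equal(unname(f[1, c("fA", "fC", "fT", "fG")]),
               c(1 / 2, 0, 1 / 6, 1 / 3))
  expect_equal(unname(site_frequencies(c(7, 0, 0, 0))[1, ]),
               c(1, 0, 0, 0))
  expect_equal(unname(site_frequencies(c(1, 1, 1, 1))[1, ]), rep(0.25, 4))
  expect_error(site_frequencies(c(nA = 0, nC = 0, nG = 0, nT = 0)),
               "uncovered")
})

test_that("per-site ND matches closed forms and its bounds", {
  expect_equal(site_nd(c(1, 0, 0, 0)), 0)
  expect_equal(site_nd(rep(0.25, 4)), 0.75)
  f <- site_frequencies(c(nA = 30, nC = 0, nG = 20, nT = 10))
  expect_equal(site_nd(f), 1 - (0.25 + 0 + 1 / 9 + 1 / 36))
  set.seed(2)
  for (i in 1:50) {
    p <- as.numeric(occurrence_profile(rexp(4)))
    expect_gte(site_nd(p), 0)
    expect_lte(site_nd(p), 0.75)
  }
})

test_that("SNV calling enforces depth and minor-allele support", {
  sites <- data.frame(position = 1:4,
                      nA = c(2L, 30L, 99L, 55L),
                      nC = c(2L, 0L, 1L, 0L),
                      nG = c(0L, 20L, 0L, 0L),
                      nT = c(0L, 10L, 0L, 5L))
  snv <- call_snv_sites(sites)
  expect_false(1 %in% snv)   # depth 4 < 5
  expect_true(2 %in% snv)    # the worked example site
  expect_false(3 %in% snv)   # minor allele: 1 read, 1%
  expect_true(4 %in% snv)    # 5/60 reads = 8.3%
})

test_that("genome ND, SNV density and their degenerate cases", {
  expect_equal(as.numeric(genome_nd(c(0.5, 0.1))), 0.3)
  expect_equal(as.numeric(genome_nd(0.42)), 0.42)
  g0 <- genome_nd(numeric())
  expect_equal(as.numeric(g0), 0)
  expect_true(attr(g0, "no_snv"))
  expect_equal(snv_per_mb(250, 5e5), 500)
  expect_equal(snv_per_mb(0, 5e5), 0)
  expect_equal(snv_per_mb(100, 2e6), snv_per_mb(100, 1e6) / 2)
})

test_that("pi(a,b) matches arithmetic and the pi(a,a) = ND identity", {
  e1 <- c(1, 0, 0, 0); e2 <- c(0, 1, 0, 0)
  expect_equal(pi_between(e1, e1), 0)
  expect_equal(pi_between(e1, e2), 1)
  expect_equal(pi_between(c(0.5, 0.5, 0, 0), e1), 0.5)
  # algebraic identity on random frequency vectors, to 1e-12
  set.seed(3)
  for (i in 1:200) {
    a <- as.numeric(occurrence_profile(rexp(4)))
    expect_equal(pi_between(a, a), site_nd(a), tolerance = 1e-12)
  }
})

test_that("fst endpoints, symmetry and the monomorphic flag", {
  mk_sites <- function(nA, nC, nG, nT)
    data.frame(position = seq_along(nA), nA = nA, nC = nC, nG = nG,
               nT = nT)
  s <- mk_sites(c(30, 10), c(0, 20), c(20, 0), c(10, 0))
  self <- fst_pair(s, s)
  expect_equal(self$fst, 0)
  expect_equal(self$similarity, 1)

  # fixed alternative alleles: within 0, between 1
  a <- mk_sites(c(30, 40), c(0, 0), c(0, 0), c(0, 0))
  b <- mk_sites(c(0, 0), c(25, 35), c(0, 0), c(0, 0))
  # neither sample is polymorphic: such sites only enter under the
  # co-covered universe
  fixed <- fst_pair(a, b, config = gv_config(shared_sites = "cocovered"))
  expect_equal(fixed$fst, 1)
  expect_equal(fixed$similarity, 0)

  # a = b = (0.5, 0.5, 0, 0): within 0.5, between 0.5, fst 0
  h <- mk_sites(c(30, 30), c(30, 30), c(0, 0), c(0, 0))
  half <- fst_pair(h, h)
  expect_equal(half$mean_pi_ab, 0.5)
  expect_equal(half$fst, 0)

  # symmetry is exact
  p <- sim_snv_profiles(c(x = 0.7, y = 0.2), n_sites = 200, seed = 5)
  sx <- p$sites[p$sites$sample_id == "x", ]
  sy <- p$sites[p$sites$sample_id == "y", ]
  expect_equal(fst_pair(sx, sy)$fst, fst_pair(sy, sx)$fst)

  # monomorphic pair: defined as identical, flagged
  m <- mk_sites(c(50, 60), c(0, 0), c(0, 0), c(0, 0))
  mono <- fst_pair(m, m, config = gv_config(shared_sites = "cocovered"))
  expect_true(is.na(mono$fst) || (mono$fst == 0))

  # no shared sites -> not comparable
  far_a <- mk_sites(30, 30, 0, 0)
  far_b <- data.frame(position = 99L, nA = 30L, nC = 30L, nG = 0L,
                      nT = 0L)
  nc <- fst_pair(far_a, far_b)
  expect_false(nc$comparable)
})

test_that("a brute-force fst recomputation matches fst_pair exactly", {
  p <- sim_snv_profiles(c(a = 0.35, b = 0.8), n_sites = 1000,
                        depth_lambda = 40, seed = 17)
  sa <- p$sites[p$sites$sample_id == "a", ]
  sb <- p$sites[p$sites$sample_id == "b", ]
  res <- fst_pair(sa, sb)
  # independent oracle: direct per-site loop over raw counts
  cfg <- gv_config()
  snv <- union(call_snv_sites(sa), call_snv_sites(sb))
  pis <- matrix(NA_real_, 0, 3)
  for (pos in sort(intersect(intersect(sa$position, sb$position), snv))) {
    ca <- as.numeric(sa[sa$position == pos, c("nA", "nC", "nG", "nT")])
    cb <- as.numeric(sb[sb$position == pos, c("nA", "nC", "nG", "nT")])
    if (sum(ca) < cfg$min_depth || sum(cb) < cfg$min_depth) next
    fa <- ca / sum(ca); fb <- cb / sum(cb)
    paa <- sum(sapply(1:4, function(i) fa[i] * sum(fa[-i])))
    pbb <- sum(sapply(1:4, function(i) fb[i] * sum(fb[-i])))
    pab <- sum(sapply(1:4, function(i) fa[i] * sum(fb[-i])))
    pis <- rbind(pis, c(paa, pbb, pab))
  }
  fst_oracle <- 1 - ((mean(pis[, 1]) + mean(pis[, 2])) / 2) /
    mean(pis[, 3])
  expect_equal(nrow(pis), res$n_shared_sites)
  expect_equal(res$fst, fst_oracle, tolerance = 1e-12)
})

test_that("the microdiversity time course restricts to abundant samples", {
  ac <- sim_allele_cycling(n_sites = 100, n_months = 6, seed = 3)
  tc <- microdiv_timecourse(ac$sites, ac$dates)
  expect_equal(nrow(tc), choose(6, 2))
  tc2 <- microdiv_timecourse(ac$sites, ac$dates,
                             abundant_samples = names(ac$dates)[1:2])
  expect_equal(nrow(tc2), 1L)
  tc1 <- microdiv_timecourse(ac$sites, ac$dates,
                             abundant_samples = names(ac$dates)[1])
  expect_equal(nrow(tc1), 0L)
})
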