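test_that("rpkm follows its unit arithmetic and scaling law", {
  m <- matrix(c(1000, 0), 1, 2,
              dimnames = list("mag", c("s1", "s2")))
  r <- rpkm(m, c(mag = 1e5), c(s1 = 1e7, s2 = 1e7))
  expect_equal(unname(r[1, ]), c(1, 0))
  r2 <- rpkm(m, c(mag = 1e5), c(s1 = 2e7, s2 = 2e7))
  expect_equal(unname(r2[1, 1]), 0.5)
  expect_error(rpkm(m, c(mag = 1e5), c(s1 = 0, s2 = 1)), "positive")
})

test_that("presence calling is strictly greater than 50% breadth", {
  expect_equal(call_presence(c(0.51, 0.50, 0)), c(TRUE, FALSE, FALSE))
  expect_error(call_presence(1.2), "0, 1")
})

test_that("the Simpson-cumulation abundant rule matches hand arithmetic", {
  one <- c(m1 = 4.2)
  expect_equal(abundant_set(one), "m1")
  # ten equal MAGs: each contributes 0.01 of the 0.10 concentration;
  # the first eight (tie-broken by id) reach the 80% target
  ten <- setNames(rep(2, 10), sprintf("m%02d", 10:1))
  expect_equal(abundant_set(ten), sprintf("m%02d", 1:8))
  # one dominant MAG already carries 0.9025 of 0.9030
  six <- setNames(c(0.95, rep(0.01, 5)), sprintf("m%d", 1:6))
  expect_equal(abundant_set(six), "m1")
  expect_warning(empty <- abundant_set(c(m1 = 0, m2 = 0)), "all-zero")
  expect_equal(empty, character())
  # monotone in the fraction
  set.seed(8)
  v <- setNames(rexp(30), sprintf("m%02d", 1:30))
  for (f in c(0.2, 0.5, 0.8, 0.95))
    expect_true(all(abundant_set(v, fraction = f) %in%
                      abundant_set(v, fraction = min(1, f + 0.05))))
})

test_that("diversity indices match closed forms and vegan", {
  u4 <- rep(0.25, 4)
  d <- diversity_indices(u4)
  expect_equal(d$shannon, log(4))
  expect_equal(d$simpson, 0.25)
  dg <- diversity_indices(c(1, 0, 0))
  expect_equal(dg$shannon, 0)
  expect_equal(dg$simpson, 1)
  d2 <- diversity_indices(c(0.5, 0.5))
  expect_equal(d2$shannon, log(2))
  expect_equal(d2$simpson, 0.5)
  expect_error(diversity_indices(c(0.5, 0.6)), "sum")
})

test_that("Sorensen similarity agrees with vegan's binary Bray-Curtis", {
  a <- sprintf("m%02d", 1:10)
  b <- sprintf("m%02d", 6:15)
  s <- sorensen_similarity(a, b)
  expect_equal(s$similarity, 0.5)
  expect_equal(sorensen_similarity(a, a)$similarity, 1)
  expect_equal(sorensen_similarity(a, "zz")$similarity, 0)
  expect_warning(se <- sorensen_similarity(character(), character()),
                 "empty")
  expect_equal(se$similarity, 1)
  # cross-check against the standard ecology implementation
  universe <- union(a, b)
  mat <- rbind(as.integer(universe %in% a), as.integer(universe %in% b))
  vg <- as.numeric(vegan::vegdist(mat, method = "bray", binary = TRUE))
  expect_equal(s$dissimilarity, vg)
})

test_that("monthly binning averages samples within calendar months", {
  st <- data.frame(sample_id = c("s1", "s2", "s3"),
                   month_key = c("2017-05", "2017-05", "2017-06"))
  m <- matrix(c(2, 4, 10), 1, 3, dimnames = list("mag", st$sample_id))
  mb <- monthly_binning(m, st)
  expect_equal(unname(mb[1, ]), c(3, 10))
  expect_equal(colnames(mb), c("2017-05", "2017-06"))
})

test_that("the similarity time course enumerates all pairs", {
  pres <- matrix(TRUE, 3, 2, dimnames = list(paste0("m", 1:3),
                                             c("a", "b")))
  dates <- as.Date(c("2017-05-01", "2018-05-01"))
  tc <- similarity_timecourse(pres, dates)
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$interval_days, 365)
  expect_equal(tc$similarity, 1)
  pres5 <- matrix(TRUE, 2, 5)
  rownames(pres5) <- c("m1", "m2")
  expect_equal(nrow(similarity_timecourse(
    pres5, seq(as.Date("2017-01-01"), by = "month", length.out = 5))),
    10L)
})

test_that("niche classification reproduces every boundary case", {
  month_vec <- function(keys) setNames(rep(TRUE, length(keys)), keys)
  expect_equal(classify_niche(month_vec(sprintf("2017-%02d", 1:5)))$label,
               "persistent")
  # four consecutive months are not enough for persistence; with no
  # reappearance in 2018 the pattern is sporadic
  expect_equal(classify_niche(month_vec(sprintf("2017-%02d", 1:4)))$label,
               "sporadic")
  expect_equal(classify_niche(
    month_vec(c("2017-06", "2017-07", "2018-06")))$label, "seasonal")
  expect_equal(classify_niche(month_vec("2017-03"))$label, "sporadic")
  # the January + September pattern cannot be covered by one window
  expect_equal(classify_niche(
    month_vec(c("2017-01", "2017-09")))$label, "sporadic")
  expect_equal(classify_niche(
    month_vec(c("2017-01", "2017-09", "2018-06")))$label, "other")
  expect_equal(classify_niche(month_vec("2018-05"))$label,
               "excluded_2018_only")
  # several 2018 occurrences inside one covering window stay seasonal
  expect_equal(classify_niche(
    month_vec(c("2017-06", "2017-07", "2018-01", "2018-06")))$label,
    "seasonal")
  # but no single window can hold Jun-Jul 2017 with both Jan and Sep 2018
  expect_equal(classify_niche(
    month_vec(c("2017-06", "2017-07", "2018-01", "2018-09")))$label,
    "other")
  expect_error(classify_niche(month_vec("2016-12")), "axis")
})

test_that("planted occurrence archetypes are recovered exactly", {
  occ <- sim_occurrence(n_per_label = 4, seed = 42)
  labels <- vapply(occ$profiles, function(p) classify_niche(p)$label, "")
  truth <- occ$truth$label[match(names(labels), occ$truth$mag_id)]
  expect_equal(unname(labels), truth)
  # labels are stable under permutation of the battery
  set.seed(1)
  perm <- sample(names(occ$profiles))
  labels2 <- vapply(occ$profiles[perm],
                    function(p) classify_niche(p)$label, "")
  expect_equal(labels2, labels[perm])
})

test_that("Levins' index obeys its closed forms and bounds", {
  expect_equal(levins_index(rep(0.25, 4)), 4)
  expect_equal(levins_index(c(1, 0, 0)), 1)
  expect_equal(levins_index(c(0.8, 0.2)), 1 / 0.68)
  expect_error(levins_index(c(0, 0)), "all-zero")
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    p <- occurrence_profile(rexp(n))
    b <- levins_index(p)
    expect_gte(b, 1)
    expect_lte(b, n + 1e-9)
  }
})

test_that("environmental correlation reports rho with BH adjustment", {
  x <- 1:10
  env <- data.frame(up = 2 * x + 1, down = -x, flat = rep(1, 10))
  res <- correlate_env(x, env)
  expect_equal(res$rho[res$variable == "up"], 1)
  expect_equal(res$rho[res$variable == "down"], -1)
  expect_true(is.na(res$rho[res$variable == "flat"]))
  expect_true(all(res$p_adj >= res$p_value, na.rm = TRUE))
  expect_error(correlate_env(1:3, data.frame(a = 1:4)), "differ")
})
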