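# Diversity, distances, ordination, AMOVA, rank tests, enrichment.

test_that("richness and Shannon follow the stated conventions", {
  expect_equal(shannon(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(richness(c(5, 0, 0)), 1)
  expect_equal(richness(numeric(3)), 0)
  expect_equal(shannon(numeric(3)), 0)  # all-zero convention
  expect_error(shannon(c(-1, 2)), "negative")
})

test_that("Bray-Curtis matches the formula and its boundary cases", {
  m <- cbind(s1 = c(1, 0, 3), s2 = c(0, 2, 1))
  expect_equal(bray_curtis(m)["s1", "s2"], 5 / 7, tolerance = 1e-12)

  ident <- cbind(a = c(1, 2), b = c(1, 2))
  expect_equal(bray_curtis(ident)["a", "b"], 0)
  disjoint <- cbind(a = c(1, 0), b = c(0, 2))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)
  zeros <- cbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_equal(bray_curtis(zeros)["a", "b"], 0)  # documented convention
  expect_equal(bray_curtis(zeros)["a", "c"], 1)
})

test_that("Bray-Curtis is a bounded symmetric dissimilarity", {
  withr::local_seed(4)
  m <- matrix(rlnorm(20 * 12), 20, 12,
              dimnames = list(NULL, paste0("s", 1:12)))
  m[sample(length(m), 60)] <- 0
  d <- bray_curtis(m)
  expect_true(all(d >= 0 & d <= 1 + 1e-12))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("PCoA reproduces line and equilateral-triangle geometry", {
  # points on a line: axis-1 distances reproduce the input exactly
  x <- c(0, 1, 4, 9)
  d <- as.matrix(dist(x))
  ord <- pcoa(d, k = 1)
  expect_equal(as.matrix(dist(ord$coordinates[, 1])), d,
               tolerance = 1e-10, ignore_attr = TRUE)

  # equilateral triangle: two equal positive eigenvalues, distances 1
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  ord3 <- pcoa(d3, k = 2)
  expect_length(ord3$eigenvalues, 2)
  expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2], tolerance = 1e-9)
  expect_equal(as.numeric(dist(ord3$coordinates)), rep(1, 3),
               tolerance = 1e-9)

  # degenerate: all-zero distances give all-zero coordinates
  dz <- matrix(0, 3, 3)
  expect_warning(ordz <- pcoa(dz, k = 2), "positive eigenvalue")
  expect_true(all(abs(ordz$coordinates) < 1e-12))
})

test_that("AMOVA matches the loop oracle and the exhaustive 2x2 example", {
  # two tight, well-separated pairs
  pts <- c(0, 0.01, 10, 10.01)
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  labels <- c("A", "A", "B", "B")
  am <- amova(dm, labels, n_permutations = 999, seed = 1)
  expect_equal(am$Fs, oracle_amova_fs(dm, labels), tolerance = 1e-12)
  expect_equal(am$ss_among + am$ss_within, am$ss_total, tolerance = 1e-12)

  # exhaustive check: of the 6 balanced labelings only the true one and its
  # complement attain the maximal Fs, so the exceedance fraction is 2/6 and
  # the add-one estimator over random permutations converges to 1/3
  combos <- utils::combn(4, 2)
  fs_all <- apply(combos, 2, function(idx) {
    lab <- rep("B", 4); lab[idx] <- "A"
    oracle_amova_fs(dm, lab)
  })
  expect_equal(mean(fs_all >= am$Fs - 1e-9), 2 / 6)
  expect_equal(am$p_value, 1 / 3, tolerance = 0.06)

  expect_error(amova(dm, rep("A", 4)), "2 groups")
  expect_error(amova(dm, c("A", "B", "B", "B")), "at least 2 samples")
})

test_that("AMOVA p is reproducible and invariant to group renaming", {
  withr::local_seed(10)
  m <- matrix(rlnorm(15 * 12), 15, 12,
              dimnames = list(NULL, paste0("s", 1:12)))
  d <- bray_curtis(m)
  g1 <- rep(c("CON", "HG"), each = 6)
  g2 <- rep(c("x", "y"), each = 6)  # same partition, new names
  a1 <- amova(d, g1, n_permutations = 500, seed = 99)
  a2 <- amova(d, g1, n_permutations = 500, seed = 99)
  a3 <- amova(d, g2, n_permutations = 500, seed = 99)
  expect_identical(a1$p_value, a2$p_value)
  expect_identical(a1$p_value, a3$p_value)
  expect_gte(a1$p_value, 1 / 501)
})

test_that("rank-sum test: exact branch, ties, and errors", {
  rt <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(rt$method, "exact")
  expect_equal(rt$p_value, 0.1, tolerance = 1e-12)

  sym <- rank_sum_test(c(1, 2), c(1, 2))
  expect_equal(sym$p_value, 1.0)
  expect_identical(sym$method, "normal-approximation")  # ties present
  expect_true(sym$tie_corrected)

  big <- rank_sum_test(rnorm(20), rnorm(20))
  expect_identical(big$method, "normal-approximation")

  expect_error(rank_sum_test(numeric(), 1), "non-empty")
})

test_that("exact rank-sum p equals full enumeration for all 2<=n,m<=5", {
  withr::local_seed(6)
  for (n in 2:5) for (m in 2:5) {
    vals <- sample(1000, n + m)  # tie-free
    x <- vals[seq_len(n)]; y <- vals[-seq_len(n)]
    expect_equal(rank_sum_test(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-12, info = paste(n, m))
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential enrichment recovers planted directions at zero noise", {
  withr::local_seed(12)
  groups <- setNames(rep(c("CON", "HG"), each = 6), paste0("s", 1:12))
  # 6 entities enriched in CON, 4 in HG (60/40 split), strong separation
  n_con <- 6; n_hg <- 4
  mat <- rbind(
    matrix(rep(c(10, 1), c(6, 6)), n_con, 12, byrow = TRUE),
    matrix(rep(c(1, 10), c(6, 6)), n_hg, 12, byrow = TRUE))
  rownames(mat) <- paste0("e", 1:10); colnames(mat) <- names(groups)
  mat <- mat * (1 + matrix(runif(120, 0, 1e-3), 10, 12))  # break ties only
  enr <- differential_enrichment(mat, groups)
  expect_true(all(enr$significant))
  expect_identical(sum(enr$direction == "CON"), 6L)
  expect_identical(sum(enr$direction == "HG"), 4L)
  expect_identical(attr(enr, "summary")$CON, 6L)

  # entity present only in one group is enriched there
  solo <- matrix(rep(c(5, 0), c(6, 6)), 1, 12,
                 dimnames = list("only_con", names(groups)))
  solo[1, 1:6] <- solo[1, 1:6] + runif(6, 0, 1e-3)
  e2 <- differential_enrichment(solo, groups)
  expect_identical(e2$direction, "CON")
  expect_error(differential_enrichment(mat, setNames(rep("A", 12),
                                                     names(groups))),
               "2 groups")
})

test_that("identical distributions are rarely flagged at alpha 0.05", {
  withr::local_seed(13)
  groups <- setNames(rep(c("A", "B"), each = 10), paste0("s", 1:20))
  flags <- vapply(1:400, function(i) {
    x <- matrix(rnorm(20), 1, 20, dimnames = list("e", names(groups)))
    differential_enrichment(x, groups)$significant
  }, NA)
  expect_lte(mean(flags), 0.07)
})
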