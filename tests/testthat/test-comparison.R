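test_that("core matrix marks citations, drops empty rows and reports them", {
  fl <- as_freelist(data.frame(
    informant = c("i1", "i2", "i3", "i4"), group = "g", rank = 1L,
    item = c("x", "y", "z", "x")))
  m <- core_matrix(fl, c("x", "y"))
  expect_equal(nrow(m), 3L)
  expect_equal(attr(m, "dropped_rows"), "i3:g")
  expect_equal(colnames(m), c("x", "y"))
  expect_equal(unname(m["i1:g", ]), c(1L, 0L))
  # an informant citing all core plants gets an all-ones row
  fl_all <- as_freelist(data.frame(informant = c("i1", "i1", "i2"), group = "g",
                                   rank = c(1, 2, 1), item = c("x", "y", "x")))
  m_all <- core_matrix(fl_all, c("x", "y"))
  expect_equal(unname(m_all["i1:g", ]), c(1L, 1L))
  expect_error(core_matrix(fl, character(0)), "empty core")
  expect_error(core_matrix(fl, "z"), "per group")  # only 1 non-empty row
})

test_that("Jaccard dissimilarity equals (b+c)/(a+b+c) and is metric", {
  m <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(1, 0, 1))
  d <- as.matrix(jaccard_distances(m))
  expect_equal(d[1, 2], 0)     # identical rows
  expect_equal(d[1, 3], 1)     # disjoint rows
  expect_equal(d[2, 4], 2/3)   # (1,1,0) vs (1,0,1): a=1,b=1,c=1
  for (s in 1:10) {
    set.seed(s)
    mm <- matrix(rbinom(12 * 6, 1, 0.5), 12, 6)
    mm[rowSums(mm) == 0, 1] <- 1
    dd <- as.matrix(jaccard_distances(mm))
    expect_equal(dd, oracle_jaccard(mm), tolerance = 1e-12, ignore_attr = TRUE)
    # triangle inequality
    n <- nrow(dd)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  }
  expect_error(jaccard_distances(rbind(c(1, 0), c(0, 0))), "all-zero")
  expect_error(jaccard_distances(rbind(c(1, 2), c(0, 1))), "binary")
})

test_that("PERMANOVA reproduces the hand-derived toy decomposition", {
  dm <- matrix(c(0, 1, 2, 2,
                 1, 0, 2, 2,
                 2, 2, 0, 1,
                 2, 2, 1, 0), 4, 4)
  pm <- permanova(stats::as.dist(dm), c("a", "a", "b", "b"))
  expect_equal(pm$ss_total, 4.5)
  expect_equal(pm$ss_within, 1.0)
  expect_equal(pm$ss_between, 3.5)
  expect_equal(pm$pseudo_f, 7.0)
  expect_equal(pm$r_squared, 3.5 / 4.5)
  expect_true(pm$exact)  # only 6 distinct relabelings
  expect_equal(pm$p_perm, 1 / 3)
})

test_that("PERMANOVA decomposition matches the Gower-trace oracle and adonis2", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rbinom(20 * 7, 1, 0.5), 20, 7)
    m[rowSums(m) == 0, 1] <- 1
    g <- rep(c("a", "b"), each = 10)
    d <- jaccard_distances(m)
    pm <- permanova(d, g, n_permutations = 99, seed = s)
    orc <- oracle_permanova_gower(d, g)
    expect_equal(pm$ss_total, orc$ss_total, tolerance = 1e-9)
    expect_equal(pm$ss_between, orc$ss_between, tolerance = 1e-9)
    expect_equal(pm$ss_within, orc$ss_within, tolerance = 1e-9)
    expect_equal(pm$ss_between + pm$ss_within, pm$ss_total, tolerance = 1e-9)
    expect_true(pm$r_squared >= 0 && pm$r_squared <= 1)
    ad <- vegan::adonis2(d ~ g, permutations = 99)
    expect_equal(pm$pseudo_f, ad$F[1], tolerance = 1e-9)
    expect_equal(pm$r_squared, ad$R2[1], tolerance = 1e-9)
  }
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  for (s in 1:3) {
    set.seed(s)
    m <- matrix(rbinom(8 * 5, 1, 0.5), 8, 5)
    m[rowSums(m) == 0, 1] <- 1
    g <- rep(c("a", "b"), each = 4)
    d <- jaccard_distances(m)
    pm <- permanova(d, g, n_permutations = 999)
    expect_true(pm$exact)
    expect_equal(pm$n_permutations, choose(8, 4))
    expect_equal(pm$p_perm, oracle_exact_permanova_p(d, g), tolerance = 1e-12)
  }
  # three unbalanced groups
  set.seed(9)
  m <- matrix(rbinom(7 * 5, 1, 0.6), 7, 5)
  m[rowSums(m) == 0, 1] <- 1
  g <- c("a", "a", "b", "b", "c", "c", "c")
  d <- jaccard_distances(m)
  pm <- permanova(d, g, n_permutations = 999)
  expect_true(pm$exact)
  expect_equal(pm$p_perm, oracle_exact_permanova_p(d, g), tolerance = 1e-12)
})

test_that("pseudo-F is invariant under co-permutation and group renaming", {
  set.seed(12)
  m <- matrix(rbinom(16 * 6, 1, 0.5), 16, 6)
  m[rowSums(m) == 0, 1] <- 1
  g <- rep(c("a", "b"), each = 8)
  d <- as.matrix(jaccard_distances(m))
  f0 <- permanova(d, g, 49, seed = 1)$pseudo_f
  ix <- sample(16)
  expect_equal(permanova(d[ix, ix], g[ix], 49, seed = 1)$pseudo_f, f0,
               tolerance = 1e-12)
  g2 <- ifelse(g == "a", "zebra", "ant")
  expect_equal(permanova(d, g2, 49, seed = 1)$pseudo_f, f0, tolerance = 1e-12)
  expect_error(permanova(d, rep("a", 16)), "two groups")
  expect_error(permanova(d, g[-1]), "does not match")
})

test_that("dispersion distances match Anderson's centroid procedure (vegan)", {
  for (s in 1:4) {
    set.seed(s)
    m <- matrix(rbinom(18 * 8, 1, 0.5), 18, 8)
    m[rowSums(m) == 0, 1] <- 1
    g <- rep(c("a", "b"), each = 9)
    d <- jaccard_distances(m)
    bd <- beta_dispersion(d, g, n_permutations = 49, seed = s)
    vb <- vegan::betadisper(d, g, type = "centroid")
    expect_equal(unname(bd$distances), unname(vb$distances), tolerance = 1e-6)
    expect_equal(unname(bd$f), unname(summary(stats::aov(vb$distances ~ g))[[1]]$`F value`[1]),
                 tolerance = 1e-8)
  }
})

test_that("dispersion is zero for degenerate groups and symmetric point sets", {
  # all rows identical within each group
  m <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 1, 1), c(0, 1, 1))
  d <- jaccard_distances(m)
  bd <- beta_dispersion(d, c("a", "a", "b", "b"), n_permutations = 19)
  expect_equal(unname(bd$distances), rep(0, 4), tolerance = 1e-9)
  # two groups with identical point sets: equal mean dispersion, F ~ 0
  m2 <- rbind(c(1, 0, 0), c(0, 1, 1), c(1, 0, 0), c(0, 1, 1))
  bd2 <- beta_dispersion(jaccard_distances(m2), c("a", "a", "b", "b"),
                         n_permutations = 19)
  expect_equal(unname(diff(bd2$group_means)), 0, tolerance = 1e-9)
  expect_equal(unname(bd2$f), 0, tolerance = 1e-9)
})

test_that("PCoA embeds distances by Gower double-centering", {
  # two points at distance d: one axis at +/- d/2
  pc2 <- pcoa(matrix(c(0, 3, 3, 0), 2, 2))
  expect_equal(ncol(pc2$coordinates), 1L)
  expect_equal(sort(pc2$coordinates[, 1]), c(-1.5, 1.5))
  # equilateral triangle: two equal positive eigenvalues, distances preserved
  dm3 <- matrix(1, 3, 3) - diag(3)
  pc3 <- pcoa(dm3)
  ev <- pc3$eigenvalues[pc3$eigenvalues > 1e-8]
  expect_equal(length(ev), 2L)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_equal(as.matrix(stats::dist(pc3$coordinates)), dm3,
               tolerance = 1e-9, ignore_attr = TRUE)
  # Euclidean-embeddable fixture reconstructs its distances to 1e-9
  set.seed(5)
  pts <- matrix(rnorm(18), 9, 2)
  de <- stats::dist(pts)
  pc <- pcoa(de)
  expect_equal(as.matrix(stats::dist(pc$coordinates)), as.matrix(de),
               tolerance = 1e-9, ignore_attr = TRUE)
  # agrees with classical scaling in stats
  cs <- stats::cmdscale(de, k = 2, eig = TRUE)
  expect_equal(abs(pc$coordinates[, 1:2]), abs(cs$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  # coordinates are centered
  expect_lt(max(abs(colMeans(pc$coordinates))), 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("non-Euclidean input yields negative eigenvalues that balance the embedding", {
  set.seed(21)
  m <- matrix(rbinom(12 * 5, 1, 0.4), 12, 5)
  m[rowSums(m) == 0, 1] <- 1
  d <- as.matrix(jaccard_distances(m))
  pc <- pcoa(d)
  expect_true(any(pc$eigenvalues < -1e-8))
  # d_ij^2 = (positive-axis distance)^2 - (negative-axis distance)^2
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(ee$values)) * 1e-8
  cp <- ee$vectors[, ee$values > tol, drop = FALSE] %*%
    diag(sqrt(ee$values[ee$values > tol]))
  cn <- ee$vectors[, ee$values < -tol, drop = FALSE] %*%
    diag(sqrt(-ee$values[ee$values < -tol]))
  d2 <- as.matrix(stats::dist(cp))^2 - as.matrix(stats::dist(cn))^2
  expect_equal(d2, d^2, tolerance = 1e-9, ignore_attr = TRUE)
  # exposed coordinates are exactly the positive-axis embedding
  expect_equal(abs(pc$coordinates), abs(cp), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("ordination plot output is deterministic and falls back to 1-D", {
  set.seed(2)
  pts <- matrix(rnorm(16), 8, 2)
  pc <- pcoa(stats::dist(pts))
  g <- rep(c("a", "b"), 4)
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  plot_ordination(pc, g, file = f1)
  plot_ordination(pc, g, file = f2)
  expect_true(file.exists(f1))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(any(grepl("legend|text|glyph", readLines(f1, warn = FALSE),
                        ignore.case = TRUE)))
  # one positive axis only: strip plot with a warning
  pc1 <- pcoa(matrix(c(0, 1, 1, 0), 2, 2))
  f3 <- tempfile(fileext = ".svg")
  expect_warning(plot_ordination(pc1, c("a", "b"), file = f3), "1-D")
  expect_true(file.exists(f3))
})
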