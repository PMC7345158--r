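test_that("co-occurrence counting matches hand-enumerated pairs", {
  # [[0, 1], [0, 1]]: two horizontal (0 -> 1) pairs
  p <- gray_patch(matrix(c(0L, 0L, 1L, 1L), 2, 2), 2)
  g <- compute_glcm(p, 1, 0, symmetric = FALSE)
  expect_equal(g$pair_count, 2)
  expect_equal(g$C, matrix(c(0, 0, 1, 0), 2, 2))  # only C(0,1) = 1

  gs <- compute_glcm(p, 1, 0, symmetric = TRUE)
  expect_equal(gs$pair_count, 4)
  expect_equal(gs$C[1, 2], 0.5)
  expect_equal(gs$C[2, 1], 0.5)

  # constant patch: all mass at the constant level, at any offset
  const <- gray_patch(matrix(3L, 10, 10), 8)
  for (d in c(1, 4, 9)) {
    g <- compute_glcm(const, d, 45)
    expect_equal(g$C[4, 4], 1)
    expect_equal(sum(g$C), 1)
  }
  expect_error(compute_glcm(const, 10, 0), "no valid pixel pairs")
  expect_error(compute_glcm(const, 1, 30), "angle")
})

test_that("features of analytic matrices are exact", {
  const <- compute_glcm(gray_patch(matrix(5L, 8, 8), 16), 2, 0)
  f <- compute_features(const)
  expect_equal(f$contrast, 0)
  expect_equal(f$energy, 1)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$entropy, 0)

  # checkerboard pair matrix: C(0,1) = C(1,0) = 0.5
  chk <- gray_patch(matrix(c(0L, 1L), 4, 4), 2)  # alternating rows
  f2 <- compute_features(compute_glcm(chk, 1, 90))
  expect_equal(f2$contrast, 1)
  expect_equal(f2$energy, 0.5)
  expect_equal(f2$homogeneity, 0.5)
  expect_equal(f2$entropy, 1)  # 1 bit

  # natural-log entropy option scales by log(2)
  f2n <- compute_features(compute_glcm(chk, 1, 90), entropy_base = exp(1))
  expect_equal(f2n$entropy, log(2))
})

test_that("implementation agrees with the pair-enumeration oracle", {
  set.seed(101)
  for (k in 1:60) {
    side <- sample(8:30, 1)
    G <- sample(2:16, 1)
    d <- sample(1:5, 1)
    ang <- sample(c(0, 45, 90, 135), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    p <- random_patch(side, G)
    g <- compute_glcm(p, d, ang, sym)
    Co <- oracle_glcm(unclass(p), G, d, ang, sym)
    expect_lt(max(abs(g$C - Co)), 1e-12)
    expect_lt(max(abs(unlist(compute_features(g)) - oracle_features(Co))),
              1e-10)
  }
})

test_that("GLCMs are normalized, symmetric when requested, and bounded", {
  set.seed(7)
  for (k in 1:80) {
    G <- sample(c(4, 16, 64), 1)
    p <- random_patch(sample(10:40, 1), G)
    g <- compute_glcm(p, sample(1:8, 1), sample(c(0, 45, 90, 135), 1))
    expect_lt(abs(sum(g$C) - 1), 1e-12)
    expect_true(all(g$C >= 0))
    expect_equal(g$C, t(g$C))
    f <- compute_features(g)
    expect_gt(f$energy, 0); expect_lte(f$energy, 1)
    expect_gt(f$homogeneity, 0); expect_lte(f$homogeneity, 1)
    expect_lte(f$entropy, 2 * log2(G))
    expect_lte(f$contrast, (G - 1)^2)
  }
})

test_that("gray-level reversal leaves all four features unchanged", {
  set.seed(8)
  for (k in 1:20) {
    G <- sample(3:12, 1)
    p <- random_patch(sample(10:25, 1), G)
    rev <- gray_patch(G - 1L - unclass(p), G)
    f1 <- unlist(compute_features(compute_glcm(p, 2, 0)))
    f2 <- unlist(compute_features(compute_glcm(rev, 2, 0)))
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("uniform mass over k cells maximizes entropy at log2(k)", {
  # build matrices directly: k equal-mass cells
  for (k in c(1, 2, 4, 8)) {
    G <- 4
    C <- matrix(0, G, G)
    C[seq_len(k)] <- 1 / k
    g <- structure(list(C = C, gray_levels = G, distance = 1, angle = 0,
                        symmetric = FALSE, pair_count = 100), class = "glcm")
    f <- compute_features(g)
    expect_equal(f$entropy, log2(k))
    expect_equal(f$energy, 1 / k)
    # unequal mass over the same support is strictly more ordered
    if (k > 1) {
      C2 <- C
      C2[1] <- C2[1] + C2[2] / 2
      C2[2] <- C2[2] / 2
      g$C <- C2
      f2 <- compute_features(g)
      expect_lt(f2$entropy, f$entropy)
      expect_gt(f2$energy, f$energy)
    }
  }
})

test_that("patch_features collects one row per patch with identifiers", {
  set.seed(9)
  patches <- lapply(1:3, function(i) random_patch(20, 8))
  tab <- patch_features(patches, distance = 3, angle = 0,
                        source_image = "img1")
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("patch_id", "source_image", "distance", "angle",
                      "contrast", "energy", "homogeneity", "entropy"))
  expect_true(all(tab$source_image == "img1"))
  expect_error(patch_features(list()), "non-empty")
})
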