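test_that("Shannon index matches hand values and conventions", {
  expect_equal(shannon(rep(1, 10)), log(10), tolerance = 1e-9)  # 2.302585
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-9)
  expect_equal(shannon(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  expect_true(is.na(shannon(c(0, 0))))
  expect_error(shannon(c(-1, 2)), ">= 0")
})

test_that("Shannon is invariant to rescaling abundances", {
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rpois(12, 5)
      if (sum(x) == 0) next
      expect_equal(shannon(x), shannon(x * runif(1, 0.1, 100)),
                   tolerance = 1e-12)
    }
  })
})

test_that("Shannon agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(2, {
    x <- rpois(15, 3)
    expect_equal(shannon(x), unname(vegan::diversity(x, index = "shannon")),
                 tolerance = 1e-12)
  })
})

test_that("Bray-Curtis matches hand values and boundary cases", {
  expect_equal(bray_curtis(c(6, 4, 0), c(3, 4, 3)), 0.30, tolerance = 1e-9)
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))
  expect_equal(bray_curtis(c(0, 0), c(0, 2)), 1)
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(bray_curtis(c(a = 1, b = 2), c(b = 2, a = 1)), "labels")
})

test_that("Bray-Curtis stays in [0,1] with zero self-dissimilarity", {
  withr::with_seed(3, {
    for (i in 1:50) {
      x <- rpois(8, 4); y <- rpois(8, 4)
      if (sum(x) + sum(y) == 0) next
      d <- bray_curtis(x, y)
      expect_gte(d, 0); expect_lte(d, 1)
      if (sum(x) > 0) expect_equal(bray_curtis(x, x), 0)
      expect_equal(d, bray_curtis(y, x))
    }
  })
})

test_that("Bray-Curtis matrix agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  withr::with_seed(4, {
    m <- matrix(rpois(40, 5), nrow = 5)
    rownames(m) <- paste0("s", 1:5)
    expect_equal(bray_curtis_matrix(m),
                 as.matrix(vegan::vegdist(m, method = "bray")),
                 tolerance = 1e-12)
  })
})

test_that("ANOSIM yields R = 1 for perfectly separated groups", {
  m <- rbind(a1 = c(10, 8, 0, 0), a2 = c(9, 10, 0, 0), a3 = c(11, 9, 0, 0),
             a4 = c(10, 10, 0, 0),
             b1 = c(0, 0, 10, 9), b2 = c(0, 0, 8, 11), b3 = c(0, 0, 9, 10),
             b4 = c(0, 0, 10, 10))
  res <- anosim(bray_curtis_matrix(m), rep(c("a", "b"), each = 4),
                n_perm = 499, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lt(res$p_value, 0.05)
})

test_that("ANOSIM statistic matches vegan on a random dataset", {
  skip_if_not_installed("vegan")
  withr::with_seed(5, {
    m <- matrix(rpois(60, 6), nrow = 10)
    g <- rep(c("x", "y"), each = 5)
    ours <- anosim(bray_curtis_matrix(m), g, n_perm = 99, seed = 1)
    theirs <- suppressWarnings(
      vegan::anosim(vegan::vegdist(m, "bray"), g, permutations = 99))
    expect_equal(ours$statistic, unname(theirs$statistic), tolerance = 1e-12)
  })
})

test_that("permutation null is invariant to relabelling and p never hits 0", {
  m <- rbind(a1 = c(10, 8, 0, 0), a2 = c(9, 10, 0, 0), a3 = c(11, 9, 0, 0),
             b1 = c(0, 0, 10, 9), b2 = c(0, 0, 8, 11), b3 = c(0, 0, 9, 10))
  d <- bray_curtis_matrix(m)
  g1 <- rep(c("a", "b"), each = 3)
  g2 <- rep(c("b", "a"), each = 3)  # same partition, swapped labels
  r1 <- anosim(d, g1, n_perm = 299, seed = 7)
  r2 <- anosim(d, g2, n_perm = 299, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 300)
  expect_error(anosim(d, c("a", rep("b", 5))), ">= 2 members")
})

test_that("both-zero sample pairs are excluded rather than imputed", {
  m <- rbind(z1 = c(0, 0, 0), z2 = c(0, 0, 0),
             a1 = c(5, 1, 0), a2 = c(6, 2, 0),
             b1 = c(0, 1, 7), b2 = c(0, 2, 6))
  d <- bray_curtis_matrix(m)
  expect_true(is.na(d["z1", "z2"]))
  expect_equal(d["z1", "a1"], 1)
  res <- anosim(d, c("a", "a", "a", "a", "b", "b"), n_perm = 99, seed = 2)
  expect_true(is.finite(res$statistic))
})

test_that("boundary delineation recovers a planted turnover", {
  sc <- community_scenario(
    n_sites = 4, conditions = rep("UW", 4), n_dates = 2,
    surface_density = c(invertebrate = 400, ciliate = 8000, flagellate = 80000),
    decay_rate = c(invertebrate = 0.02, ciliate = 0.02, flagellate = 0.02),
    boundary_depth = c(UW = 10, DW = 15), turnover_sharpness = 3, seed = 31)
  res <- delineate_boundary(simulate_community(sc), "UW", n_perm = 499,
                            seed = 8)
  expect_equal(res$boundary$upper_stratum, 1)
  expect_equal(res$boundary$lower_stratum, 2)
  expect_equal(res$boundary$interface_depth_cm, 10)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("a depth-homogeneous community rarely produces a boundary", {
  hits <- vapply(1:12, function(s) {
    sc <- community_scenario(
      n_sites = 4, conditions = rep("DW", 4), n_dates = 2,
      surface_density = c(invertebrate = 200, ciliate = 4000,
                          flagellate = 40000),
      decay_rate = c(invertebrate = 1e-6, ciliate = 1e-6, flagellate = 1e-6),
      boundary_depth = c(UW = 34, DW = 34), turnover_sharpness = 5, seed = s)
    res <- delineate_boundary(simulate_community(sc), "DW", n_perm = 199,
                              seed = s + 50)
    !is.null(res$boundary)
  }, logical(1))
  # expected false-positive rate is ~alpha per scanned pair; with six pairs
  # the per-dataset rate stays well below one half
  expect_lte(sum(hits), 4)
})

test_that("boundary scan truncates below the colonised zone", {
  sc <- quick_community(seed = 13)
  comm <- simulate_community(sc)
  comm$count[comm$layer >= 4] <- 0
  comm$abundance_l[comm$layer >= 4] <- 0
  expect_warning(res <- delineate_boundary(comm, "UW", n_perm = 99, seed = 1),
                 "truncated")
  expect_lte(max(res$pairs$lower_stratum), 3)
})

test_that("UPGMA clustering merges the closest pair first and is label-invariant", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- cluster_layers(d)
  expect_equal(hc$height[1], 0.1)
  first <- rownames(d)[-hc$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  perm <- c("C", "A", "B")
  hc2 <- cluster_layers(d[perm, perm])
  expect_equal(sort(hc$height), sort(hc2$height))
})

test_that("UPGMA reproduces an ultrametric exactly", {
  # ultrametric: d(A,B)=0.2, d(A,C)=d(B,C)=0.6, d(*,D)=0.8
  lab <- c("A", "B", "C", "D")
  d <- matrix(0.8, 4, 4, dimnames = list(lab, lab))
  d[1:3, 1:3] <- 0.6
  d[1, 2] <- d[2, 1] <- 0.2
  diag(d) <- 0
  hc <- cluster_layers(d)
  expect_equal(sort(hc$height), c(0.2, 0.6, 0.8))
  expect_equal(as.matrix(stats::cophenetic(hc))[lab, lab], d)
  expect_error(cluster_layers(matrix(c(0, NA, NA, 0), 2, 2)), ">= 3 labels")
})

test_that("dendrograms serialise to Newick", {
  d <- bray_curtis_matrix(rbind(a = c(5, 1, 0), b = c(4, 2, 0),
                                c = c(0, 1, 6)))
  txt <- cluster_to_newick(cluster_layers(d))
  expect_match(txt, "^\\(.*\\);$")
  expect_true(all(vapply(c("a", "b", "c"), grepl, logical(1), x = txt)))
})

test_that("diversity profile flags empty layers as missing", {
  comm <- simulate_community(quick_community(seed = 17))
  comm$count[comm$layer == 6] <- 0
  d <- diversity_profile(comm)
  expect_true(all(is.na(d$diversity[d$layer == 6])))
  expect_true(all(!is.na(d$diversity[d$layer == 0])))
})
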