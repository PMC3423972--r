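# 1-D toy profiles {0, 1, 10}: merge heights are hand-enumerable
toy_tree <- function(linkage) {
  m <- as_chemgen(matrix(c(0, 1, 10), 3, 1,
                         dimnames = list(c("a", "b", "c"), "g1")))
  d <- pairwise_distance(m, "euclidean")
  cluster_profiles(d, linkage, profiles = m)
}

test_that("toy 1-D example reproduces hand-enumerated heights per linkage", {
  expect_equal(toy_tree("single")$height, c(1, 9))     # min(10, 9)
  expect_equal(toy_tree("complete")$height, c(1, 10))  # max(10, 9)
  expect_equal(toy_tree("average")$height, c(1, 9.5))  # (10 + 9)/2
  expect_equal(toy_tree("centroid")$height, c(1, 9.5)) # |10 - 0.5|
  t <- toy_tree("single")
  expect_equal(t$merge[1, ], c(-1L, -2L))  # first merge pairs a and b
})

test_that("cutting a tree returns the expected partitions", {
  t <- toy_tree("single")
  expect_equal(cut_dendrogram(t, 1), list(c("a", "b", "c")))
  expect_equal(cut_dendrogram(t, 3), list("a", "b", "c"))
  expect_equal(cut_dendrogram(t, 2), list(c("a", "b"), "c"))
  expect_error(cut_dendrogram(t, 0), "between 1")
  expect_error(cut_dendrogram(t, 4), "between 1")
})

test_that("cophenetic distances come from the joining merges", {
  t <- toy_tree("single")
  coph <- stats::cophenetic(t)$d
  expect_equal(coph["a", "b"], 1)
  expect_equal(coph["a", "c"], 9)
  expect_equal(coph["b", "c"], 9)
  expect_equal(unname(diag(coph)), rep(0, 3))
})

test_that("single-linkage cophenetic distance never exceeds input distance", {
  # classical subdominant-ultrametric property
  for (seed in 1:5) {
    m <- random_chemgen(n = 10, g = 12, missing_rate = 0.1, seed = seed)
    d <- pairwise_distance(m, "cityblock")
    t <- cluster_profiles(d, "single")
    coph <- stats::cophenetic(t)$d
    expect_true(all(coph <= d$d + 1e-12), label = paste("seed", seed))
  }
})

test_that("heights are monotone non-decreasing for single/complete/average", {
  for (seed in 1:3) {
    m <- random_chemgen(n = 11, g = 18, missing_rate = 0.1, seed = seed)
    for (measure in c("euclidean", "centered_corr")) {
      d <- pairwise_distance(m, measure)
      for (linkage in c("single", "complete", "average")) {
        t <- cluster_profiles(d, linkage)
        expect_true(all(diff(t$height) >= -1e-12),
                    label = paste(measure, linkage, seed))
      }
    }
  }
})

test_that("agglomeration matches the naive O(n^3) re-scan oracle", {
  # light version of the full acceptance sweep: all 28 combinations on a few
  # random matrices with missing values
  for (seed in 1:3) {
    n <- sample(8:12, 1)
    m <- random_chemgen(n = n, g = 20, missing_rate = 0.1, seed = seed)
    for (measure in chemo_measures()) {
      d <- pairwise_distance(m, measure)
      for (linkage in chemo_linkages()) {
        t <- suppressMessages(
          cluster_profiles(d, linkage, profiles = m))
        orc <- oracle_cluster(d$d, linkage, v = m$values, measure = measure)
        lbl <- sprintf("%s/%s seed %d", measure, linkage, seed)
        expect_equal(t$height, orc$heights, tolerance = 1e-9, label = lbl)
        expect_equal(stats::cophenetic(t)$d, orc$coph, tolerance = 1e-9,
                     label = lbl)
      }
    }
  }
})

test_that("results agree with stats::hclust on complete data", {
  m <- random_chemgen(n = 12, g = 16, missing_rate = 0, seed = 9)
  d <- pairwise_distance(m, "euclidean")
  hd <- stats::dist(m$values)
  for (linkage in c("single", "complete", "average")) {
    t <- cluster_profiles(d, linkage)
    h <- stats::hclust(hd, method = linkage)
    expect_equal(t$height, h$height, tolerance = 1e-12, label = linkage)
    expect_equal(stats::cophenetic(t)$d,
                 as.matrix(stats::cophenetic(h)), tolerance = 1e-12,
                 ignore_attr = TRUE, label = linkage)
  }
})

test_that("permuting input rows yields an isomorphic tree", {
  m <- random_chemgen(n = 10, g = 15, missing_rate = 0.1, seed = 12)
  perm <- c(4, 9, 1, 7, 2, 10, 3, 6, 8, 5)
  v2 <- m$values[perm, ]
  m2 <- chemgen_matrix(v2, m$transform)
  for (linkage in chemo_linkages()) {
    t1 <- suppressMessages(cluster_profiles(
      pairwise_distance(m, "centered_corr"), linkage, profiles = m))
    t2 <- suppressMessages(cluster_profiles(
      pairwise_distance(m2, "centered_corr"), linkage, profiles = m2))
    expect_equal(sort(t1$height), sort(t2$height), tolerance = 1e-12,
                 label = linkage)
    ids <- t1$leaf_ids
    c1 <- stats::cophenetic(t1)$d[ids, ids]
    c2 <- stats::cophenetic(t2)$d[ids, ids]
    expect_equal(c1, c2, tolerance = 1e-12, label = linkage)
  }
})

test_that("deterministic lexicographic tie-breaking on equal distances", {
  # four equidistant-pair points: 0,1 and 10,11 tie at distance 1
  m <- as_chemgen(matrix(c(0, 1, 10, 11), 4, 1,
                         dimnames = list(c("p", "q", "r", "s"), "g1")))
  d <- pairwise_distance(m, "euclidean")
  t <- cluster_profiles(d, "single")
  expect_equal(t$merge[1, ], c(-1L, -2L))  # (p, q) merged before (r, s)
  expect_equal(t$merge[2, ], c(-3L, -4L))
  expect_equal(t$height, c(1, 1, 9))
})

test_that("degenerate and invalid inputs raise the right errors", {
  m <- random_chemgen(n = 5, g = 8, seed = 2)
  d <- pairwise_distance(m, "euclidean")
  expect_error(cluster_profiles(d, "centroid"), "requires 'profiles'")
  expect_error(cluster_profiles(d, "ward"))
  v <- rbind(a = c(0.2, 0.1, NA, NA), b = c(NA, NA, 0.5, 0.6),
             c = c(0.3, 0.4, 0.5, 0.6))
  dm <- suppressWarnings(pairwise_distance(as_chemgen(v), "euclidean"))
  expect_error(cluster_profiles(dm, "single"),
               class = "chemo_degenerate_error")
})

test_that("centroid linkage can invert heights and reports it", {
  # near-equilateral triangle: a = (0,0), b = (1,0), c = (0.5, 0.8). The
  # closest pair (a, c) merges at sqrt(0.89) ~ 0.943; the centroid of {a, c}
  # sits at (0.25, 0.4), only 0.85 from b -> height inversion
  m <- as_chemgen(matrix(c(0, 1, 0.5, 0, 0, 0.8), 3, 2,
                         dimnames = list(c("a", "b", "c"), c("g1", "g2"))))
  d <- pairwise_distance(m, "euclidean")
  expect_message(t <- cluster_profiles(d, "centroid", profiles = m),
                 "inversion")
  expect_equal(t$height, c(sqrt(0.89), 0.85), tolerance = 1e-12)
  expect_lt(t$height[2], t$height[1])
})
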