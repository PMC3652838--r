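dist_fixture <- function(d_named) {
  # build a pairwise_dist from a full symmetric matrix
  structure(list(ids = rownames(d_named), model = "k2p", d = d_named,
                 sites = matrix(100L, nrow(d_named), ncol(d_named)),
                 n_undefined = sum(is.na(d_named[lower.tri(d_named)])),
                 taxonomy = NULL),
            class = "pairwise_dist")
}

sym <- function(ids, fill) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(fill)))
    d[fill[k, 1], fill[k, 2]] <- d[fill[k, 2], fill[k, 1]] <-
      as.numeric(fill[k, 3])
  d
}

test_that("sorted-gap detection finds the dominant gap and clips to window", {
  g <- find_barcode_gap(c(0.010, 0.012, 0.080, 0.090), window = c(0.5, 10))
  expect_true(g$found)
  expect_equal(g$gap_low_pct, 1.2)
  expect_equal(g$gap_high_pct, 8)

  # largest in-window consecutive gap is (4.1, 20), clipped to (4.1, 6)
  g2 <- find_barcode_gap(c(0.005, 0.039, 0.041, 0.20), window = c(2, 6))
  expect_equal(g2$gap_low_pct, 4.1)
  expect_equal(g2$gap_high_pct, 6)

  # uniform grid: every consecutive gap is equal; ties break to the lower
  # interval, and a grid fully covering the window at fine spacing still
  # yields an interval -- but a degenerate all-equal set does not
  g3 <- find_barcode_gap(rep(0.05, 10), window = c(1, 10))
  expect_false(g3$found)
})

test_that("histogram gap detection refines empty-bin runs to observations", {
  d <- c(0.008, 0.011, 0.012, 0.062, 0.07)
  g <- find_barcode_gap(d, window = c(0, 10), method = "histogram",
                        bin_width = 0.5)
  expect_true(g$found)
  expect_equal(g$gap_low_pct, 1.2)
  expect_equal(g$gap_high_pct, 6.2)

  # continuous coverage of the window -> no gap
  g2 <- find_barcode_gap(seq(0.001, 0.1, by = 0.001), window = c(1, 10),
                         method = "histogram", bin_width = 0.5)
  expect_false(g2$found)
})

test_that("threshold clustering forms single-linkage components", {
  ids <- c("s1", "s2", "s3")
  m <- dist_fixture(sym(ids, rbind(c(1, 2, 0.01), c(1, 3, 0.2),
                                   c(2, 3, 0.2))))
  del <- delimit_at_threshold(m, 4)
  expect_equal(del$n_clusters, 2L)
  expect_equal(del$clusters, list(c("s1", "s2"), "s3"))

  # chain transitivity: 1-2 and 2-3 below t join 1-3 despite d(1,3) = 6%
  mc <- dist_fixture(sym(ids, rbind(c(1, 2, 0.03), c(2, 3, 0.03),
                                    c(1, 3, 0.06))))
  expect_equal(delimit_at_threshold(mc, 4)$n_clusters, 1L)
  # complete linkage splits the same chain
  expect_equal(delimit_at_threshold(mc, 4, linkage = "complete")$n_clusters,
               2L)

  # t above the maximum -> one cluster; strict inequality at the boundary
  expect_equal(delimit_at_threshold(mc, 7)$n_clusters, 1L)
  mb <- dist_fixture(sym(c("a", "b"), rbind(c(1, 2, 0.04))))
  expect_equal(delimit_at_threshold(mb, 4)$n_clusters, 2L)  # 4.0% pair split
  expect_error(delimit_at_threshold(mb, 0), "positive")
})

test_that("undefined distances never join clusters", {
  d <- sym(c("a", "b", "c"), rbind(c(1, 2, 0.01)))
  d["a", "c"] <- d["c", "a"] <- NA
  d["b", "c"] <- d["c", "b"] <- NA
  m <- dist_fixture(d)
  del <- delimit_at_threshold(m, 50)
  expect_equal(del$n_clusters, 2L)
  expect_equal(del$undefined_pairs, 2L)
})

test_that("cluster count is non-increasing in the threshold", {
  cx <- simulate_complex(n_species = 5, members_per_species = 3,
                         seq_length = 300, seed = 12)
  m <- distance_matrix(cx$alignment)
  prof <- threshold_profile(m, c(0.05, 1, 2, 5, 8, 12, 20, 40))
  expect_true(all(diff(prof$n_clusters) <= 0))
  # extremes: below the minimum distance every sequence is its own cluster
  expect_equal(prof$n_clusters[[1L]], length(m$ids))
  expect_equal(prof$n_clusters[[nrow(prof)]], 1L)

  # two tight clusters: count is 2 across the whole gap
  cx2 <- simulate_complex(n_species = 2, members_per_species = 4,
                          seq_length = 500, d_intra = 0.01, d_inter = 0.1,
                          seed = 3)
  m2 <- distance_matrix(cx2$alignment)
  prof2 <- threshold_profile(m2, c(3, 4, 5, 6, 7, 8))
  expect_true(all(prof2$n_clusters == 2L))
})

test_that("partition comparison computes pair counts and the adjusted Rand index", {
  a <- stats::setNames(c(1, 1, 2, 2), paste0("s", 1:4))
  cmp_same <- compare_delimitations(a, a)
  expect_equal(cmp_same$adjusted_rand_index, 1)
  expect_equal(cmp_same$both_together, 2)
  expect_equal(cmp_same$both_apart, 4)

  # all-singletons vs one-cluster on 3 ids -> ARI 0
  singles <- stats::setNames(1:3, c("x", "y", "z"))
  lump <- stats::setNames(rep(1, 3), c("x", "y", "z"))
  expect_equal(compare_delimitations(singles, lump)$adjusted_rand_index, 0)

  expect_error(
    compare_delimitations(a, stats::setNames(1:3, c("s1", "s2", "s9"))),
    "different id sets")
})

test_that("ARI matches mclust's implementation on random partitions", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (rep in 1:10) {
    n <- 40
    a <- stats::setNames(sample(1:5, n, replace = TRUE), paste0("i", 1:n))
    b <- stats::setNames(sample(1:4, n, replace = TRUE), paste0("i", 1:n))
    expect_equal(compare_delimitations(a, b)$adjusted_rand_index,
                 mclust::adjustedRandIndex(a, b[names(a)]),
                 tolerance = 1e-12)
  }
})

test_that("delimitation recovers the simulated partition across the gap", {
  for (seed in c(1, 2, 3)) {
    cx <- simulate_complex(n_species = 8, members_per_species = 3,
                           seq_length = 650, seed = seed)
    m <- distance_matrix(cx$alignment)
    del <- delimit_at_threshold(m, 4)
    expect_equal(del$n_clusters, 8L)
    expect_equal(compare_delimitations(del, cx$truth)$adjusted_rand_index, 1)
    gap <- find_barcode_gap(m, window = c(1, 14))
    within <- m$d[outer(cx$truth, cx$truth, "==") & lower.tri(m$d)]
    expect_true(gap$found)
    expect_gte(gap$gap_low_pct, 100 * max(within) - 1e-9)
  }
})
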