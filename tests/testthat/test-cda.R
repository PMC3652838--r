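euclid_dist_obj <- function(X) {
  d <- as.matrix(stats::dist(X))
  dimnames(d) <- list(rownames(X), rownames(X))
  structure(list(ids = rownames(d), model = "p", d = d,
                 sites = matrix(1L, nrow(d), ncol(d)), n_undefined = 0L,
                 taxonomy = NULL),
            class = "pairwise_dist")
}

test_that("principal coordinates reproduce Euclidean configurations", {
  set.seed(31)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("p", 1:10), NULL))
  co <- distances_to_coordinates(euclid_dist_obj(X))
  # embedded pairwise distances equal the input distances
  expect_equal(as.matrix(stats::dist(co$coords)),
               unname(as.matrix(stats::dist(X))) |>
                 `dimnames<-`(list(co$ids, co$ids)),
               tolerance = 1e-8)
  expect_true(all(diff(co$eigenvalues) <= 1e-8))  # decreasing order

  # equilateral: three points at equal distance embed equidistantly
  d3 <- matrix(0.2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  co3 <- distances_to_coordinates(structure(
    list(ids = letters[1:3], model = "p", d = d3,
         sites = matrix(1L, 3, 3), n_undefined = 0L, taxonomy = NULL),
    class = "pairwise_dist"))
  emb <- stats::dist(co3$coords)
  expect_equal(max(emb) - min(emb), 0, tolerance = 1e-10)
})

test_that("undefined pairs require explicit imputation; zero matrix degenerates", {
  d <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- structure(list(ids = c("a", "b"), model = "k2p", d = d,
                      sites = matrix(1L, 2, 2), n_undefined = 1L,
                      taxonomy = NULL), class = "pairwise_dist")
  expect_error(distances_to_coordinates(m), "impute")
  expect_silent(distances_to_coordinates(m, impute = TRUE))

  z <- matrix(0, 3, 3)
  co <- distances_to_coordinates(z)
  expect_true(all(co$coords == 0))
})

test_that("the first axis separates two well-separated clusters", {
  cx <- simulate_complex(n_species = 2, members_per_species = 6,
                         seq_length = 500, d_intra = 0.01, d_inter = 0.12,
                         seed = 8)
  m <- distance_matrix(cx$alignment)
  co <- suppressMessages(distances_to_coordinates(m, n_components = 1))
  ax1 <- split(co$coords[, 1L], cx$truth)
  expect_true(max(ax1[[1L]]) < min(ax1[[2L]]) ||
                max(ax1[[2L]]) < min(ax1[[1L]]))
})

test_that("CDA recovers the discriminating direction in a 1-D problem", {
  set.seed(19)
  x <- c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  g <- rep(c("a", "b"), each = 20)
  fit <- fit_cda(cbind(x, rnorm(40)), g, n_components = 2)
  expect_equal(ncol(fit$scores), 1L)  # two groups -> one canonical axis
  # axis dominated by the informative coordinate
  w <- abs(fit$axes[, 1L]) / max(abs(fit$axes[, 1L]))
  expect_equal(w[[1L]], 1)
  expect_gt(abs(diff(fit$centroids[, 1L])), 5 * stats::sd(fit$scores[g == "a", 1L]))
})

test_that("sample order only changes canonical axes up to sign", {
  cx <- simulate_complex(n_species = 4, members_per_species = 4,
                         seq_length = 400, seed = 23)
  m <- distance_matrix(cx$alignment)
  co <- suppressMessages(distances_to_coordinates(m))
  fit <- fit_cda(co, cx$truth)
  set.seed(2); perm <- sample(length(m$ids))
  co_p <- structure(list(ids = co$ids[perm],
                         coords = co$coords[perm, , drop = FALSE],
                         eigenvalues = co$eigenvalues,
                         n_components = co$n_components),
                    class = "pcoa_coords")
  fit_p <- fit_cda(co_p, cx$truth[perm])
  s1 <- fit$scores[order(rownames(fit$scores)), 1L]
  s2 <- fit_p$scores[order(rownames(fit_p$scores)), 1L]
  expect_equal(abs(stats::cor(s1, s2)), 1, tolerance = 1e-6)
})

test_that("nearest-centroid CDA assignment agrees with MASS::lda on balanced groups", {
  skip_if_not_installed("MASS")
  set.seed(55)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  rownames(X) <- paste0("r", 1:40)
  g <- rep(c("g1", "g2"), each = 20)
  fit <- fit_cda(X, g, n_components = 2)
  ours <- predict(fit, X)
  theirs <- as.character(predict(MASS::lda(X, grouping = g,
                                           prior = c(0.5, 0.5)))$class)
  expect_equal(ours, theirs)
})

test_that("LOOCV is perfect on separated groups and conserves row sums", {
  cx <- simulate_complex(n_species = 5, members_per_species = 4,
                         seq_length = 500, d_intra = 0.01, d_inter = 0.15,
                         seed = 17)
  m <- distance_matrix(cx$alignment)
  co <- suppressMessages(distances_to_coordinates(m))
  rep <- loocv_classify(co, cx$truth[m$ids])
  expect_equal(rep$overall_correct_pct, 100)
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(factor(cx$truth,
                                             unique(cx$truth))))))
  expect_equal(length(rep$failed_folds), 0L)
})

test_that("LOOCV on identically distributed groups is near chance", {
  set.seed(91)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(paste0("n", 1:60), NULL))
  g <- rep(c("a", "b", "c"), 20)  # labels carry no information
  rep <- loocv_classify(X, g, n_components = 3)
  expect_lt(rep$overall_correct_pct, 60)  # chance is ~33%
  expect_equal(sum(rep$confusion), 60)
})

test_that("classification is invariant to uniform distance scaling", {
  cx <- simulate_complex(n_species = 4, members_per_species = 3,
                         seq_length = 400, seed = 37)
  m <- distance_matrix(cx$alignment)
  m2 <- m; m2$d <- 3.7 * m$d
  r1 <- loocv_classify(suppressMessages(distances_to_coordinates(m)),
                       cx$truth[m$ids])
  r2 <- loocv_classify(suppressMessages(distances_to_coordinates(m2)),
                       cx$truth[m$ids])
  expect_equal(r1$confusion, r2$confusion)
  expect_equal(r1$overall_correct_pct, r2$overall_correct_pct)
})

test_that("singleton groups fit but their held-out member is misclassified", {
  cx <- simulate_complex(n_species = 3, members_per_species = c(4, 4, 1),
                         seq_length = 400, seed = 44)
  m <- distance_matrix(cx$alignment)
  co <- suppressMessages(distances_to_coordinates(m))
  fit <- fit_cda(co, cx$truth[m$ids])
  expect_equal(length(fit$groups), 3L)
  rep <- loocv_classify(co, cx$truth[m$ids])
  expect_equal(unname(rep$per_group_correct_pct[c("sp01", "sp02")]),
               c(100, 100))
  expect_equal(unname(rep$per_group_correct_pct[["sp03"]]), 0)
})
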