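test_that("zero-length branches copy the parent; bad inputs error", {
  s <- paste(rep("ACGT", 50), collapse = "")
  expect_identical(evolve_sequence(s, 0), s)
  expect_error(evolve_sequence(s, -0.1), ">= 0")
  expect_error(evolve_sequence(s, 0.1, kappa = 0), "positive")
  expect_error(evolve_sequence("ACGN", 0.1), "A/C/G/T")
})

test_that("long branches drive the base composition to uniform", {
  set.seed(2)
  s <- paste(rep("A", 8000), collapse = "")
  child <- strsplit(evolve_sequence(s, 30), "")[[1L]]
  tab <- table(factor(child, c("A", "C", "G", "T")))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("K2P distance estimates are consistent with the branch length", {
  set.seed(123)
  d_target <- 0.1
  est <- replicate(200, {
    root <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                  collapse = "")
    k2p_distance(root, evolve_sequence(root, d_target))
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - d_target), 3 * se)
})

test_that("the transition bias follows kappa", {
  set.seed(7)
  root <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  child <- evolve_sequence(root, 0.1, kappa = 4)
  cc <- count_site_classes(root, child)
  # with kappa = 4 and short branches, transitions outnumber the two
  # transversion channels combined (expected ratio ~ 2:1)
  expect_gt(cc[["n_transitions"]] / cc[["n_transversions"]], 1.3)
})

test_that("simulated complexes are deterministic and labelled with truth", {
  a <- simulate_complex(n_species = 4, members_per_species = 2,
                        seq_length = 120, seed = 99)
  b <- simulate_complex(n_species = 4, members_per_species = 2,
                        seq_length = 120, seed = 99)
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$truth, b$truth)
  expect_equal(a$alignment$taxonomy$group, unname(a$truth))
  expect_equal(length(a$truth), 8L)

  # seed isolation: the global RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_complex(n_species = 2, seed = 5))
  expect_identical(runif(1), before)

  # FASTA serialization is byte-identical for equal seeds
  f1 <- tempfile(); f2 <- tempfile()
  write_alignment(a$alignment, f1)
  write_alignment(b$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-species sizes, singletons and geometry parameters validate", {
  cx <- simulate_complex(n_species = 3, members_per_species = c(1, 2, 5),
                         seq_length = 100, seed = 4)
  expect_equal(as.integer(table(cx$truth)[c("sp01", "sp02", "sp03")]),
               c(1L, 2L, 5L))
  expect_error(simulate_complex(d_intra = 0.2, d_inter = 0.1), "d_intra")
  expect_error(simulate_complex(n_species = 0), "n_species")

  # all singletons: any threshold below the separation recovers n species
  s <- simulate_complex(n_species = 5, members_per_species = 1,
                        seq_length = 400, seed = 21)
  m <- distance_matrix(s$alignment)
  expect_equal(delimit_at_threshold(m, 4)$n_clusters, 5L)
})

test_that("complex geometry recovers d_intra and d_inter in expectation", {
  intra_means <- inter_means <- numeric(10)
  for (k in 1:10) {
    cx <- simulate_complex(n_species = 10, members_per_species = 3,
                           seq_length = 1000, seed = 500 + k)
    m <- distance_matrix(cx$alignment)
    same <- outer(cx$truth, cx$truth, "==")[lower.tri(m$d)]
    v <- m$d[lower.tri(m$d)]
    intra_means[k] <- mean(v[same])
    inter_means[k] <- mean(v[!same])
  }
  se_i <- stats::sd(intra_means) / sqrt(10)
  se_o <- stats::sd(inter_means) / sqrt(10)
  expect_lt(abs(mean(intra_means) - 0.012), 3 * se_i)
  expect_lt(abs(mean(inter_means) - 0.157), 3 * se_o)
})

test_that("two-clade complexes separate the designated species on axis 1", {
  clade <- c(rep(1L, 4), rep(2L, 4))
  cx <- simulate_complex(n_species = 8, members_per_species = 3,
                         seq_length = 600, clade_of = clade, d_clade = 0.15,
                         seed = 6)
  m <- distance_matrix(cx$alignment)
  co <- suppressMessages(distances_to_coordinates(m))
  fit <- fit_cda(co, cx$truth[m$ids])
  ax1 <- split(fit$scores[, 1L], clade[as.integer(sub("sp", "",
                                                      cx$truth[m$ids]))])
  expect_true(max(ax1[[1L]]) < min(ax1[[2L]]) ||
                max(ax1[[2L]]) < min(ax1[[1L]]))
})

test_that("panel simulation scales divergence with the rate multiplier", {
  panel <- simulate_panel(n_taxa = 20, seed = 31)
  expect_equal(length(panel$taxa), 20L)
  mats <- panel_distances(panel)
  means <- vapply(mats, function(m) mean(dist_values(m)), numeric(1L))
  expect_gt(means[["ND5"]], means[["COI"]])
  expect_lt(means[["lrRNA"]], means[["COI"]])

  # equal multipliers -> statistically indistinguishable divergences
  eq <- simulate_panel(n_taxa = 12,
                       gene_specs = data.frame(gene = c("g1", "g2"),
                                               length = c(800L, 800L),
                                               rate = c(1, 1)),
                       seed = 15)
  em <- panel_distances(eq)
  v1 <- em$g1$d[lower.tri(em$g1$d)]; v2 <- em$g2$d[lower.tri(em$g2$d)]
  w <- paired_wilcoxon(v1, v2, alternative = "two.sided")
  expect_gt(w$p_value, 0.05)
  expect_lt(abs(mean(v1) - mean(v2)) / mean(v1), 0.1)

  expect_identical(simulate_panel(n_taxa = 5, seed = 3)$alignments$COI$seqs,
                   simulate_panel(n_taxa = 5, seed = 3)$alignments$COI$seqs)
})
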