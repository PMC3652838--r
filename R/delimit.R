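#' Locate the barcode gap in a distance distribution
#'
#' The barcode gap is the empty interval separating within-species from
#' between-species pairwise distances; its position motivates the
#' delimitation threshold. Two detection methods:
#'
#' * `sorted_gap` (default, bin-free): the largest difference between
#'   consecutive sorted distances among intervals intersecting the search
#'   window, reported clipped to the window.
#' * `histogram`: the longest maximal run of empty `bin_width`-wide bins
#'   inside the window, refined to the nearest observed distances on either
#'   side.
#'
#' Ties in gap length are broken in favour of the lower interval (the more
#' conservative threshold). If no empty region exists in the window a
#' no-gap result is returned (`found = FALSE`).
#'
#' @param distances Numeric vector of pairwise distances (proportions);
#'   `NA`s dropped. A `pairwise_dist` object is also accepted.
#' @param window Search window in percent, default `c(1, 10)`.
#' @param method `"sorted_gap"` or `"histogram"`.
#' @param bin_width Bin width in percentage points (histogram method).
#' @return An object of class `gap_report`: list with `found`, `gap_low_pct`,
#'   `gap_high_pct`, `gap_width_pct`, `method`, `window_pct`, `bin_width_pct`.
#' @export
find_barcode_gap <- function(distances, window = c(1, 10),
                             method = c("sorted_gap", "histogram"),
                             bin_width = 0.5) {
  if (inherits(distances, "pairwise_dist")) distances <- dist_values(distances)
  method <- match.arg(method)
  if (length(window) != 2L || window[[1L]] >= window[[2L]])
    stop("window must be c(low, high) with low < high (percent)",
         call. = FALSE)
  v <- sort(100 * distances[!is.na(distances)])
  if (length(v) < 2L)
    stop("need at least two defined distances", call. = FALSE)
  lo <- window[[1L]]; hi <- window[[2L]]
  no_gap <- structure(
    list(found = FALSE, gap_low_pct = NA_real_, gap_high_pct = NA_real_,
         gap_width_pct = NA_real_, method = method, window_pct = window,
         bin_width_pct = if (method == "histogram") bin_width else NA_real_),
    class = "gap_report")

  if (method == "sorted_gap") {
    a <- v[-length(v)]; b <- v[-1L]
    width <- b - a
    # interval (a, b) must intersect the window and be a genuine gap
    cand <- which(width > 0 & b > lo & a < hi)
    if (!length(cand)) return(no_gap)
    best <- cand[which.max(width[cand])]  # which.max takes the first = lower
    gl <- max(a[[best]], lo); gh <- min(b[[best]], hi)
    if (gh <= gl) return(no_gap)
  } else {
    if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
    edges <- seq(lo, hi + bin_width, by = bin_width)
    edges <- edges[edges <= hi + 1e-9]
    if (edges[[length(edges)]] < hi) edges <- c(edges, hi)
    counts <- vapply(seq_len(length(edges) - 1L), function(k)
      sum(v >= edges[[k]] & v < edges[[k + 1L]]), integer(1L))
    empty <- counts == 0L
    if (!any(empty)) return(no_gap)
    r <- rle(empty)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    span <- edges[ends[runs] + 1L] - edges[starts[runs]]
    best <- runs[[which.max(span)]]
    run_lo <- edges[[starts[[best]]]]
    run_hi <- edges[[ends[[best]] + 1L]]
    # refine to nearest observed distances bounding the empty run
    below <- v[v < run_lo + 1e-12]
    above <- v[v >= run_hi - 1e-12]
    gl <- if (length(below)) max(max(below), lo) else run_lo
    gh <- if (length(above)) min(min(above), hi) else run_hi
    if (gh <= gl) return(no_gap)
  }
  structure(
    list(found = TRUE, gap_low_pct = gl, gap_high_pct = gh,
         gap_width_pct = gh - gl, method = method, window_pct = window,
         bin_width_pct = if (method == "histogram") bin_width else NA_real_),
    class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (!x$found) {
    cat("No barcode gap found in window [",
        x$window_pct[[1L]], "%, ", x$window_pct[[2L]], "%] (",
        x$method, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Barcode gap: %.2f%% - %.2f%% (width %.2f%%), method %s, window [%g%%, %g%%]\n",
      x$gap_low_pct, x$gap_high_pct, x$gap_width_pct, x$method,
      x$window_pct[[1L]], x$window_pct[[2L]]))
  }
  invisible(x)
}

#' Delimit putative species by threshold clustering
#'
#' Single-linkage clustering at a fixed distance threshold: the clusters
#' are the connected components of the graph joining every pair with
#' distance strictly below `threshold_pct`. Undefined distances are treated
#' as larger than any threshold. A pair at exactly the threshold is split.
#'
#' @param m A `pairwise_dist` from [distance_matrix()].
#' @param threshold_pct Delimitation threshold in percent (> 0), e.g. 3.5
#'   or 4.
#' @param linkage `"single"` (connected components, default) or
#'   `"complete"` (every within-cluster pair below the threshold, computed
#'   by complete-linkage hierarchical clustering) for sensitivity analysis.
#' @return An object of class `species_delimitation`: list with
#'   `threshold_pct`, `clusters` (list of id vectors, ordered by first
#'   member), `n_clusters`, `membership` (named integer vector),
#'   `undefined_pairs`, `linkage`.
#' @export
delimit_at_threshold <- function(m, threshold_pct,
                                 linkage = c("single", "complete")) {
  stopifnot(inherits(m, "pairwise_dist"))
  linkage <- match.arg(linkage)
  if (threshold_pct <= 0)
    stop("threshold_pct must be positive", call. = FALSE)
  t_prop <- threshold_pct / 100
  n <- length(m$ids)
  d <- m$d
  if (linkage == "single") {
    # union-find over edges d < t (NA = no edge)
    parent <- seq_len(n)
    find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
    edges <- which(lower.tri(d) & !is.na(d) & d < t_prop, arr.ind = TRUE)
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[[k, 1L]]); rj <- find(edges[[k, 2L]])
      if (ri != rj) parent[[max(ri, rj)]] <- min(ri, rj)
    }
    comp <- vapply(seq_len(n), find, integer(1L))
  } else {
    dmax <- 2  # larger than any defined proportion distance
    d2 <- d; d2[is.na(d2)] <- dmax
    hc <- stats::hclust(stats::as.dist(d2), method = "complete")
    comp <- stats::cutree(hc, h = t_prop * (1 - 1e-12))
  }
  comp <- match(comp, unique(comp))  # renumber in order of first appearance
  clusters <- split(m$ids, comp)
  names(clusters) <- NULL
  structure(
    list(threshold_pct = threshold_pct, clusters = clusters,
         n_clusters = length(clusters),
         membership = stats::setNames(comp, m$ids),
         undefined_pairs = m$n_undefined, linkage = linkage),
    class = "species_delimitation")
}

#' @export
print.species_delimitation <- function(x, ...) {
  cat("Species delimitation at ", x$threshold_pct, "% (", x$linkage,
      " linkage): ", x$n_clusters, " putative species from ",
      length(x$membership), " sequences\n", sep = "")
  sz <- sort(lengths(x$clusters), decreasing = TRUE)
  cat("  cluster sizes: ", paste(utils::head(sz, 15L), collapse = " "),
      if (length(sz) > 15L) " ...", "\n", sep = "")
  if (x$undefined_pairs)
    cat("  undefined pairs treated as above-threshold: ",
        x$undefined_pairs, "\n", sep = "")
  invisible(x)
}

#' @export
summary.species_delimitation <- function(object, ...) {
  df <- data.frame(
    cluster = seq_along(object$clusters),
    size = lengths(object$clusters),
    members = vapply(object$clusters, function(m)
      paste(utils::head(m, 4L), collapse = ","), character(1L))
  )
  print(object)
  df
}

#' Cluster counts along a grid of thresholds
#'
#' Evaluates [delimit_at_threshold()] at each threshold; the cluster count
#' is non-increasing in the threshold.
#'
#' @param m A `pairwise_dist`.
#' @param t_grid_pct Numeric vector of thresholds in percent.
#' @return `data.frame` with columns `threshold_pct`, `n_clusters`.
#' @export
threshold_profile <- function(m, t_grid_pct) {
  if (!length(t_grid_pct)) stop("empty threshold grid", call. = FALSE)
  data.frame(
    threshold_pct = t_grid_pct,
    n_clusters = vapply(t_grid_pct, function(t)
      delimit_at_threshold(m, t)$n_clusters, integer(1L))
  )
}

#' Compare two partitions of the same sequences
#'
#' Counts sequence pairs co-clustered in both partitions, separated in
#' both, and split by exactly one, and computes the adjusted Rand index.
#'
#' @param a A `species_delimitation`, or a named membership vector.
#' @param b Second partition: a `species_delimitation`, or a named vector
#'   of reference labels (e.g. the true species of a simulated complex).
#' @return List with `n_pairs`, `both_together`, `both_apart`,
#'   `split_in_b_only` (together in `a`, apart in `b`), `merged_in_b_only`,
#'   `rand_index`, `adjusted_rand_index`.
#' @export
compare_delimitations <- function(a, b) {
  lab_a <- as_membership(a); lab_b <- as_membership(b)
  if (!setequal(names(lab_a), names(lab_b)))
    stop("partitions cover different id sets", call. = FALSE)
  lab_b <- lab_b[names(lab_a)]
  tab <- table(lab_a, lab_b)
  n <- length(lab_a)
  npairs <- choose(n, 2)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  both_together <- sum_ij
  split_b <- sum_i - sum_ij    # together in a, apart in b
  merged_b <- sum_j - sum_ij   # apart in a, together in b
  both_apart <- npairs - sum_i - sum_j + sum_ij
  rand <- (both_together + both_apart) / npairs
  expected <- sum_i * sum_j / npairs
  denom <- (sum_i + sum_j) / 2 - expected
  ari <- if (denom == 0) 1 else (sum_ij - expected) / denom
  list(n_pairs = npairs, both_together = both_together,
       both_apart = both_apart, split_in_b_only = split_b,
       merged_in_b_only = merged_b, rand_index = rand,
       adjusted_rand_index = ari)
}

as_membership <- function(x) {
  if (inherits(x, "species_delimitation")) return(x$membership)
  if (is.null(names(x)))
    stop("membership vector must be named by sequence id", call. = FALSE)
  stats::setNames(as.integer(factor(as.character(x))), names(x))
}
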