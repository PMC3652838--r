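# Distances are computed under pairwise deletion: for each sequence pair,
# only sites where BOTH sequences carry an unambiguous A/C/G/T are compared.
# A=1, C=2, G=3, T=4; anything else (gaps, N, IUPAC ambiguity codes) is NA.

encode_nt <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  unname(c(A = 1L, C = 2L, G = 3L, T = 4L)[chars])
}

# transition iff both bases are purines (A,G) or both pyrimidines (C,T)
.purine <- c(TRUE, FALSE, TRUE, FALSE)

site_classes_coded <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  xi <- xi[ok]; xj <- xj[ok]
  diff <- xi != xj
  ts <- sum(diff & (.purine[xi] == .purine[xj]))
  c(n_compared = length(xi), n_transitions = ts,
    n_transversions = sum(diff) - ts)
}

#' Classify compared sites between two aligned sequences
#'
#' Applies pairwise deletion (sites where either sequence has a gap or any
#' non-ACGT code are excluded) and classifies the remaining sites as
#' identical, transition (A<->G, C<->T) or transversion differences. These
#' counts feed the p-distance and the Kimura 2-parameter distance, whose
#' inputs are P = transitions / compared and Q = transversions / compared.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @return Named integer vector with `n_compared`, `n_transitions`,
#'   `n_transversions`.
#' @export
count_site_classes <- function(a, b) {
  xi <- encode_nt(a); xj <- encode_nt(b)
  if (length(xi) != length(xj))
    stop("sequences differ in length (", length(xi), " vs ", length(xj), ")",
         call. = FALSE)
  site_classes_coded(xi, xj)
}

dist_from_counts <- function(counts, model) {
  n <- counts[[1L]]
  if (n == 0L) return(NA_real_)
  if (model == "p") return((counts[[2L]] + counts[[3L]]) / n)
  P <- counts[[2L]] / n
  Q <- counts[[3L]] / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)  # saturated
  -0.5 * log(w1 * sqrt(w2))
}

#' Uncorrected p-distance between two sequences
#'
#' Proportion of differing sites among pairwise-deletion compared sites.
#'
#' @inheritParams count_site_classes
#' @return Numeric in `[0, 1]`, or `NA` if no sites are comparable.
#' @export
p_distance <- function(a, b) {
  dist_from_counts(count_site_classes(a, b), "p")
}

#' Kimura 2-parameter distance between two sequences
#'
#' Substitution-corrected distance
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where P and Q are the
#' proportions of transition and transversion differences among compared
#' sites. Always at least the p-distance of the same pair. When the log
#' argument is non-positive (substitution saturation) the distance is
#' undefined and `NA` is returned.
#'
#' @inheritParams count_site_classes
#' @return Non-negative numeric, or `NA` (no comparable sites / saturation).
#' @export
k2p_distance <- function(a, b) {
  dist_from_counts(count_site_classes(a, b), "k2p")
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all `n*(n-1)/2` pairwise distances under the chosen model with
#' pairwise deletion. Undefined pairs (no comparable sites, or K2P
#' saturation) are stored as `NA` and counted, never silently zeroed.
#'
#' @param aln A [barcode_alignment()] with at least two records.
#' @param model `"k2p"` (default) or `"p"`.
#' @return An object of class `pairwise_dist`: a list with `ids`, `model`,
#'   `d` (symmetric numeric matrix of proportions, zero diagonal, `NA` for
#'   undefined pairs), `sites` (per-pair compared-site counts) and
#'   `n_undefined`. The alignment's taxonomy travels along as `taxonomy`.
#' @export
distance_matrix <- function(aln, model = c("k2p", "p")) {
  stopifnot(inherits(aln, "barcode_alignment"))
  model <- match.arg(model)
  n <- length(aln$ids)
  if (n < 2L)
    stop("need at least two sequences for a distance matrix", call. = FALSE)
  coded <- matrix(unlist(lapply(aln$seqs, encode_nt)),
                  nrow = n, byrow = TRUE)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  sites <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  diag(sites) <- as.integer(rowSums(!is.na(coded)))
  undef <- character(0L)
  for (i in seq_len(n - 1L)) {
    xi <- coded[i, ]
    for (j in seq.int(i + 1L, n)) {
      counts <- site_classes_coded(xi, coded[j, ])
      dij <- dist_from_counts(counts, model)
      d[i, j] <- d[j, i] <- dij
      sites[i, j] <- sites[j, i] <- counts[[1L]]
      if (is.na(dij))
        undef <- c(undef, paste(aln$ids[[i]], aln$ids[[j]], sep = " / "))
    }
  }
  if (length(undef))
    warning(length(undef), " pair(s) with undefined distance: ",
            paste(utils::head(undef, 5L), collapse = "; "), call. = FALSE)
  structure(
    list(ids = aln$ids, model = model, d = d, sites = sites,
         n_undefined = length(undef), taxonomy = aln$taxonomy),
    class = "pairwise_dist"
  )
}

#' @export
print.pairwise_dist <- function(x, ...) {
  v <- dist_values(x)
  cat("Pairwise ", toupper(x$model), " distances: ", length(x$ids),
      " sequences, ", length(v) + x$n_undefined, " pairs",
      if (x$n_undefined) paste0(" (", x$n_undefined, " undefined)"),
      "\n", sep = "")
  if (length(v))
    cat(sprintf("  range %.1f%% - %.1f%%, mean %.1f%%\n",
                100 * min(v), 100 * max(v), 100 * mean(v)))
  invisible(x)
}

#' Extract the defined pairwise distances of a `pairwise_dist`
#' @param m A `pairwise_dist` from [distance_matrix()].
#' @return Numeric vector of the defined lower-triangle distances
#'   (proportions).
#' @export
dist_values <- function(m) {
  stopifnot(inherits(m, "pairwise_dist"))
  v <- m$d[lower.tri(m$d)]
  v[!is.na(v)]
}

# Lower-triangle pair table in a fixed (i < j) order; shared by the
# profiling, delimitation and gene-comparison code.
pair_table <- function(m) {
  n <- length(m$ids)
  idx <- which(lower.tri(m$d), arr.ind = TRUE)  # row > col
  data.frame(i = idx[, "col"], j = idx[, "row"],
             id_i = m$ids[idx[, "col"]], id_j = m$ids[idx[, "row"]],
             dist = m$d[idx], stringsAsFactors = FALSE)
}

#' Write a pairwise distance matrix as TSV
#' @param m A `pairwise_dist`.
#' @param path Output path: columns `id_i`, `id_j`, `distance`,
#'   `n_compared` (one row per unordered pair, `NA` distance = undefined).
#' @return `m`, invisibly.
#' @export
write_distances <- function(m, path) {
  pt <- pair_table(m)
  pt$n_compared <- m$sites[cbind(pt$j, pt$i)]
  out <- data.frame(id_i = pt$id_i, id_j = pt$id_j,
                    distance = signif(pt$dist, 10), n_compared = pt$n_compared)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
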