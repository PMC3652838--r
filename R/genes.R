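#' Build a multi-gene panel
#'
#' A `gene_panel` bundles one alignment per gene over an identical,
#' identically-ordered set of taxa (e.g. eleven mitochondrial genes across
#' a panel of complete mitogenomes).
#'
#' @param alignments Named list of [barcode_alignment()] objects, one per
#'   gene; all must cover the same taxa in the same order.
#' @return An object of class `gene_panel`: list with `taxa`, `genes`
#'   (names), `alignments`.
#' @export
gene_panel <- function(alignments) {
  if (!length(alignments) || is.null(names(alignments)) ||
      any(!nzchar(names(alignments))))
    stop("alignments must be a non-empty named list (one name per gene)",
         call. = FALSE)
  taxa <- alignments[[1L]]$ids
  for (g in names(alignments)) {
    if (!inherits(alignments[[g]], "barcode_alignment"))
      stop("gene '", g, "' is not a barcode_alignment", call. = FALSE)
    if (!identical(alignments[[g]]$ids, taxa))
      stop("gene '", g, "' covers different taxa (or different order)",
           call. = FALSE)
  }
  structure(list(taxa = taxa, genes = names(alignments),
                 alignments = alignments),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel: ", length(x$genes), " genes x ", length(x$taxa),
      " taxa (", choose(length(x$taxa), 2), " pairs per gene)\n", sep = "")
  cat("  genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-gene pairwise distance matrices for a panel
#'
#' @param panel A [gene_panel()].
#' @param model `"k2p"` (default) or `"p"`.
#' @return Named list of `pairwise_dist`, one per gene, all over the same
#'   taxon pairs in the same order.
#' @export
panel_distances <- function(panel, model = c("k2p", "p")) {
  stopifnot(inherits(panel, "gene_panel"))
  model <- match.arg(model)
  lapply(panel$alignments, distance_matrix, model = model)
}

#' Paired Wilcoxon signed-rank test between two loci
#'
#' Standard signed-rank test on paired distances: differences
#' `d = x - y`, zeros dropped (and counted), absolute differences ranked
#' with midranks for ties, and `w_plus` / `w_minus` computed as the rank
#' sums of positive and negative differences
#' (`w_plus + w_minus = n_used (n_used + 1) / 2`). The p-value is exact
#' (convolution of the permutation distribution of the rank sum, valid
#' under midranks) for `n_used <= 25`, and a normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' With `alternative = "auto"` (default) the one-sided alternative is
#' chosen by the sign of the median difference, matching the directional
#' reading of locus-rate comparisons; the `direction` field is set only
#' when p < 0.05.
#'
#' @param x,y Equal-length numeric vectors of paired distances (e.g. the
#'   per-pair distances of a reference gene and another gene). Pairs where
#'   either value is `NA` are dropped and counted.
#' @param alternative `"auto"`, `"less"` (x < y), `"greater"` or
#'   `"two.sided"`.
#' @return An object of class `wilcoxon_result`: list with `w_plus`,
#'   `w_minus`, `n_used`, `n_zero`, `n_na`, `p_value`, `alternative`,
#'   `direction` (`"x<y"`, `"x>y"` or `"none"`).
#' @export
paired_wilcoxon <- function(x, y,
                            alternative = c("auto", "less", "greater",
                                            "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n_na <- sum(!ok)
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0L)
    return(structure(list(w_plus = 0, w_minus = 0, n_used = 0L,
                          n_zero = n_zero, n_na = n_na, p_value = 1,
                          alternative = alternative, direction = "none"),
                     class = "wilcoxon_result"))
  r <- rank(abs(d))  # midranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (alternative == "auto") {
    med <- stats::median(d)
    alternative <- if (med < 0 || (med == 0 && w_plus < w_minus))
      "less" else "greater"
  }
  p <- signrank_p(w_plus, r, alternative, exact = n <= 25L)
  dir <- "none"
  if (alternative != "two.sided" && p < 0.05)
    dir <- if (alternative == "less") "x<y" else "x>y"
  structure(list(w_plus = w_plus, w_minus = w_minus, n_used = n,
                 n_zero = n_zero, n_na = n_na, p_value = p,
                 alternative = alternative, direction = dir),
            class = "wilcoxon_result")
}

# Null distribution of W+ given the (mid)ranks r: each rank enters the sum
# with probability 1/2. Exact tail by polynomial convolution over doubled
# ranks (integers even under midranks); otherwise normal approximation with
# tie and continuity corrections.
signrank_p <- function(w_plus, r, alternative, exact) {
  n <- length(r)
  if (exact) {
    r2 <- as.integer(round(2 * r))
    f <- 1  # coefficients of the generating polynomial over W2 = 2*W+
    for (ri in r2) {
      g <- c(f, numeric(ri))
      g[(ri + 1L):(ri + length(f))] <- g[(ri + 1L):(ri + length(f))] + f
      f <- g
    }
    f <- f / 2^n
    w2 <- round(2 * w_plus)
    p_le <- sum(f[seq_len(w2 + 1L)])          # P(W2 <= w2), support 0..len-1
    p_ge <- sum(f[(w2 + 1L):length(f)])
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_le <- (w_plus - mu + 0.5) / sqrt(sigma2)
    z_ge <- (w_plus - mu - 0.5) / sqrt(sigma2)
    p <- switch(alternative,
                less = stats::pnorm(z_le),
                greater = stats::pnorm(z_ge, lower.tail = FALSE),
                two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                           stats::pnorm(z_ge,
                                                        lower.tail = FALSE))))
  }
  max(p, .Machine$double.xmin)  # p in (0, 1]
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed-rank: W+ = ", x$w_plus, ", W- = ", x$w_minus,
      ", n = ", x$n_used, ", p = ", format.pval(x$p_value, digits = 3),
      " (", x$alternative, ")\n", sep = "")
  cat("  direction: ", x$direction,
      if (x$n_zero) paste0("  [", x$n_zero, " zero differences dropped]"),
      "\n", sep = "")
  invisible(x)
}

#' Regress one gene's pairwise distances on a reference gene's
#'
#' Ordinary least-squares line and Pearson correlation of `y` on `x`,
#' quantifying how linearly another locus tracks the reference barcode
#' locus across the same taxon pairs.
#'
#' @param x Reference-gene pair distances.
#' @param y Other-gene pair distances (same pairs, same order).
#' @return List with `slope`, `intercept`, `r`, `n_used`.
#' @export
regress_vs_coi <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need at least three defined pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stop("zero variance in reference distances", call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[[2L]]),
       intercept = unname(stats::coef(fit)[[1L]]),
       r = stats::cor(x, y), n_used = length(x))
}

#' Compare every gene of a panel against a reference gene
#'
#' Runs the paired Wilcoxon signed-rank test and the per-pair regression of
#' each non-reference gene against the reference over the shared taxon
#' pairs.
#'
#' @param panel A [gene_panel()], or the output of [panel_distances()].
#' @param ref_gene Name of the reference gene (default `"COI"`).
#' @param model Distance model if `panel` is a `gene_panel`.
#' @return A `data.frame` with one row per non-reference gene: `gene`,
#'   `w_plus`, `w_minus`, `n_used`, `p_value`, `direction` (rendered as
#'   e.g. `"COI<ND5"`), `slope`, `intercept`, `r`.
#' @export
compare_genes <- function(panel, ref_gene = "COI", model = c("k2p", "p")) {
  mats <- if (inherits(panel, "gene_panel"))
    panel_distances(panel, match.arg(model)) else panel
  if (!ref_gene %in% names(mats))
    stop("reference gene '", ref_gene, "' not in panel", call. = FALSE)
  x <- mats[[ref_gene]]$d[lower.tri(mats[[ref_gene]]$d)]
  rows <- lapply(setdiff(names(mats), ref_gene), function(gname) {
    y <- mats[[gname]]$d[lower.tri(mats[[gname]]$d)]
    w <- paired_wilcoxon(x, y)
    reg <- regress_vs_coi(x, y)
    dir_label <- switch(w$direction,
                        "x<y" = paste0(ref_gene, "<", gname),
                        "x>y" = paste0(ref_gene, ">", gname),
                        "none")
    data.frame(gene = gname, w_plus = w$w_plus, w_minus = w$w_minus,
               n_used = w$n_used, p_value = w$p_value,
               direction = dir_label, slope = reg$slope,
               intercept = reg$intercept, r = reg$r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
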