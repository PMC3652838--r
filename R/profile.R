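#' Partition pairwise distances by taxonomic level
#'
#' Each unordered pair is assigned to exactly one level: same species ->
#' `within_species`; different species in the same genus ->
#' `within_genus_between_species`; different genera in the same family ->
#' `within_family_between_genera`; different families -> excluded. The
#' assignment is exclusive and hierarchical by default (a congeneric pair is
#' not also counted as confamilial); `nested = TRUE` instead counts a pair
#' at every level whose labels match (a conspecific pair then also appears
#' at the genus and family levels).
#'
#' Pairs with a missing label at the level needed to place them are skipped
#' and counted in `n_skipped`.
#'
#' @param m A `pairwise_dist` from [distance_matrix()].
#' @param taxonomy Optional taxonomy `data.frame` (columns `id`, `species`,
#'   `genus`, `family`); defaults to the taxonomy carried by `m`.
#' @param nested Use nested (non-exclusive) level counting.
#' @return A list with one numeric vector of distances per level (possibly
#'   with `NA` for undefined pairs), plus `n_skipped` and `n_excluded`
#'   attributes.
#' @export
partition_pairs_by_level <- function(m, taxonomy = NULL, nested = FALSE) {
  stopifnot(inherits(m, "pairwise_dist"))
  if (is.null(taxonomy)) taxonomy <- m$taxonomy
  if (is.null(taxonomy))
    stop("no taxonomy available", call. = FALSE)
  idx <- match(m$ids, taxonomy$id)
  if (anyNA(idx))
    stop("taxonomy is missing ids: ",
         paste(utils::head(m$ids[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  sp <- taxonomy$species[idx]; ge <- taxonomy$genus[idx]
  fa <- taxonomy$family[idx]
  pt <- pair_table(m)
  known <- function(v) !is.na(v[pt$i]) & !is.na(v[pt$j])
  same <- function(v) known(v) & v[pt$i] == v[pt$j]
  diff <- function(v) known(v) & v[pt$i] != v[pt$j]
  same_sp <- same(sp); same_ge <- same(ge); same_fa <- same(fa)
  if (nested) {
    lv_sp <- same_sp
    lv_ge <- same_ge & diff(sp)
    lv_fa <- same_fa & diff(ge)
    skipped <- !lv_sp & !lv_ge & !lv_fa & !diff(fa)
  } else {
    # exclusive, hierarchical placement: a pair must be known different at
    # every lower level before it counts at a higher one; a missing label
    # that blocks placement skips the pair
    lv_sp <- same_sp
    lv_ge <- diff(sp) & same_ge
    lv_fa <- diff(sp) & diff(ge) & same_fa
    skipped <- !lv_sp & !lv_ge & !lv_fa &
      !(diff(sp) & diff(ge) & diff(fa))
  }
  excluded <- !lv_sp & !lv_ge & !lv_fa & !skipped
  out <- list(
    within_species = pt$dist[lv_sp],
    within_genus_between_species = pt$dist[lv_ge],
    within_family_between_genera = pt$dist[lv_fa]
  )
  attr(out, "n_skipped") <- sum(skipped)
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Summarize a level partition into a divergence profile
#'
#' For every taxonomic level with at least one pair, reports the average,
#' minimum and maximum pairwise distance (as percentages) and the number of
#' comparisons. Undefined (`NA`) distances are excluded from the summary
#' statistics and counted separately.
#'
#' @param partition Output of [partition_pairs_by_level()], or any named
#'   list of distance vectors (proportions).
#' @return A `divergence_profile`: a `data.frame` with columns `level`,
#'   `avg_pct`, `min_pct`, `max_pct`, `n_comparisons`, `n_undefined`.
#' @export
summarize_levels <- function(partition) {
  rows <- lapply(names(partition), function(lv) {
    v <- partition[[lv]]
    und <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    data.frame(level = lv, avg_pct = 100 * mean(v), min_pct = 100 * min(v),
               max_pct = 100 * max(v), n_comparisons = length(v),
               n_undefined = und, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(level = character(), avg_pct = numeric(),
                      min_pct = numeric(), max_pct = numeric(),
                      n_comparisons = integer(), n_undefined = integer())
  class(out) <- c("divergence_profile", "data.frame")
  out
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat("Divergence profile (values in %):\n")
  df <- as.data.frame(x)
  if (nrow(df)) {
    df$avg_pct <- sprintf("%.1f", df$avg_pct)
    df$range <- sprintf("%.1f-%.1f", x$min_pct, x$max_pct)
    print(df[c("level", "avg_pct", "range", "n_comparisons")],
          row.names = FALSE)
  } else cat("  (no comparisons)\n")
  invisible(x)
}

#' Histogram of pairwise divergences
#'
#' Bins distances into half-open bins `[k*w, (k+1)*w)` from 0 to the
#' maximum; a value exactly on an edge goes to the upper bin. Counts sum to
#' the number of defined distances.
#'
#' @param distances Numeric vector of distances (proportions); `NA`s are
#'   dropped.
#' @param bin_width Bin width in percentage points (default 0.5).
#' @return A `data.frame` with `bin_low_pct`, `bin_high_pct`, `count`
#'   (class `divergence_histogram`); empty for empty input.
#' @export
divergence_histogram <- function(distances, bin_width = 0.5) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  v <- 100 * distances[!is.na(distances)]
  if (!length(v)) {
    out <- data.frame(bin_low_pct = numeric(), bin_high_pct = numeric(),
                      count = integer())
  } else {
    k <- floor(v / bin_width)
    n_bins <- max(k) + 1L
    counts <- tabulate(k + 1L, nbins = n_bins)
    out <- data.frame(bin_low_pct = bin_width * (seq_len(n_bins) - 1L),
                      bin_high_pct = bin_width * seq_len(n_bins),
                      count = counts)
  }
  class(out) <- c("divergence_histogram", "data.frame")
  out
}

#' @export
plot.divergence_histogram <- function(x, xlab = "K2P distance (%)",
                                      ylab = "Number of pairs", ...) {
  graphics::barplot(x$count, names.arg = sprintf("%g", x$bin_low_pct),
                    space = 0, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Per-species (intra) or per-species-pair (inter) divergence summaries
#'
#' In `intra` mode, summarizes within-group pairwise distances for every
#' group with at least two members; singleton groups are skipped and listed
#' in the `skipped_singletons` attribute. In `inter` mode, summarizes all
#' cross-group distances for each named pair of groups.
#'
#' @param m A `pairwise_dist`.
#' @param group_labels Named character vector `id -> group`, or `NULL` to
#'   use the `group` column of the taxonomy carried by `m` (falling back to
#'   `species`).
#' @param mode `"intra"` or `"inter"`.
#' @param pairs For `inter` mode, a list of 2-element character vectors of
#'   group names.
#' @return A `data.frame` with columns `name`, `avg_pct`, `min_pct`,
#'   `max_pct`, `n_comparisons`, `n_undefined`.
#' @export
per_group_summaries <- function(m, group_labels = NULL,
                                mode = c("intra", "inter"), pairs = NULL) {
  stopifnot(inherits(m, "pairwise_dist"))
  mode <- match.arg(mode)
  if (is.null(group_labels)) {
    tx <- m$taxonomy
    if (is.null(tx)) stop("no group labels available", call. = FALSE)
    g <- tx$group
    if (all(is.na(g))) g <- tx$species
    group_labels <- stats::setNames(g, tx$id)
  }
  grp <- unname(group_labels[m$ids])
  pt <- pair_table(m)
  gi <- grp[pt$i]; gj <- grp[pt$j]
  summary_row <- function(name, v) {
    und <- sum(is.na(v)); v <- v[!is.na(v)]
    data.frame(name = name,
               avg_pct = if (length(v)) 100 * mean(v) else NA_real_,
               min_pct = if (length(v)) 100 * min(v) else NA_real_,
               max_pct = if (length(v)) 100 * max(v) else NA_real_,
               n_comparisons = length(v), n_undefined = und,
               stringsAsFactors = FALSE)
  }
  if (mode == "intra") {
    sizes <- table(grp[!is.na(grp)])
    multi <- names(sizes)[sizes >= 2L]
    singletons <- names(sizes)[sizes == 1L]
    rows <- lapply(multi, function(g)
      summary_row(g, pt$dist[!is.na(gi) & !is.na(gj) & gi == g & gj == g]))
    if (length(singletons))
      message("skipped ", length(singletons),
              " singleton group(s): ", paste(singletons, collapse = ", "))
    out <- do.call(rbind, rows)
    attr(out, "skipped_singletons") <- singletons
  } else {
    if (is.null(pairs)) stop("inter mode needs `pairs`", call. = FALSE)
    known <- unique(grp[!is.na(grp)])
    rows <- lapply(pairs, function(p) {
      if (length(p) != 2L || !all(p %in% known))
        stop("unknown group in pair: ", paste(p, collapse = " / "),
             call. = FALSE)
      sel <- (!is.na(gi) & !is.na(gj)) &
        ((gi == p[[1L]] & gj == p[[2L]]) | (gi == p[[2L]] & gj == p[[1L]]))
      summary_row(paste(p, collapse = " - "), pt$dist[sel])
    })
    out <- do.call(rbind, rows)
  }
  out
}
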