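#' Configuration for the full delimitation pipeline
#'
#' @param fasta Path to the aligned FASTA input (or `NULL` when an
#'   in-memory alignment is passed to [run_pipeline()]).
#' @param taxonomy Optional path to the taxonomy TSV.
#' @param model Distance model, `"k2p"` (default) or `"p"`.
#' @param reference_id Optional reference id for window trimming.
#' @param window_length Barcode window length (used only with
#'   `reference_id`); default 650.
#' @param thresholds_pct Delimitation thresholds to evaluate, default
#'   `c(3.5, 4)`.
#' @param gap_window_pct Barcode-gap search window, default `c(1, 10)`.
#' @param gap_method `"sorted_gap"` or `"histogram"`.
#' @param bin_width_pct Histogram bin width, default 0.5.
#' @param var_explained PCoA variance fraction retained for the CDA.
#' @param group_source Groups for the CDA stage: `"taxonomy"` (the `group`
#'   column, falling back to `species`) when labels exist, else
#'   `"delimitation"` (clusters at the largest threshold). `"auto"`
#'   (default) picks taxonomy if present.
#' @param out_dir Output directory (created); `NULL` for no file output.
#' @param seed Seed recorded in the provenance block (the pipeline itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, taxonomy = NULL,
                            model = c("k2p", "p"), reference_id = NULL,
                            window_length = 650,
                            thresholds_pct = c(3.5, 4),
                            gap_window_pct = c(1, 10),
                            gap_method = c("sorted_gap", "histogram"),
                            bin_width_pct = 0.5, var_explained = 0.95,
                            group_source = c("auto", "taxonomy",
                                             "delimitation"),
                            out_dir = NULL, seed = NULL) {
  if (any(thresholds_pct <= 0))
    stop("thresholds must be positive", call. = FALSE)
  structure(
    list(fasta = fasta, taxonomy = taxonomy, model = match.arg(model),
         reference_id = reference_id, window_length = window_length,
         thresholds_pct = sort(thresholds_pct),
         gap_window_pct = gap_window_pct,
         gap_method = match.arg(gap_method),
         bin_width_pct = bin_width_pct, var_explained = var_explained,
         group_source = match.arg(group_source), out_dir = out_dir,
         seed = seed),
    class = "pipeline_config")
}

# hash of the analysis-relevant configuration: the output location does
# not affect results and is excluded, so reruns into different directories
# share a hash
provenance_config <- function(cfg) {
  cfg <- unclass(cfg)
  cfg[setdiff(names(cfg), "out_dir")]
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(provenance_config(cfg), auto_unbox = TRUE,
                              null = "null", digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

stage_error <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_error(stage, e))
}

#' Run the full barcode-gap delimitation pipeline
#'
#' Executes, in order: input reading, optional reference-window trimming,
#' haplotype deduplication, pairwise distances, divergence profiling (when
#' species/genus/family labels exist), barcode-gap detection, threshold
#' delimitation at each configured threshold, and CDA + leave-one-out
#' validation of the grouping. A failure in any stage aborts with a
#' stage-named error. Rerunning with the same configuration and inputs
#' reproduces the outputs byte-identically.
#'
#' @param cfg A [pipeline_config()].
#' @param alignment Optional in-memory [barcode_alignment()] (bypasses
#'   `cfg$fasta`).
#' @return An object of class `pipeline_report` (see
#'   [write_pipeline_report()] for the serialized form): per-stage counts,
#'   the divergence profile, the gap report, one delimitation per
#'   threshold, the LOOCV report, and a provenance block with the config
#'   hash and seed.
#' @export
run_pipeline <- function(cfg, alignment = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  aln <- run_stage("input", {
    if (!is.null(alignment)) alignment
    else if (!is.null(cfg$fasta))
      read_alignment(cfg$fasta, cfg$taxonomy,
                     reference_id = cfg$reference_id)
    else stop("no input alignment", call. = FALSE)
  })
  n_in <- length(aln$ids)

  if (!is.null(cfg$reference_id))
    aln <- run_stage("trim", trim_to_reference_window(
      aln, cfg$reference_id, cfg$window_length))

  dd <- run_stage("dedup", dedup_haplotypes(aln))
  reps <- dd$alignment

  m <- run_stage("distances", distance_matrix(reps, model = cfg$model))

  have_levels <- !all(is.na(reps$taxonomy$species))
  profile <- NULL
  if (have_levels)
    profile <- run_stage("profile",
                         summarize_levels(partition_pairs_by_level(m)))
  hist_tab <- run_stage("profile",
                        divergence_histogram(dist_values(m),
                                             cfg$bin_width_pct))

  gap <- run_stage("gap", find_barcode_gap(
    m, window = cfg$gap_window_pct, method = cfg$gap_method,
    bin_width = cfg$bin_width_pct))

  delims <- run_stage("delimit", lapply(cfg$thresholds_pct, function(t)
    delimit_at_threshold(m, t)))
  names(delims) <- sprintf("%g%%", cfg$thresholds_pct)

  use_tax <- switch(cfg$group_source,
                    taxonomy = TRUE, delimitation = FALSE,
                    auto = !all(is.na(reps$taxonomy$group)) ||
                      !all(is.na(reps$taxonomy$species)))
  groups <- if (use_tax) {
    g <- reps$taxonomy$group
    if (all(is.na(g))) g <- reps$taxonomy$species
    g
  } else {
    paste0("cluster", delims[[length(delims)]]$membership)
  }
  cda <- loocv <- NULL
  if (length(unique(groups)) >= 2L && m$n_undefined == 0L) {
    coords <- run_stage("cda", distances_to_coordinates(m))
    cda <- run_stage("cda", fit_cda(coords, groups,
                                    var_explained = cfg$var_explained))
    loocv <- run_stage("cda", loocv_classify(coords, groups,
                                             var_explained = cfg$var_explained))
  }

  report <- structure(
    list(stages = list(
           input = list(n_sequences = n_in,
                        alignment_length = alignment_length(aln)),
           dedup = list(n_in = n_in, n_representatives = length(reps$ids),
                        n_collapsed = n_in - length(reps$ids)),
           distances = list(model = cfg$model,
                            n_pairs = choose(length(reps$ids), 2),
                            n_undefined = m$n_undefined)),
         profile = profile, histogram = hist_tab, gap = gap,
         delimitations = delims, cda = cda, loocv = loocv,
         groups = groups,
         provenance = list(package = "barcodegap",
                           version = as.character(
                             utils::packageVersion("barcodegap")),
                           config = provenance_config(cfg),
                           config_hash = config_hash(cfg),
                           seed = cfg$seed)),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    write_alignment(reps, file.path(out_dir, "representatives.fasta"),
                    file.path(out_dir, "representatives_taxonomy.tsv"))
    write_haplotype_map(dd$map, file.path(out_dir, "haplotype_map.tsv"))
    write_distances(m, file.path(out_dir, "distances.tsv"))
    utils::write.table(hist_tab, file.path(out_dir, "histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(profile))
      utils::write.table(as.data.frame(profile),
                         file.path(out_dir, "profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(delims)) {
      df <- data.frame(id = names(delims[[nm]]$membership),
                       cluster = delims[[nm]]$membership)
      utils::write.table(df, file.path(out_dir, paste0(
        "delimitation_", gsub("%", "pct", nm), ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(loocv))
      write_loocv_report(loocv, file.path(out_dir, "loocv_confusion.tsv"))
    if (!is.null(cda)) {
      sc <- data.frame(id = reps$ids, group = groups,
                       round(cda$scores, 8), check.names = FALSE)
      utils::write.table(sc, file.path(out_dir, "cda_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_pipeline_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  st <- x$stages
  cat("Barcode-gap pipeline report\n")
  cat("  input: ", st$input$n_sequences, " sequences x ",
      st$input$alignment_length, " columns\n", sep = "")
  cat("  dedup: ", st$dedup$n_representatives, " representative haplotypes\n",
      sep = "")
  cat("  distances: ", st$distances$n_pairs, " ", toupper(st$distances$model),
      " pairs (", st$distances$n_undefined, " undefined)\n", sep = "")
  if (!is.null(x$gap)) print(x$gap)
  for (nm in names(x$delimitations))
    cat("  delimitation at ", nm, ": ", x$delimitations[[nm]]$n_clusters,
        " clusters\n", sep = "")
  if (!is.null(x$loocv))
    cat(sprintf("  LOOCV: %.1f%% correct\n", x$loocv$overall_correct_pct))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' The JSON layout follows the schema shipped at
#' `system.file("schema", "report-schema.json", package = "barcodegap")`.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output path.
#' @return The report list that was serialized, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  delims <- lapply(report$delimitations, function(d)
    list(threshold_pct = d$threshold_pct, n_clusters = d$n_clusters,
         cluster_sizes = unname(lengths(d$clusters)),
         undefined_pairs = d$undefined_pairs))
  out <- list(
    stages = report$stages,
    profile = if (!is.null(report$profile)) as.data.frame(report$profile),
    gap = report$gap[c("found", "gap_low_pct", "gap_high_pct", "method")],
    delimitations = delims,
    loocv = if (!is.null(report$loocv))
      list(overall_correct_pct = report$loocv$overall_correct_pct,
           n = report$loocv$n,
           per_group_correct_pct =
             as.list(report$loocv$per_group_correct_pct)),
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(out)
}

#' Check a report JSON file against the shipped schema
#'
#' Structural conformance check (required keys and scalar types) against
#' `inst/schema/report-schema.json`.
#'
#' @param path Path to a report JSON written by [write_pipeline_report()].
#' @return `TRUE` (invisibly) if conformant, otherwise an error describing
#'   the first violation.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "barcodegap"))
  doc <- jsonlite::read_json(path)
  check_node <- function(node, spec, where) {
    for (key in names(spec$required)) {
      if (is.null(node[[key]]))
        stop("missing required key '", where, key, "'", call. = FALSE)
      want <- spec$required[[key]]
      if (is.character(want)) {
        ok <- switch(want,
                     number = is.numeric(node[[key]]),
                     string = is.character(node[[key]]),
                     boolean = is.logical(node[[key]]),
                     object = is.list(node[[key]]),
                     array = is.list(node[[key]]) || is.vector(node[[key]]),
                     TRUE)
        if (!ok)
          stop("key '", where, key, "' is not of type ", want, call. = FALSE)
      } else {
        check_node(node[[key]], list(required = want), paste0(where, key, "."))
      }
    }
  }
  check_node(doc, list(required = schema$required), "")
  invisible(TRUE)
}
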