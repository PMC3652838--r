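#' Construct a barcode alignment
#'
#' A `barcode_alignment` holds equal-length aligned nucleotide sequences
#' (upper-case, over `A C G T -`, `N` and IUPAC ambiguity codes) together with
#' an optional taxonomy (species / genus / family / putative-group labels).
#'
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @param seqs Character vector of aligned sequences, one string per record,
#'   all of identical length.
#' @param taxonomy Optional `data.frame` with columns `id`, `species`,
#'   `genus`, `family`, `group`. Missing labels are `NA` ("unassigned").
#'   Rows are matched to `ids`; records without a row get all-`NA` labels.
#' @param reference_id Optional id of the reference (standard) sequence used
#'   to anchor the barcode window, e.g. the complete mitogenome record the
#'   alignment was built against.
#'
#' @return An object of class `barcode_alignment`: a list with elements
#'   `ids`, `seqs`, `taxonomy` (always present, `NA`-filled if none given)
#'   and `reference_id`.
#' @seealso [read_alignment()], [trim_to_reference_window()],
#'   [dedup_haplotypes()]
#' @export
barcode_alignment <- function(ids, seqs, taxonomy = NULL, reference_id = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  if (length(ids) == 0L)
    stop("alignment must contain at least one record", call. = FALSE)
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("sequence ids must be non-empty", call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs)))
    stop("sequences must be non-empty", call. = FALSE)
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    off <- ids[len != stats::median(len)]
    stop("sequences are not aligned (unequal lengths): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  if (!is.null(reference_id) && !reference_id %in% ids)
    stop("reference_id '", reference_id, "' not found among ids", call. = FALSE)
  tax <- empty_taxonomy(ids)
  if (!is.null(taxonomy)) {
    taxonomy <- validate_taxonomy(taxonomy, ids)
    m <- match(ids, taxonomy$id)
    for (col in c("species", "genus", "family", "group")) {
      hit <- !is.na(m)
      tax[[col]][hit] <- taxonomy[[col]][m[hit]]
    }
  }
  structure(
    list(ids = ids, seqs = seqs, taxonomy = tax, reference_id = reference_id),
    class = "barcode_alignment"
  )
}

empty_taxonomy <- function(ids) {
  data.frame(
    id = ids, species = NA_character_, genus = NA_character_,
    family = NA_character_, group = NA_character_,
    stringsAsFactors = FALSE
  )
}

validate_taxonomy <- function(taxonomy, ids) {
  need <- c("id", "species", "genus", "family", "group")
  if (!all(need %in% names(taxonomy)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  taxonomy <- taxonomy[need]
  for (col in need) {
    v <- trimws(as.character(taxonomy[[col]]))
    v[!nzchar(v)] <- NA_character_
    taxonomy[[col]] <- v
  }
  if (anyDuplicated(taxonomy$id))
    stop("duplicate ids in taxonomy table", call. = FALSE)
  extra <- setdiff(taxonomy$id, ids)
  if (length(extra))
    stop("taxonomy ids absent from alignment: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  taxonomy
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("Barcode alignment: ", length(x$ids), " sequences x ",
      alignment_length(x), " columns\n", sep = "")
  n_sp <- length(unique(stats::na.omit(x$taxonomy$species)))
  n_gr <- length(unique(stats::na.omit(x$taxonomy$group)))
  if (n_sp) cat("  species labels: ", n_sp, "\n", sep = "")
  if (n_gr) cat("  group labels:   ", n_gr, "\n", sep = "")
  if (!is.null(x$reference_id))
    cat("  reference: ", x$reference_id, "\n", sep = "")
  invisible(x)
}

#' Number of columns in an alignment
#' @param aln A [barcode_alignment()].
#' @return Integer, the common sequence length.
#' @export
alignment_length <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  nchar(aln$seqs[[1L]])
}

#' Read an aligned FASTA file (with optional taxonomy table)
#'
#' Reads a wrapped or unwrapped FASTA alignment and attaches taxonomy labels
#' from a tab-separated table with header `id species genus family group`
#' (empty cells mean "unassigned"). Sequence characters are upper-cased.
#'
#' @param fasta_path Path to an aligned FASTA file; all sequences must have
#'   identical length.
#' @param taxonomy_path Optional path to the taxonomy TSV; its ids must be a
#'   subset of the FASTA ids.
#' @param reference_id Optional reference sequence id (must be in the FASTA).
#' @return A [barcode_alignment()].
#' @export
read_alignment <- function(fasta_path, taxonomy_path = NULL,
                           reference_id = NULL) {
  if (!file.exists(fasta_path))
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  dna <- suppressWarnings(ape::read.FASTA(fasta_path))
  if (is.null(dna) || length(dna) == 0L)
    stop("no sequences found in ", fasta_path, call. = FALSE)
  ids <- names(dna)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("FASTA records must be named", call. = FALSE)
  # first whitespace-delimited token is the id, FASTA convention
  ids <- vapply(strsplit(ids, "[ \t]+"), `[[`, character(1L), 1L)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""),
                 character(1L))
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  barcode_alignment(ids, seqs, taxonomy = tax, reference_id = reference_id)
}

#' Write an alignment to FASTA (and optionally its taxonomy to TSV)
#'
#' @param aln A [barcode_alignment()].
#' @param fasta_path Output FASTA path.
#' @param taxonomy_path Optional output path for the taxonomy TSV.
#' @return `aln`, invisibly.
#' @export
write_alignment <- function(aln, fasta_path, taxonomy_path = NULL) {
  stopifnot(inherits(aln, "barcode_alignment"))
  lines <- character(2L * length(aln$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- aln$seqs
  writeLines(lines, fasta_path)
  if (!is.null(taxonomy_path)) {
    tax <- aln$taxonomy
    tax[is.na(tax)] <- ""
    utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(aln)
}

#' Trim an alignment to the 3' barcode window of a reference sequence
#'
#' Restricts the alignment to the columns spanning the last `window_length`
#' non-gap positions of the reference sequence (its 3' end), keeping any gap
#' columns interleaved within that span. This reproduces the usual barcoding
#' practice of anchoring a fixed-length window (e.g. 650 bp of COI) on a
#' complete reference record.
#'
#' Records whose trimmed sequence is more than 50% gaps/`N` are flagged with
#' a warning (and dropped if `drop_sparse = TRUE`).
#'
#' @param aln A [barcode_alignment()].
#' @param ref_id Id of the reference record.
#' @param window_length Number of reference bases in the window (>= 1).
#' @param drop_sparse Drop flagged sparse records instead of keeping them.
#' @return The trimmed [barcode_alignment()]; the reference retains exactly
#'   `window_length` non-gap characters.
#' @export
trim_to_reference_window <- function(aln, ref_id, window_length,
                                     drop_sparse = FALSE) {
  stopifnot(inherits(aln, "barcode_alignment"))
  if (!ref_id %in% aln$ids)
    stop("reference id '", ref_id, "' not found in alignment", call. = FALSE)
  window_length <- as.integer(window_length)
  if (is.na(window_length) || window_length < 1L)
    stop("window_length must be a positive integer", call. = FALSE)
  ref <- strsplit(aln$seqs[[match(ref_id, aln$ids)]], "")[[1L]]
  base_cols <- which(ref != "-")
  if (length(base_cols) < window_length)
    stop("reference '", ref_id, "' has only ", length(base_cols),
         " non-gap positions, fewer than window_length = ", window_length,
         call. = FALSE)
  keep <- utils::tail(base_cols, window_length)
  span <- seq.int(keep[[1L]], keep[[length(keep)]])
  seqs <- substr(aln$seqs, span[[1L]], span[[length(span)]])
  out <- barcode_alignment(aln$ids, seqs, taxonomy = aln$taxonomy,
                           reference_id = aln$reference_id)
  frac_bad <- vapply(strsplit(out$seqs, ""), function(s)
    mean(s %in% c("-", "N")), numeric(1L))
  sparse <- frac_bad > 0.5
  if (any(sparse)) {
    warning(sum(sparse), " record(s) >50% gap/N in trimmed window: ",
            paste(utils::head(out$ids[sparse], 5L), collapse = ", "),
            if (drop_sparse) " (dropped)" else " (retained)",
            call. = FALSE)
    if (drop_sparse) {
      keep_ids <- out$ids[!sparse]
      ref_kept <- if (!is.null(out$reference_id) &&
                      out$reference_id %in% keep_ids) out$reference_id
      out <- barcode_alignment(keep_ids, out$seqs[!sparse],
                               taxonomy = out$taxonomy[!sparse, ],
                               reference_id = ref_kept)
    }
  }
  out
}

#' Collapse duplicate haplotypes
#'
#' Records with byte-identical sequence strings are collapsed to a single
#' representative (the first occurrence in input order). Ambiguity codes are
#' not resolved: a sequence with `N` at a site differs from one with `A`.
#'
#' @param aln A [barcode_alignment()].
#' @return A list with elements `alignment` (representatives, in input
#'   order) and `map`, an object of class `haplotype_map`: a named list
#'   `representative id -> character vector of member ids` (each
#'   representative is a member of its own list).
#' @export
dedup_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  first <- !duplicated(aln$seqs)
  rep_of <- aln$ids[first][match(aln$seqs, aln$seqs[first])]
  map <- split(aln$ids, factor(rep_of, levels = aln$ids[first]))
  out <- barcode_alignment(aln$ids[first], aln$seqs[first],
                           taxonomy = aln$taxonomy[first, ],
                           reference_id =
                             if (!is.null(aln$reference_id) &&
                                 aln$reference_id %in% aln$ids[first])
                               aln$reference_id)
  list(alignment = out, map = structure(as.list(map), class = "haplotype_map"))
}

#' @export
print.haplotype_map <- function(x, ...) {
  n_members <- sum(lengths(x))
  cat("Haplotype map: ", length(x), " representatives for ", n_members,
      " sequences\n", sep = "")
  collapsed <- x[lengths(x) > 1L]
  if (length(collapsed))
    cat("  collapsed groups: ", length(collapsed), " (largest ",
        max(lengths(collapsed)), " members)\n", sep = "")
  invisible(x)
}

#' Write a haplotype map as a two-column TSV
#' @param map A `haplotype_map` from [dedup_haplotypes()].
#' @param path Output path; columns `representative_id`, `member_id`.
#' @return `map`, invisibly.
#' @export
write_haplotype_map <- function(map, path) {
  df <- data.frame(representative_id = rep(names(map), lengths(map)),
                   member_id = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map)
}
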