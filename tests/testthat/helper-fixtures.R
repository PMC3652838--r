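# Small programmatic fixtures shared across the test files.

make_aln <- function(seqs, ids = NULL, taxonomy = NULL, reference_id = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  barcode_alignment(ids, seqs, taxonomy = taxonomy,
                    reference_id = reference_id)
}

make_tax <- function(ids, species = NA, genus = NA, family = NA, group = NA) {
  data.frame(id = ids, species = species, genus = genus, family = family,
             group = group, stringsAsFactors = FALSE)
}

write_fasta_lines <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
}

random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}

# moderately diverged sequences (no K2P saturation): star radiation from a
# common ancestor at expected pairwise distance d
related_seqs <- function(n, len, d = 0.15) {
  root <- random_seqs(1, len)
  vapply(seq_len(n), function(i) evolve_sequence(root, d / 2),
         character(1L))
}

# Independent per-site re-count of p/K2P distances: a deliberately naive
# character-level oracle used to cross-check the vectorized implementation.
naive_distance <- function(a, b, model) {
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  nc <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(ca)) {
    x <- ca[[k]]; y <- cb[[k]]
    if (!x %in% c("A", "C", "G", "T") || !y %in% c("A", "C", "G", "T")) next
    nc <- nc + 1L
    if (x == y) next
    pair <- paste(sort(c(x, y)), collapse = "")
    if (pair %in% c("AG", "CT")) ts <- ts + 1L else tv <- tv + 1L
  }
  if (nc == 0L) return(NA_real_)
  if (model == "p") return((ts + tv) / nc)
  P <- ts / nc; Q <- tv / nc
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Brute-force one-sided signed-rank p by enumerating all 2^n sign vectors.
brute_signrank_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (alternative == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}
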