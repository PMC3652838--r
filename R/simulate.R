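# Kimura 2-parameter simulator. The substitution process has transition
# rate alpha (A<->G, C<->T) and transversion rate beta for each of the two
# transversion targets; kappa = alpha/beta is the transition/transversion
# rate ratio, and the expected number of substitutions per site over time t
# is d = (alpha + 2 beta) t. The stationary base distribution is uniform.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

k2p_site_probs <- function(branch_d, kappa) {
  bt <- branch_d / (kappa + 2)       # beta * t
  at <- kappa * bt                   # alpha * t
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.25 - 0.25 * exp(-4 * bt) # each of the two transversions
  c(ts = p_ts, tv = p_tv)
}

.ts_partner <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T (A=1 C=2 G=3 T=4)
.tv_first   <- c(2L, 1L, 2L, 1L)
.tv_second  <- c(4L, 3L, 4L, 3L)
.nt_chars <- c("A", "C", "G", "T")

evolve_coded <- function(parent, branch_d, kappa) {
  if (branch_d == 0) return(parent)
  pr <- k2p_site_probs(branch_d, kappa)
  u <- stats::runif(length(parent))
  child <- parent
  sel <- u < pr[["ts"]]
  child[sel] <- .ts_partner[parent[sel]]
  sel <- u >= pr[["ts"]] & u < pr[["ts"]] + pr[["tv"]]
  child[sel] <- .tv_first[parent[sel]]
  sel <- u >= pr[["ts"]] + pr[["tv"]] & u < pr[["ts"]] + 2 * pr[["tv"]]
  child[sel] <- .tv_second[parent[sel]]
  child
}

#' Evolve a sequence along a branch under the K2P model
#'
#' Each site mutates independently with the K2P transition probabilities
#' for a branch of expected length `branch_d` substitutions per site,
#' solved from `branch_d = (alpha + 2 beta) t` with `alpha / beta = kappa`:
#' `P(transition) = 1/4 + 1/4 exp(-4 bt) - 1/2 exp(-2 (at + bt))` and
#' `P(each transversion) = 1/4 - 1/4 exp(-4 bt)`. Uses the current R
#' random-number stream.
#'
#' @param parent Character string over `A C G T`.
#' @param branch_d Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio (> 0), default 2
#'   (typical insect mitochondrial bias).
#' @return The child sequence (character string, same length).
#' @export
evolve_sequence <- function(parent, branch_d, kappa = 2) {
  if (branch_d < 0) stop("branch_d must be >= 0", call. = FALSE)
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  coded <- encode_nt(parent)
  if (anyNA(coded))
    stop("parent sequence must contain only A/C/G/T", call. = FALSE)
  paste(.nt_chars[evolve_coded(coded, branch_d, kappa)], collapse = "")
}

random_root <- function(n_sites) {
  sample.int(4L, n_sites, replace = TRUE)  # uniform stationary composition
}

#' Simulate a species complex with known truth
#'
#' Generates an aligned set of barcode sequences from a star phylogeny: a
#' uniform-random ancestral sequence, one ancestor per species, and the
#' members of each species radiating from their ancestor. Branch lengths
#' are chosen so the *expected* K2P distance between two members of the
#' same species is `d_intra` and between members of different species is
#' `d_inter` (member branches `d_intra / 2`, species branches
#' `(d_inter - d_intra) / 2`), making parameter-recovery checks exact in
#' expectation. Defaults mirror a whitefly-type complex: 31 species,
#' within-species divergence about 1.2% and between-species about 15.7% on
#' a 650-bp window.
#'
#' An optional two-clade geometry (`clade_of` + `d_clade`) places the
#' species on two deep branches, adding `d_clade` expected divergence
#' between species of different clades.
#'
#' @param n_species Number of species (>= 1).
#' @param members_per_species Integer scalar or vector of per-species
#'   sample sizes (singletons allowed).
#' @param seq_length Number of sites (default 650).
#' @param d_intra Expected within-species K2P distance (proportion); a
#'   scalar, or a vector recycled over species to give some species a
#'   deeper internal divergence. Species branches are
#'   `(d_inter - d_intra) / 2` per species, which keeps the expected
#'   between-species distance at `d_inter` even when `d_intra` varies.
#' @param d_inter Expected between-species K2P distance (> `d_intra`).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param clade_of Optional integer vector (values 1 or 2) assigning each
#'   species to a clade.
#' @param d_clade Extra expected divergence between clades (proportion).
#' @return An object of class `species_complex`: list with `alignment`
#'   (a [barcode_alignment()] whose `species`/`group` taxonomy columns
#'   carry the truth), `truth` (named membership vector), `config`.
#' @export
simulate_complex <- function(n_species = 31, members_per_species = 3,
                             seq_length = 650, d_intra = 0.012,
                             d_inter = 0.157, kappa = 2, seed = NULL,
                             clade_of = NULL, d_clade = 0) {
  if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (any(d_intra < 0) || any(d_intra >= d_inter))
    stop("need 0 <= d_intra < d_inter", call. = FALSE)
  d_intra_sp <- rep_len(d_intra, n_species)
  sizes <- rep_len(as.integer(members_per_species), n_species)
  if (any(sizes < 1L)) stop("each species needs >= 1 member", call. = FALSE)
  if (!is.null(clade_of) && length(clade_of) != n_species)
    stop("clade_of must have one entry per species", call. = FALSE)
  with_seed(seed, {
    root <- random_root(seq_length)
    clade_anc <- NULL
    if (!is.null(clade_of) && d_clade > 0)
      clade_anc <- list(evolve_coded(root, d_clade / 2, kappa),
                        evolve_coded(root, d_clade / 2, kappa))
    ids <- character(0L); seqs <- character(0L); truth <- character(0L)
    sp_names <- sprintf("sp%02d", seq_len(n_species))
    for (s in seq_len(n_species)) {
      base <- if (is.null(clade_anc)) root else clade_anc[[clade_of[[s]]]]
      anc <- evolve_coded(base, (d_inter - d_intra_sp[[s]]) / 2, kappa)
      for (k in seq_len(sizes[[s]])) {
        tip <- evolve_coded(anc, d_intra_sp[[s]] / 2, kappa)
        ids <- c(ids, sprintf("%s_m%02d", sp_names[[s]], k))
        seqs <- c(seqs, paste(.nt_chars[tip], collapse = ""))
        truth <- c(truth, sp_names[[s]])
      }
    }
    tax <- data.frame(id = ids, species = truth, genus = "Bemisia",
                      family = "Aleyrodidae", group = truth,
                      stringsAsFactors = FALSE)
    aln <- barcode_alignment(ids, seqs, taxonomy = tax)
    structure(
      list(alignment = aln, truth = stats::setNames(truth, ids),
           config = list(n_species = n_species, members = sizes,
                         seq_length = seq_length, d_intra = d_intra,
                         d_inter = d_inter, kappa = kappa, seed = seed,
                         clade_of = clade_of, d_clade = d_clade)),
      class = "species_complex")
  })
}

#' @export
print.species_complex <- function(x, ...) {
  cfg <- x$config
  cat("Simulated species complex: ", cfg$n_species, " species, ",
      length(x$truth), " sequences x ", cfg$seq_length, " sites\n", sep = "")
  cat(sprintf("  expected divergence: %.1f%% within, %.1f%% between (kappa %g)\n",
              100 * cfg$d_intra, 100 * cfg$d_inter, cfg$kappa))
  if (!is.null(cfg$seed)) cat("  seed: ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' Default mitochondrial gene panel specification
#'
#' Eleven commonly used insect mitochondrial loci with realistic lengths
#' and relative divergence-rate multipliers: the two rRNAs evolve slower
#' than COI, the protein-coding NADH-dehydrogenase-type loci faster.
#'
#' @return `data.frame` with columns `gene`, `length`, `rate`.
#' @export
default_gene_specs <- function() {
  data.frame(
    gene = c("COI", "ATP6", "COII", "CytB", "ND1", "ND2", "ND3", "ND4",
             "ND5", "lrRNA", "srRNA"),
    length = c(1531L, 678L, 688L, 1137L, 936L, 978L, 354L, 1330L, 1717L,
               1300L, 780L),
    rate = c(1, 1.8, 1.5, 1.6, 1.7, 1.9, 1.8, 1.7, 2.0, 0.4, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-gene genome panel
#'
#' Taxa radiate from a star tree with one branch length per taxon, drawn
#' uniformly in `(0.5, 1.5) * base_depth / 2` so taxon pairs differ in
#' divergence depth (mean pairwise distance `base_depth` at rate
#' multiplier 1). Every gene is evolved on the *same* taxon branch
#' lengths, scaled by its rate multiplier; the shared depths are what
#' makes per-pair distances of different loci linearly related, as
#' observed across mitochondrial genes.
#'
#' @param n_taxa Number of taxa (default 20, giving 190 pairs per gene).
#' @param gene_specs `data.frame` with columns `gene`, `length` (>= 50)
#'   and `rate` (> 0); default [default_gene_specs()].
#' @param base_depth Expected pairwise distance at multiplier 1
#'   (default 0.15, a deep between-genus divergence).
#' @param kappa Transition/transversion rate ratio.
#' @param seed Integer seed.
#' @return A [gene_panel()] whose alignments are the simulated genes; the
#'   configuration is attached as attribute `config`.
#' @export
simulate_panel <- function(n_taxa = 20, gene_specs = default_gene_specs(),
                           base_depth = 0.15, kappa = 2, seed = NULL) {
  if (n_taxa < 2L) stop("need at least two taxa", call. = FALSE)
  if (any(gene_specs$length < 50L))
    stop("gene lengths must be >= 50", call. = FALSE)
  if (any(gene_specs$rate <= 0))
    stop("rate multipliers must be positive", call. = FALSE)
  with_seed(seed, {
    taxa <- sprintf("taxon%02d", seq_len(n_taxa))
    depths <- stats::runif(n_taxa, 0.5, 1.5) * base_depth / 2
    alns <- vector("list", nrow(gene_specs))
    names(alns) <- gene_specs$gene
    for (g in seq_len(nrow(gene_specs))) {
      L <- gene_specs$length[[g]]
      rate <- gene_specs$rate[[g]]
      root <- random_root(L)
      seqs <- vapply(seq_len(n_taxa), function(i)
        paste(.nt_chars[evolve_coded(root, rate * depths[[i]], kappa)],
              collapse = ""), character(1L))
      alns[[g]] <- barcode_alignment(taxa, seqs)
    }
    panel <- gene_panel(alns)
    attr(panel, "config") <- list(n_taxa = n_taxa, gene_specs = gene_specs,
                                  base_depth = base_depth, kappa = kappa,
                                  seed = seed)
    panel
  })
}
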