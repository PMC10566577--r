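#' Map k-mer types to their nested (k-2)-mer equivalence classes
#'
#' Two k-mer types are in the same class when they share the same nested
#' (k-2)-mer type (one flanking base trimmed from each side).
#'
#' @param types Character vector of k-mer type labels (k >= 3).
#' @return Factor of (k-2)-mer class labels, one per input type.
#' @export
nested_classes <- function(types) {
  k <- unique(parse_types(types)$k)
  if (length(k) != 1L || k < 3L) stop("types must share one context size k >= 3")
  factor(trim_type(types, k - 2L))
}

# per-type within-class target fractions for one species
.class_fractions <- function(types, targets) {
  anc <- parse_types(types)$anc
  t_m <- targets[anc]
  if (anyNA(t_m)) stop("target counts lack some ancestral k-mers")
  cls <- nested_classes(types)
  tot <- stats::ave(as.numeric(t_m), cls, FUN = sum)
  frac <- ifelse(tot > 0, t_m / tot, 0)
  stats::setNames(frac, types)
}

#' Randomize k-mer counts within nested (k-2)-mer equivalence classes
#'
#' For each genome and each (k-2)-mer class, the class's total count is
#' redistributed over the member k-mer types by a single multinomial draw
#' whose probabilities are the genome's within-class ancestral-target
#' fractions. This removes any dependence of mutation rate on the outermost
#' flanking bases while preserving the nested (k-2)-mer spectrum exactly.
#'
#' @param x A count-stage `spectrum_table` (k >= 3).
#' @param targets Genome target counts: a named vector (applied to every
#'   row) or a named list keyed by row label.
#' @param seed RNG seed.
#' @return A `spectrum_table` of randomized counts, same provenance plus
#'   `"class_randomized"`.
#' @export
randomize_within_classes <- function(x, targets, seed = NULL) {
  stopifnot(inherits(x, "spectrum_table"))
  .assert_counts(x, "randomize_within_classes()")
  types <- colnames(x)
  cls <- nested_classes(types)
  per_row <- if (is.list(targets)) targets else
    stats::setNames(rep(list(targets), nrow(x)), rownames(x))
  out <- unclass(x) * 0
  .with_seed(seed, {
    for (r in rownames(x)) {
      frac <- .class_fractions(types, per_row[[r]])
      for (cl in levels(cls)) {
        member <- which(cls == cl)
        total <- round(sum(x[r, member]))
        if (total == 0) next
        pr <- frac[member]
        if (sum(pr) == 0) next  # class with zero total target: skip
        out[r, member] <- as.numeric(stats::rmultinom(1, total, prob = pr))
      }
    }
  })
  .push_provenance(x, "class_randomized", out)
}

#' Conditional test for phylogenetic signal beyond the nested context
#'
#' Asks whether the k-mer spectrum carries phylogenetic signal beyond what
#' it inherits from its nested (k-2)-mer spectrum. The observed Mantel
#' correlation between Aitchison spectrum distances and phylogenetic
#' distances is compared against control spectra in which each genome's
#' k-mer counts are randomized within (k-2)-mer equivalence classes
#' (eliminating any species-specific dependence on the outer bases). Every
#' control passes through the identical downstream chain (pseudocount, CLR,
#' Aitchison distance, Mantel r). The p-value is
#' `(1 + #\{controls with r* >= r_obs\}) / (n_control + 1)`.
#'
#' @param x A count-stage `spectrum_table`, one row per species, at the
#'   same stage the empirical Mantel consumes (typically rescaled and
#'   downsampled).
#' @param targets Per-species target counts (named list keyed by row, or a
#'   single named vector).
#' @param d_phylo Phylogenetic distance matrix (square-rooted cophenetic
#'   distances).
#' @param n_control Number of control spectra (>= 1).
#' @param pseudocount Pseudocount applied before CLR.
#' @param seed RNG seed.
#' @return List with `r_observed`, `null_r` (length `n_control`), `p`,
#'   `n_control`.
#' @export
nested_signal_test <- function(x, targets, d_phylo, n_control = 5000,
                               pseudocount = 1, seed = NULL) {
  stopifnot(inherits(x, "spectrum_table"))
  if (n_control < 1) stop("n_control must be at least 1")
  d_phylo <- as.matrix(d_phylo)
  chain_r <- function(tab) {
    d <- aitchison_distance_matrix(clr(add_pseudocount(tab, pseudocount)))
    al <- .align_dist(d, d_phylo)
    .offdiag_cor(al$D1, al$D2)
  }
  r_obs <- chain_r(x)
  null_r <- .with_seed(seed, vapply(seq_len(n_control), function(i) {
    chain_r(randomize_within_classes(x, targets, seed = NULL))
  }, numeric(1)))
  p <- (1 + sum(null_r >= r_obs)) / (n_control + 1)
  list(r_observed = r_obs, null_r = null_r, p = p, n_control = n_control)
}
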