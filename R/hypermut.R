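#' Fisher's exact scan for hyper- and hypomutable k-mer types
#'
#' For one genome, compares each k-mer type's mutation rate (count over
#' ancestral-target count) against the rate of its central 1-mer class. The
#' 2x2 table for a focal type is
#' `[[x_k, t_k - x_k], [x_b, t_b - x_b]]`, where `x_b`/`t_b` are the 1-mer
#' class counts and central-base targets with the focal k-mer excluded
#' (avoiding self-comparison); the p-value is the standard two-sided
#' Fisher's exact probability (sum over tables at least as improbable as
#' the observed one). The reported fold enrichment follows the full 1-mer
#' rate: `(x_k / t_k) / (x_1 / t_1)`.
#'
#' Counts must be raw (unrescaled, undownsampled): rates are within-genome
#' and need no cross-species normalisation.
#'
#' @param x A raw count-stage `spectrum_table` with a single row (k >= 3).
#' @param targets Named target-count vector for the same genome.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return A data.frame with columns `type`, `count`, `target`,
#'   `class_count`, `class_target`, `fold`, `p`, `p_bonferroni_threshold`,
#'   `significant`, `is_cpg`.
#' @export
fisher_scan <- function(x, targets, alpha = 0.05) {
  stopifnot(inherits(x, "spectrum_table"))
  if (nrow(x) != 1L) stop("fisher_scan() works on a single-genome table")
  .assert_counts(x, "fisher_scan()")
  prov <- attr(x, "provenance")
  if (any(prov %in% c("rescaled", "downsampled", "pseudocount"))) {
    stop("fisher_scan() requires raw counts")
  }
  types <- colnames(x)
  p <- parse_types(types)
  x_k <- round(as.numeric(x[1, ]))
  t_k <- as.numeric(targets[p$anc])
  if (anyNA(t_k)) stop("target counts lack some ancestral k-mers")
  if (any(x_k > t_k)) stop("count exceeds target for some type (impossible)")
  cls <- central_1mer(types)
  x_1 <- as.numeric(tapply(x_k, cls, sum)[cls])
  # central-base targets: each ancestral central base serves 3 substitutions,
  # so class targets sum targets over distinct ancestral k-mers of the class
  base_target <- vapply(split(seq_along(types), cls), function(i) {
    sum(targets[unique(p$anc[i])])
  }, numeric(1))
  t_1 <- as.numeric(base_target[cls])
  ok <- t_k > 0
  fold <- rep(NA_real_, length(types))
  fold[ok] <- (x_k[ok] / t_k[ok]) / (x_1[ok] / t_1[ok])
  pv <- rep(NA_real_, length(types))
  for (i in which(ok)) {
    tab <- matrix(c(x_k[i], t_k[i] - x_k[i],
                    x_1[i] - x_k[i], (t_1[i] - t_k[i]) - (x_1[i] - x_k[i])),
                  2, 2, byrow = TRUE)
    pv[i] <- stats::fisher.test(tab)$p.value
  }
  n_tested <- sum(ok)
  thresh <- bonferroni_threshold(alpha, n_tested)
  data.frame(type = types,
             count = x_k, target = t_k,
             class_count = x_1, class_target = t_1,
             fold = fold, p = pv,
             p_bonferroni_threshold = thresh,
             significant = !is.na(pv) & pv < thresh,
             is_cpg = is_cpg_transition(types),
             stringsAsFactors = FALSE)
}

#' Species-specific CpG transition enrichment threshold
#'
#' The aggregate rate of all CpG-transition types (summed counts over
#' summed CpG-context targets) divided by the aggregate C>T 1-mer rate
#' (all C>T counts over all central-C targets). Used as the benchmark that
#' candidate hypermutable motifs must exceed.
#'
#' @param x A raw count-stage `spectrum_table`, single row, k >= 3.
#' @param targets Named target-count vector for the same genome.
#' @return The fold enrichment (scalar).
#' @export
cpg_enrichment_threshold <- function(x, targets) {
  stopifnot(inherits(x, "spectrum_table"))
  if (nrow(x) != 1L) stop("single-genome table required")
  s <- attr(x, "schema")
  if (s$k < 3L) stop("CpG context requires k >= 3")
  types <- colnames(x)
  p <- parse_types(types)
  ct <- central_1mer(types) == "C>T"
  if (sum(x[1, ct]) == 0) stop("no C>T counts observed")
  cpg <- is_cpg_transition(types)
  cpg_anc <- unique(p$anc[cpg])
  ct_anc <- unique(p$anc[p$central == "C"])
  rate_cpg <- sum(x[1, cpg]) / sum(targets[cpg_anc])
  rate_ct <- sum(x[1, ct]) / sum(targets[ct_anc])
  rate_cpg / rate_ct
}

#' Filter a Fisher scan for motifs more mutable than CpG transitions
#'
#' Keeps Bonferroni-significant non-CpG-transition types whose fold
#' enrichment meets or exceeds the genome's CpG transition threshold.
#'
#' @param records Data.frame from [fisher_scan()].
#' @param threshold Fold threshold from [cpg_enrichment_threshold()].
#' @return The filtered subset of `records`.
#' @export
flag_super_cpg <- function(records, threshold) {
  if (nrow(records) == 0) return(records)
  keep <- records$significant & !records$is_cpg &
    !is.na(records$fold) & records$fold >= threshold
  records[keep, , drop = FALSE]
}
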