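#' Signature sets
#'
#' A signature set is a types-by-signatures matrix of probability vectors
#' (columns sum to 1) over a schema's mutation-type universe.
#'
#' @param mat Numeric matrix, rows named by type labels, columns by
#'   signature names; columns are normalised to sum to 1.
#' @return A `signature_set` matrix.
#' @export
signature_set <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("signature rows must be named by mutation type")
  if (any(mat < 0)) stop("signature entries must be non-negative")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("a signature has zero total mass")
  mat <- sweep(mat, 2, cs, "/")
  structure(mat, class = c("signature_set", "matrix", "array"))
}

#' Read signatures from a COSMIC-style TSV
#'
#' Expects a header row of signature names and a first column of mutation
#' type labels (either this package's `"ACG>ATG"` form or the COSMIC
#' `"A[C>T]G"` form, which is converted).
#'
#' @param path TSV path.
#' @return A `signature_set`.
#' @export
read_signatures_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- df[[1]]
  cosmic <- grepl("^[ACGT]*\\[[ACGT]>[ACGT]\\][ACGT]*$", labels)
  if (any(cosmic)) {
    labels[cosmic] <- .from_cosmic(labels[cosmic])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  signature_set(m)
}

.from_cosmic <- function(x) {
  left <- sub("\\[.*$", "", x)
  right <- sub("^.*\\]", "", x)
  core <- sub("^.*\\[([ACGT]>[ACGT])\\].*$", "\\1", x)
  anc <- paste0(left, substr(core, 1, 1), right)
  type_label(anc, substr(core, 3, 3))
}

#' Write signatures to TSV
#' @param sigs A `signature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures_tsv <- function(sigs, path) {
  df <- data.frame(type = rownames(sigs), unclass(sigs), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parental-age regression coefficient table
#'
#' TSV with columns `class` (the six non-CpG 1-mer types), `slope_maternal`,
#' `intercept_maternal`, `slope_paternal`, `intercept_paternal`, in units of
#' de novo mutations per year of parental age (slopes) and mutations
#' (intercepts).
#'
#' A synthetic example table ships with the package (the real coefficients
#' come from published human-trio regression studies and are supplied by the
#' user).
#'
#' @param path TSV path.
#' @return Data.frame with those columns.
#' @examples
#' tb <- read_aging_table_tsv(system.file("extdata",
#'   "aging_coefficients_synthetic.tsv", package = "spectratree"))
#' build_aging_signatures(tb)
#' @export
read_aging_table_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("class", "slope_maternal", "intercept_maternal",
            "slope_paternal", "intercept_paternal")
  if (!all(need %in% names(df))) {
    stop("aging table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Build reproductive-aging mutational signatures
#'
#' From per-class parental-age regressions (expected mutations of class `c`
#' inherited from a parent of age `a`: `y_c(a) = m_c * a + b_c`), builds
#' three 6-class signatures over the 1-mer-minus-CpG spectrum:
#' the maternal age signature `m_c,mat / sum_c' m_c',mat`, the paternal age
#' signature `m_c,pat / sum_c' m_c',pat`, and the "young parent" signature
#' `(y_c,mat(a0) + y_c,pat(a0)) / sum_c' (...)` evaluated at the age of
#' puberty `a0` (13 years in humans).
#'
#' @param table Data.frame as returned by [read_aging_table_tsv()].
#' @param puberty_age Age at puberty used for the young-parent signature.
#' @return A `signature_set` with columns `maternal`, `paternal`,
#'   `young_parent` over the 1-mer "excluded" schema types.
#' @export
build_aging_signatures <- function(table, puberty_age = 13) {
  classes <- enumerate_types(spectrum_schema(1, "excluded"))
  if (!setequal(table$class, classes)) {
    stop("aging table classes must be exactly the 6 non-CpG 1-mer types")
  }
  table <- table[match(classes, table$class), ]
  mat <- table$slope_maternal
  pat <- table$slope_paternal
  young <- (mat * puberty_age + table$intercept_maternal) +
    (pat * puberty_age + table$intercept_paternal)
  norm1 <- function(v, name) {
    if (sum(v) == 0) stop(name, " signature has all-zero mass")
    out <- v / sum(v)
    if (any(out < 0)) {
      stop(name, " signature has negative entries after normalisation ",
           "(a negative slope dominates its class)")
    }
    out
  }
  m <- cbind(maternal = norm1(mat, "maternal"),
             paternal = norm1(pat, "paternal"),
             young_parent = norm1(young, "young_parent"))
  rownames(m) <- classes
  signature_set(m)
}

# multinomial log-likelihood of count rows under per-row mixture probs
.mix_loglik <- function(X, P) {
  sum(X[X > 0] * log(P[X > 0]))
}

#' Fit signature exposures by maximum-likelihood EM
#'
#' Models each genome's count vector as multinomial with probabilities
#' `p = sum_s e_s * sig_s` and estimates the exposure simplex `e` per
#' genome by expectation-maximisation
#' (`e_s <- sum_t x_t e_s sig_s(t) / p(t) / sum_t x_t`), whose
#' log-likelihood is non-decreasing at every iteration.
#'
#' @param x A count-stage `spectrum_table`.
#' @param sigs A `signature_set` over the same type universe.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @return An object of class `exposure_fit`: list with `exposures`
#'   (genomes x signatures, rows on the simplex), `reconstruction`
#'   (genomes x types, proportions), `residuals` (observed minus
#'   reconstructed proportions), `cosine` (per genome), `loglik`, and
#'   `loglik_trace`.
#' @export
fit_exposures <- function(x, sigs, max_iter = 2000, tol = 1e-10) {
  stopifnot(inherits(x, "spectrum_table"), inherits(sigs, "signature_set"))
  .assert_counts(x, "fit_exposures()")
  S <- .align_signatures(sigs, colnames(x))
  X <- unclass(x)
  fit <- .em_exposures(X, S, max_iter = max_iter, tol = tol)
  .finish_fit(X, S, fit$E, fit$trace, novel = NULL)
}

.align_signatures <- function(sigs, types) {
  if (!all(types %in% rownames(sigs))) {
    stop("signatures lack some of the spectrum's mutation types")
  }
  unclass(sigs)[types, , drop = FALSE]
}

.em_exposures <- function(X, S, E0 = NULL, max_iter = 2000, tol = 1e-10) {
  n <- nrow(X); ns <- ncol(S)
  E <- if (is.null(E0)) matrix(1 / ns, n, ns) else E0
  dimnames(E) <- list(rownames(X), colnames(S))
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    P <- E %*% t(S)                       # n x types
    if (any(P[X > 0] <= 0)) {
      stop("a type with positive count has probability 0 under all signatures")
    }
    ll <- .mix_loglik(X, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
    R <- X / P
    R[X == 0] <- 0
    E <- E * (R %*% S)
    E <- E / rowSums(E)
  }
  list(E = E, trace = trace)
}

.finish_fit <- function(X, S, E, trace, novel = NULL) {
  recon <- E %*% t(S)
  obs_prop <- sweep(X, 1, rowSums(X), "/")
  resid <- obs_prop - recon
  cosv <- vapply(seq_len(nrow(X)), function(i)
    cosine_similarity(obs_prop[i, ], recon[i, ]), numeric(1))
  names(cosv) <- rownames(X)
  structure(list(exposures = E, signatures = S,
                 reconstruction = recon, residuals = resid,
                 cosine = cosv, loglik = trace[length(trace)],
                 loglik_trace = trace, novel = novel),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("<exposure_fit> %d genomes x %d signatures, loglik = %.2f\n",
              nrow(x$exposures), ncol(x$exposures), x$loglik))
  cat("mean cosine similarity:", round(mean(x$cosine), 4), "\n")
  invisible(x)
}

#' Fit fixed signatures plus one novel signature
#'
#' Block EM that alternates per-genome exposure updates with updates of a
#' single novel signature shared by all genomes
#' (`novel_t` proportional to the expected counts attributed to the novel
#' component, pooled across genomes). The fit is restarted from several
#' seeded random initial signatures and the highest-likelihood solution is
#' returned; by likelihood nesting it can never fit worse than the
#' fixed-only model.
#'
#' @param x A count-stage `spectrum_table` with at least 2 rows.
#' @param fixed A `signature_set` of fixed signatures.
#' @param max_iter,tol EM controls.
#' @param n_restarts Number of seeded random restarts.
#' @param seed RNG seed.
#' @return An `exposure_fit` whose `signatures` include a `novel` column;
#'   element `novel_similarity` gives the cosine similarity of the novel
#'   signature to each fixed one.
#' @export
fit_extract_novel <- function(x, fixed, max_iter = 2000, tol = 1e-10,
                              n_restarts = 10, seed = NULL) {
  stopifnot(inherits(x, "spectrum_table"), inherits(fixed, "signature_set"))
  .assert_counts(x, "fit_extract_novel()")
  if (nrow(x) < 2) stop("novel-signature extraction needs at least 2 genomes")
  Sfix <- .align_signatures(fixed, colnames(x))
  X <- unclass(x)
  nt <- ncol(X)
  best <- NULL
  .with_seed(seed, {
    for (rs in seq_len(n_restarts)) {
      nov <- stats::rgamma(nt, 1, 1)
      nov <- nov / sum(nov)
      S <- cbind(Sfix, novel = nov)
      E <- matrix(1 / ncol(S), nrow(X), ncol(S),
                  dimnames = list(rownames(X), colnames(S)))
      ll_old <- -Inf
      trace <- numeric(0)
      for (it in seq_len(max_iter)) {
        P <- E %*% t(S)
        if (any(P[X > 0] <= 0)) stop("zero probability for an observed type")
        ll <- .mix_loglik(X, P)
        trace <- c(trace, ll)
        if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
        ll_old <- ll
        R <- X / P
        R[X == 0] <- 0
        # the same responsibilities feed both block updates
        E_new <- E * (R %*% S)
        # expected counts attributed to the novel component, pooled over genomes
        nov_counts <- S[, "novel"] * as.numeric(crossprod(R, E[, "novel"]))
        E <- E_new / rowSums(E_new)
        if (sum(nov_counts) > 0) {
          S[, "novel"] <- nov_counts / sum(nov_counts)
        }
      }
      if (is.null(best) || trace[length(trace)] > best$ll) {
        best <- list(E = E, S = S, trace = trace, ll = trace[length(trace)])
      }
    }
  })
  fit <- .finish_fit(X, best$S, best$E, best$trace,
                     novel = best$S[, "novel"])
  fit$novel_similarity <- vapply(colnames(Sfix), function(s)
    cosine_similarity(best$S[, "novel"], Sfix[, s]), numeric(1))
  if (any(fit$novel_similarity > 0.999)) {
    warning("novel signature degenerated onto a fixed signature (cosine > 0.999)")
  }
  fit
}

#' Reconstruction quality metrics for an exposure fit
#'
#' @param fit An `exposure_fit`.
#' @param observed The count-stage `spectrum_table` the fit was made on.
#' @return List with `cosine` (per genome) and `residuals` (observed minus
#'   reconstructed proportions; rows sum to 0).
#' @export
reconstruction_metrics <- function(fit, observed) {
  stopifnot(inherits(fit, "exposure_fit"))
  X <- unclass(observed)
  obs_prop <- sweep(X, 1, rowSums(X), "/")
  recon <- fit$reconstruction
  resid <- obs_prop - recon
  cosv <- vapply(seq_len(nrow(X)), function(i)
    cosine_similarity(obs_prop[i, ], recon[i, ]), numeric(1))
  names(cosv) <- rownames(X)
  list(cosine = cosv, residuals = resid)
}

#' Mantel test on reconstructed spectra
#'
#' CLR-transforms the fit's reconstructed proportions, computes Aitchison
#' distances between genomes, and runs a Mantel test against a phylogenetic
#' distance matrix. Zero reconstructed proportions are floored at a small
#' positive value with a warning.
#'
#' @param fit An `exposure_fit`.
#' @param d_phylo Phylogenetic distance matrix (square-rooted cophenetic).
#' @param n_perm,seed As in [mantel_test()].
#' @return A `mantel_result`.
#' @export
reconstructed_signal_test <- function(fit, d_phylo, n_perm = 999, seed = NULL) {
  recon <- fit$reconstruction
  if (any(recon <= 0)) {
    warning("zero reconstructed proportions floored before CLR")
    floorv <- min(recon[recon > 0]) / 2
    recon[recon <= 0] <- floorv
    recon <- sweep(recon, 1, rowSums(recon), "/")
  }
  d <- aitchison_distance_matrix(clr(recon))
  mantel_test(d, d_phylo, n_perm = n_perm, seed = seed)
}

#' Remove CpG-transition types from a spectrum and its signatures
#'
#' Drops CpG-transition columns from the table and the matching rows from
#' the signature set, renormalising each signature to sum to 1. For the
#' 7-class 1-mer + CpG schema this yields the 6-class spectrum.
#'
#' @param x A `spectrum_table` whose schema separates CpG
#'   (`cpg_policy = "separate"`, or any k >= 3 schema).
#' @param sigs Optional `signature_set` to strip in parallel.
#' @return The stripped `spectrum_table`, or `list(spectrum, signatures)`
#'   when `sigs` is supplied.
#' @export
strip_cpg <- function(x, sigs = NULL) {
  stopifnot(inherits(x, "spectrum_table"))
  s <- attr(x, "schema")
  if (s$cpg_policy == "excluded") {
    out <- x
  } else {
    if (s$k == 1L && s$cpg_policy == "merged") {
      stop("bare 1-mer schema cannot separate CpG transitions")
    }
    keep <- !is_cpg_transition(colnames(x))
    out <- spectrum_table(unclass(x)[, keep, drop = FALSE],
                          spectrum_schema(s$k, "excluded", s$folded),
                          provenance = attr(x, "provenance"))
  }
  if (is.null(sigs)) return(out)
  kept <- rownames(sigs)[!is_cpg_transition(rownames(sigs))]
  list(spectrum = out,
       signatures = signature_set(unclass(sigs)[kept, , drop = FALSE]))
}
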