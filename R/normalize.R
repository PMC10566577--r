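#' Rescale spectrum counts to a common genome composition
#'
#' Transforms each count `x[m->j]` into the count expected if the focal
#' genome's ancestral k-mer composition matched a chosen reference
#' composition while per-target mutation rates stayed fixed:
#' `x_r = x * (t_ref[m] / T_ref) / (t_A[m] / T_A)`, where `t_A[m]` is the
#' focal genome's target count for the ancestral k-mer of type `m` and
#' `T_A` its total (likewise `t_ref`, `T_ref` for the reference genome).
#' Rescaled counts are real-valued; only [downsample_multinomial()]
#' re-integerises.
#'
#' @param x A count-stage `spectrum_table`.
#' @param targets Target counts of the spectra's own genome(s): a named
#'   vector from [count_targets()] (applied to every row), or a named list
#'   of such vectors keyed by row label.
#' @param targets_ref Target counts of the reference composition.
#' @return A `spectrum_table` with provenance stage `"rescaled"`.
#' @export
rescale_counts <- function(x, targets, targets_ref) {
  stopifnot(inherits(x, "spectrum_table"))
  .assert_counts(x, "rescale_counts()")
  anc <- parse_types(colnames(x))$anc
  t_ref <- targets_ref[anc]
  T_ref <- sum(targets_ref)
  if (anyNA(t_ref)) stop("reference targets lack some ancestral k-mers")
  per_row <- if (is.list(targets)) targets else
    stats::setNames(rep(list(targets), nrow(x)), rownames(x))
  out <- unclass(x) * 0
  drop_warned <- FALSE
  for (r in rownames(x)) {
    tr <- per_row[[r]]
    if (is.null(tr)) stop("no target counts supplied for row ", r)
    t_A <- tr[anc]
    T_A <- sum(tr)
    bad <- t_A == 0 & x[r, ] > 0
    if (any(bad)) {
      stop("row ", r, ": observed mutations in k-mers with zero target count")
    }
    f <- (t_ref / T_ref) / (t_A / T_A)
    f[t_A == 0] <- 0
    zero_ref <- t_ref == 0 & x[r, ] > 0
    if (any(zero_ref)) {
      if (!drop_warned) {
        warning("types with zero reference target were zeroed out")
        drop_warned <- TRUE
      }
      f[zero_ref] <- 0
    }
    out[r, ] <- as.numeric(x[r, ]) * as.numeric(f)
  }
  .push_provenance(x, "rescaled", out)
}

#' Multinomial downsampling of spectrum rows
#'
#' Each row is replaced by one multinomial draw of size `n_target` with
#' probabilities proportional to the row's entries. Used to equalise SNP
#' numbers across genomes before log-ratio transformation.
#'
#' @param x A count-stage `spectrum_table`.
#' @param n_target Draw size; default is the minimum row total (rounded
#'   down), the lowest-diversity genome's count.
#' @param seed RNG seed.
#' @return A `spectrum_table` of integer counts, provenance `"downsampled"`.
#' @export
downsample_multinomial <- function(x, n_target = NULL, seed = NULL) {
  stopifnot(inherits(x, "spectrum_table"))
  .assert_counts(x, "downsample_multinomial()")
  if (any(rowSums(x) == 0)) stop("cannot downsample an all-zero row")
  if (is.null(n_target)) n_target <- floor(min(rowSums(x)))
  out <- unclass(x) * 0
  .with_seed(seed, {
    for (i in seq_len(nrow(x))) {
      out[i, ] <- as.numeric(stats::rmultinom(1, n_target, prob = x[i, ]))
    }
  })
  .push_provenance(x, "downsampled", out)
}

#' Add a pseudocount to every cell
#'
#' Regularises zero counts so the centred log-ratio transform is finite.
#'
#' @param x A count-stage `spectrum_table`.
#' @param c Pseudocount added to every cell (default 1).
#' @return A `spectrum_table` with provenance `"pseudocount"`.
#' @export
add_pseudocount <- function(x, c = 1) {
  stopifnot(inherits(x, "spectrum_table"))
  .assert_counts(x, "add_pseudocount()")
  .push_provenance(x, "pseudocount", unclass(x) + c)
}

#' Centred log-ratio transform
#'
#' `clr(p)_i = log(p_i) - mean_j log(p_j)`. Rows sum to zero and the
#' transform is invariant to rescaling a row by any positive constant.
#'
#' @param x Strictly positive numeric vector, matrix (row-wise), or
#'   count/proportion-stage `spectrum_table`.
#' @return Object of the same shape; `spectrum_table` input gains
#'   provenance `"clr"`.
#' @examples
#' clr(c(0.25, 0.75))
#' @export
clr <- function(x) {
  f <- function(v) {
    if (any(v <= 0)) stop("clr requires strictly positive entries")
    lv <- log(v)
    lv - mean(lv)
  }
  if (inherits(x, "spectrum_table")) {
    out <- t(apply(unclass(x), 1, f))
    return(.push_provenance(x, "clr", out))
  }
  if (is.matrix(x)) return(t(apply(x, 1, f)))
  f(x)
}

# orthonormal Helmert-type contrast basis for the D-part simplex: a
# D x (D-1) matrix V with V'V = I and columns summing to zero
.ilr_basis <- function(D) {
  V <- stats::contr.helmert(D)
  sweep(V, 2, sqrt(colSums(V^2)), "/")
}

#' Isometric log-ratio transform
#'
#' Projects the CLR image onto an orthonormal basis of the zero-sum
#' subspace, giving `D - 1` coordinates whose Euclidean distances equal
#' Aitchison (CLR) distances. The default basis is a normalised
#' Helmert-type contrast in schema order.
#'
#' @param x Strictly positive vector, matrix, or `spectrum_table`.
#' @param basis Optional `D x (D-1)` orthonormal zero-sum basis.
#' @return ILR coordinates; `spectrum_table` input returns a plain matrix
#'   (the coordinates no longer index mutation types).
#' @export
ilr <- function(x, basis = NULL) {
  vecin <- !is.matrix(x) && !inherits(x, "spectrum_table")
  m <- if (inherits(x, "spectrum_table")) unclass(x) else if (is.matrix(x)) x else matrix(x, 1)
  D <- ncol(m)
  if (is.null(basis)) basis <- .ilr_basis(D)
  if (!all(dim(basis) == c(D, D - 1L)) ||
      max(abs(crossprod(basis) - diag(D - 1L))) > 1e-8 ||
      max(abs(colSums(basis))) > 1e-8) {
    stop("basis must be an orthonormal D x (D-1) zero-sum contrast matrix")
  }
  out <- clr(m) %*% basis
  rownames(out) <- rownames(m)
  if (vecin) as.numeric(out) else out
}

#' Aitchison distance matrix between spectrum rows
#'
#' Euclidean distance between CLR-transformed rows. Accepts a CLR-stage
#' table directly, or a positive count/proportion table which is
#' CLR-transformed on the fly.
#'
#' @param x A `spectrum_table` or numeric matrix.
#' @return Labelled symmetric distance matrix with zero diagonal.
#' @export
aitchison_distance_matrix <- function(x) {
  m <- if (inherits(x, "spectrum_table")) unclass(x) else as.matrix(x)
  already_clr <- if (inherits(x, "spectrum_table")) {
    "clr" %in% attr(x, "provenance")
  } else {
    max(abs(rowSums(m))) < 1e-8   # CLR rows sum to zero
  }
  if (!already_clr) m <- clr(m)
  d <- as.matrix(stats::dist(m))
  attr(d, "kind") <- "aitchison"
  d
}

#' Cosine similarity between two vectors
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Convert counts to row proportions
#'
#' @param x A count-stage `spectrum_table`.
#' @return A `spectrum_table` of proportions (rows sum to 1).
#' @export
to_proportions <- function(x) {
  stopifnot(inherits(x, "spectrum_table"))
  .assert_counts(x, "to_proportions()")
  if (any(rowSums(x) == 0)) stop("cannot normalise an all-zero row")
  .push_provenance(x, "proportions", sweep(unclass(x), 1, rowSums(x), "/"))
}
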