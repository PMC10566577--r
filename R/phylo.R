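#' Cophenetic distance matrix of a phylogeny
#'
#' Sum of branch lengths on the path between every pair of leaves, with an
#' optional elementwise square root. Under Brownian trait evolution the
#' expected squared trait distance between two leaves is proportional to
#' their cophenetic distance, so trait distances are compared against the
#' square-rooted matrix.
#'
#' @param tree An `ape::phylo` tree, or a Newick string/file path.
#' @param sqrt_transform Take the elementwise square root.
#' @return Labelled symmetric distance matrix.
#' @export
cophenetic_matrix <- function(tree, sqrt_transform = FALSE) {
  tree <- .as_tree(tree)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length")
  }
  d <- ape::cophenetic.phylo(tree)
  if (sqrt_transform) d <- sqrt(d)
  attr(d, "kind") <- if (sqrt_transform) "sqrt_cophenetic" else "cophenetic"
  d
}

.as_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, Newick string, or file path")
}

# align D2's labels to D1's and return the pair of lower-triangle vectors
.align_dist <- function(D1, D2) {
  if (is.null(rownames(D1)) || is.null(rownames(D2))) {
    if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in size")
    return(list(D1 = D1, D2 = D2))
  }
  if (!setequal(rownames(D1), rownames(D2))) {
    stop("distance matrices have different label sets")
  }
  list(D1 = D1, D2 = D2[rownames(D1), rownames(D1)])
}

#' Smallest attainable Mantel permutation p-value
#'
#' The permutation estimator `p = (1 + b) / (n_perm + 1)` cannot fall below
#' `1 / (n_perm + 1)`; e.g. 99,999 permutations floor at 1e-5.
#'
#' @param n_perm Number of permutations.
#' @return The floor `1 / (n_perm + 1)`.
#' @export
mantel_p_floor <- function(n_perm) 1 / (n_perm + 1)

.offdiag_cor <- function(D1, D2) {
  stats::cor(D1[lower.tri(D1)], D2[lower.tri(D2)])
}

#' Mantel permutation test for distance-matrix correlation
#'
#' The statistic is the Pearson correlation over off-diagonal entries of
#' the two matrices; the null distribution is built by jointly permuting
#' rows and columns of the second matrix. The p-value uses the
#' bias-corrected estimator `(1 + #\{r* >= r\}) / (n_perm + 1)` for the
#' upper tail (and symmetrically for other tails). With
#' `permutations = "exhaustive"` (feasible for <= 7 labels) all `n!` label
#' permutations are enumerated and `p = #\{r* >= r\} / n!`.
#'
#' @param D1,D2 Labelled symmetric distance matrices over the same label
#'   set.
#' @param n_perm Number of random permutations.
#' @param tail `"greater"` (default), `"less"`, or `"two.sided"`.
#' @param seed RNG seed.
#' @param permutations `"random"` or `"exhaustive"`.
#' @return An object of class `mantel_result` with elements `r`, `p`,
#'   `n_perm`, `tail`, `p_floor`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, tail = c("greater", "less", "two.sided"),
                        seed = NULL, permutations = c("random", "exhaustive")) {
  tail <- match.arg(tail)
  permutations <- match.arg(permutations)
  al <- .align_dist(as.matrix(D1), as.matrix(D2))
  D1 <- al$D1; D2 <- al$D2
  n <- nrow(D1)
  v1 <- D1[lower.tri(D1)]
  if (stats::sd(v1) == 0 || stats::sd(D2[lower.tri(D2)]) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  r_obs <- .offdiag_cor(D1, D2)
  tail_count <- function(r_perm) {
    switch(tail,
           greater = sum(r_perm >= r_obs),
           less = sum(r_perm <= r_obs),
           two.sided = sum(abs(r_perm) >= abs(r_obs)))
  }
  if (permutations == "exhaustive") {
    if (n > 7L) stop("exhaustive enumeration limited to 7 labels")
    perms <- .all_permutations(n)
    r_perm <- vapply(perms, function(p) .offdiag_cor(D1, D2[p, p]), numeric(1))
    p <- tail_count(r_perm) / length(perms)
    n_perm <- length(perms)
  } else {
    if (n_perm < 1) stop("n_perm must be at least 1")
    r_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      .offdiag_cor(D1, D2[p, p])
    }, numeric(1)))
    p <- (1 + tail_count(r_perm)) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, tail = tail,
                 p_floor = mantel_p_floor(n_perm), seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.3g (%s tail, %d permutations)\n",
              x$r, x$p, x$tail, x$n_perm))
  invisible(x)
}

.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Phylogenetically aware (partial) Mantel test
#'
#' Correlates the residuals of `D1 ~ D3` with the residuals of `D2 ~ D3`
#' (least squares over off-diagonal entries), asking whether `D2` explains
#' variation in `D1` beyond what the phylogeny `D3` explains. The null is
#' built by permuting the labels of the residual matrix of `D1`.
#'
#' @param D1 Response distance matrix (e.g. spectrum distances).
#' @param D2 Covariate distance matrix.
#' @param D3 Conditioning (phylogenetic) distance matrix.
#' @param n_perm,tail,seed As in [mantel_test()].
#' @return A `mantel_result`.
#' @export
partial_mantel <- function(D1, D2, D3, n_perm = 999,
                           tail = c("greater", "less", "two.sided"), seed = NULL) {
  tail <- match.arg(tail)
  D1 <- as.matrix(D1)
  al2 <- .align_dist(D1, as.matrix(D2)); D2 <- al2$D2
  al3 <- .align_dist(D1, as.matrix(D3)); D3 <- al3$D2
  lt <- lower.tri(D1)
  res_mat <- function(Y, X) {
    fit <- stats::lm.fit(cbind(1, X[lt]), Y[lt])
    R <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y))
    R[lt] <- fit$residuals
    R + t(R)
  }
  R1 <- res_mat(D1, D3)
  R2 <- res_mat(D2, D3)
  if (stats::sd(R1[lt]) == 0) {
    stop("response fully explained by the conditioning matrix: correlation undefined")
  }
  if (stats::sd(R2[lt]) < 1e-12) {
    # covariate carries no information beyond the conditioning matrix
    warning("covariate residuals are constant; partial correlation is 0")
    return(structure(list(r = 0, p = 1, n_perm = n_perm, tail = tail,
                          p_floor = mantel_p_floor(n_perm), seed = seed),
                     class = "mantel_result"))
  }
  r_obs <- .offdiag_cor(R1, R2)
  r_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(nrow(R1))
    .offdiag_cor(R1[p, p], R2)
  }, numeric(1)))
  b <- switch(tail,
              greater = sum(r_perm >= r_obs),
              less = sum(r_perm <= r_obs),
              two.sided = sum(abs(r_perm) >= abs(r_obs)))
  structure(list(r = r_obs, p = (1 + b) / (n_perm + 1), n_perm = n_perm,
                 tail = tail, p_floor = mantel_p_floor(n_perm), seed = seed),
            class = "mantel_result")
}

#' Multivariate Blomberg's K (K_mult)
#'
#' Measures phylogenetic signal in a multivariate trait as the ratio of
#' observed to Brownian-expected trait structure. With `C` the Brownian
#' tip covariance implied by the tree, `a` the generalised-least-squares
#' phylogenetic mean, and `Y` the tips-by-traits matrix,
#' `K = [sum((Y-a)^2) / sum((Y-a)' C^-1 (Y-a))] /
#'     [(tr(C) - n / sum(C^-1)) / (n - 1)]`.
#' K equals 1 in expectation under Brownian motion; smaller values mean
#' less phylogenetic structure than Brownian expectation. Significance is
#' assessed by shuffling tip labels.
#'
#' @param tree Phylogeny (`phylo`, Newick string, or path).
#' @param traits Numeric matrix (rows = tips, rownames = tip labels) or a
#'   CLR-stage `spectrum_table` with one row per tip.
#' @param n_perm Number of tip-label permutations (0 skips the test).
#' @param seed RNG seed.
#' @return An object of class `kmult_result` with `K`, `p`, `n_perm`.
#' @export
k_mult <- function(tree, traits, n_perm = 999, seed = NULL) {
  tree <- .as_tree(tree)
  Y <- if (inherits(traits, "spectrum_table")) unclass(traits) else as.matrix(traits)
  if (is.null(rownames(Y))) stop("traits must have tip labels as rownames")
  if (!setequal(rownames(Y), tree$tip.label)) {
    stop("trait rows do not match the tree's tips")
  }
  Y <- Y[tree$tip.label, , drop = FALSE]
  C <- ape::vcv(tree)
  Ci <- tryCatch(solve(C), error = function(e) stop("singular tip covariance matrix"))
  n <- nrow(Y)
  one <- matrix(1, n, 1)
  denom_scale <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  kstat <- function(Ym) {
    a <- as.numeric(crossprod(one, Ci %*% Ym)) / sum(Ci)
    Yt <- sweep(Ym, 2, a)
    num <- sum(Yt^2)
    den <- sum(Yt * (Ci %*% Yt))
    (num / den) / denom_scale
  }
  K_obs <- kstat(Y)
  p <- NA_real_
  if (n_perm > 0) {
    K_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
      kstat(Y[sample.int(n), , drop = FALSE])
    }, numeric(1)))
    p <- (1 + sum(K_perm >= K_obs)) / (n_perm + 1)
  }
  structure(list(K = K_obs, p = p, n_perm = n_perm, seed = seed),
            class = "kmult_result")
}

#' @export
print.kmult_result <- function(x, ...) {
  cat(sprintf("K_mult = %.4f, p = %.3g (%d permutations)\n", x$K, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise absolute-difference matrix of a scalar covariate
#'
#' @param values Named numeric vector (one value per species).
#' @param species Optional label set to require/order by.
#' @return Labelled symmetric matrix of `|v_i - v_j|`.
#' @export
scalar_distance_matrix <- function(values, species = names(values)) {
  if (is.null(names(values))) stop("values must be named by species")
  missing_sp <- setdiff(species, names(values))
  if (length(missing_sp)) stop("missing species: ", paste(missing_sp, collapse = ", "))
  v <- values[species]
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(species, species)
  attr(d, "kind") <- "scalar_abs_diff"
  d
}

#' Watterson's theta per site
#'
#' `S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`, where `S` is the number
#' of segregating sites, `n` the number of sampled chromosomes, and `L` the
#' accessible sequence length.
#'
#' @param n_chromosomes Number of sampled chromosomes (>= 2).
#' @param n_segregating Number of segregating sites.
#' @param L_accessible Accessible sequence length (> 0).
#' @return Per-site Watterson's theta.
#' @export
watterson_theta <- function(n_chromosomes, n_segregating, L_accessible) {
  if (n_chromosomes < 2) stop("need at least 2 chromosomes")
  if (L_accessible <= 0) stop("L_accessible must be positive")
  a_n <- sum(1 / seq_len(n_chromosomes - 1))
  n_segregating / (a_n * L_accessible)
}

#' PCA of CLR-transformed spectra
#'
#' Column-centred singular value decomposition of the CLR rows. The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param x A CLR-stage `spectrum_table` (or numeric matrix of CLR rows).
#' @return List with `scores` (rows = samples), `loadings` (rows = types),
#'   and `var_frac` (variance fractions summing to 1).
#' @export
clr_pca <- function(x) {
  m <- if (inherits(x, "spectrum_table")) {
    if (!"clr" %in% attr(x, "provenance")) stop("clr_pca() expects a CLR-stage table")
    unclass(x)
  } else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 rows for PCA")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, var_frac = vf)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 7)  # 0.00714...
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}
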