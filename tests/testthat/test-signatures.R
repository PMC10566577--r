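aging_table <- function(m_mat, b_mat, m_pat, b_pat) {
  data.frame(class = enumerate_types(spectrum_schema(1, "excluded")),
             slope_maternal = m_mat, intercept_maternal = b_mat,
             slope_paternal = m_pat, intercept_paternal = b_pat)
}

test_that("reproductive-aging signatures are normalised regression slopes", {
  # equal slopes give the uniform signature
  tb <- aging_table(rep(0.1, 6), rep(2, 6), rep(0.3, 6), rep(5, 6))
  sigs <- build_aging_signatures(tb)
  expect_equal(as.numeric(sigs[, "maternal"]), rep(1 / 6, 6))
  expect_equal(as.numeric(sigs[, "paternal"]), rep(1 / 6, 6))
  expect_equal(as.numeric(sigs[, "young_parent"]), rep(1 / 6, 6))
  # worked example: paternal slopes (2,1,1,1,1,0)
  tb2 <- aging_table(rep(0.1, 6), rep(0, 6), c(2, 1, 1, 1, 1, 0), rep(0, 6))
  sigs2 <- build_aging_signatures(tb2)
  expect_equal(as.numeric(sigs2[, "paternal"]),
               c(1 / 3, 1 / 6, 1 / 6, 1 / 6, 1 / 6, 0))
  # zero intercepts, equal slopes for both parents: young parent uniform
  tb3 <- aging_table(rep(0.2, 6), rep(0, 6), rep(0.2, 6), rep(0, 6))
  expect_equal(as.numeric(build_aging_signatures(tb3)[, "young_parent"]),
               rep(1 / 6, 6))
  # every signature sums to one
  expect_equal(unname(colSums(sigs2)), rep(1, 3))
  # a dominating negative slope is rejected with a diagnostic
  tb4 <- aging_table(c(-1, rep(0.1, 5)), rep(0, 6), rep(0.3, 6), rep(0, 6))
  expect_error(build_aging_signatures(tb4), "negative")
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tb2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_aging_table_tsv(f), tb2, ignore_attr = TRUE)
})

test_that("exposure EM recovers known mixtures with monotone likelihood", {
  sch <- spectrum_schema(3)
  sigs <- two_signatures(sch)
  # spectrum sampled exactly from one signature
  one <- simulate_signature_mixture(sigs, c(sigA = 1, sigB = 0), 2e5, sch, seed = 1)
  f1 <- fit_exposures(one, sigs)
  expect_gt(f1$exposures[1, "sigA"], 1 - 1e-4)
  # 0.3 / 0.7 mixture at n = 1e6
  mix <- simulate_signature_mixture(sigs, rbind(sp = c(0.3, 0.7)), 1e6, sch, seed = 2)
  f2 <- fit_exposures(mix, sigs)
  expect_lt(max(abs(f2$exposures[1, ] - c(0.3, 0.7))), 0.01)
  # exposures live on the simplex
  expect_equal(unname(rowSums(f2$exposures)), 1)
  expect_true(all(f2$exposures >= 0))
  # monotone non-decreasing log-likelihood trace
  expect_true(all(diff(f2$loglik_trace) >= -1e-8))
  # oracle: direct multinomial log-likelihood evaluation at the fitted point
  P <- f2$exposures %*% t(f2$signatures)
  x <- as.numeric(mix[1, ])
  expect_equal(f2$loglik, sum(x[x > 0] * log(P[1, ][x > 0])), tolerance = 1e-9)
})

test_that("novel-signature extraction recovers a planted hidden process", {
  sch <- spectrum_schema(3)
  fixed <- two_signatures(sch, seed = 30)
  types <- enumerate_types(sch)
  hidden <- spectratree:::.with_seed(31, {
    w <- stats::rgamma(length(types), 0.3, 1) + 1e-5
    w / sum(w)
  })
  all3 <- signature_set(cbind(unclass(fixed), hidden = hidden))
  n_sp <- 8
  expo <- t(sapply(seq_len(n_sp), function(i) {
    if (i <= 4) c(0.5, 0.5, 0) else c(0.35, 0.35, 0.3)  # hidden in half the genomes
  }))
  rownames(expo) <- paste0("sp", seq_len(n_sp))
  colnames(expo) <- colnames(all3)
  counts <- simulate_signature_mixture(all3, expo, 1e6, sch, seed = 32)
  fit <- fit_extract_novel(counts, fixed, n_restarts = 5, seed = 33)
  expect_gte(cosine_similarity(fit$novel, hidden), 0.95)
  # nesting: at least as good as the fixed-only fit
  fit_fixed <- fit_exposures(counts, fixed)
  expect_gte(fit$loglik, fit_fixed$loglik)
  # null data: novel exposures collapse toward zero
  null_counts <- simulate_signature_mixture(fixed,
    matrix(0.5, 4, 2, dimnames = list(paste0("n", 1:4), colnames(fixed))),
    5e5, sch, seed = 34)
  fit_null <- suppressWarnings(fit_extract_novel(null_counts, fixed,
                                                 n_restarts = 3, seed = 35))
  expect_gte(fit_null$loglik, fit_exposures(null_counts, fixed)$loglik)
})

test_that("reconstruction metrics and the reconstructed-spectrum Mantel test compose", {
  sch <- spectrum_schema(3)
  sigs <- two_signatures(sch, seed = 40)
  expo <- rbind(a = c(0.2, 0.8), b = c(0.9, 0.1), c = c(0.5, 0.5))
  colnames(expo) <- colnames(sigs)
  counts <- simulate_signature_mixture(sigs, expo, 5e5, sch, seed = 41)
  fit <- fit_exposures(counts, sigs)
  met <- reconstruction_metrics(fit, counts)
  expect_true(all(met$cosine > 0.99))
  expect_lt(max(abs(rowSums(met$residuals))), 1e-12)
  expect_equal(met$cosine, fit$cosine)
  # perfect reconstruction: feed the reconstruction itself as "observed"
  perfect <- spectrum_table(fit$reconstruction * 1e6, sch)
  met_p <- reconstruction_metrics(fit, perfect)
  expect_equal(unname(met_p$cosine), rep(1, 3), tolerance = 1e-12)
  expect_lt(max(abs(met_p$residuals)), 1e-12)
  # Mantel on reconstructions equals composing the public ops
  d_phylo <- cophenetic_matrix("((a:1,b:1):1,c:2);", sqrt_transform = TRUE)
  res <- reconstructed_signal_test(fit, d_phylo, n_perm = 99, seed = 42)
  d_manual <- aitchison_distance_matrix(clr(fit$reconstruction))
  res_manual <- mantel_test(d_manual, d_phylo, n_perm = 99, seed = 42)
  expect_equal(res$r, res_manual$r, tolerance = 1e-12)
  expect_equal(res$p, res_manual$p)
  # identical exposures give identical reconstructions: constant matrix error
  same <- simulate_signature_mixture(sigs,
    matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 3, 2,
           dimnames = list(c("a", "b", "c"), colnames(sigs))), 5e5, sch, seed = 43)
  fit_same <- fit_exposures(same, sigs)
  fit_same$reconstruction <- fit_same$reconstruction[c(1, 1, 1), ]
  rownames(fit_same$reconstruction) <- c("a", "b", "c")
  expect_error(reconstructed_signal_test(fit_same, d_phylo, n_perm = 9), "constant")
})

test_that("CpG stripping drops the class and renormalises", {
  sch7 <- spectrum_schema(1, "separate")
  m <- matrix(1:7, 1, dimnames = list("s", enumerate_types(sch7)))
  tab <- spectrum_table(m, sch7)
  sigs <- signature_set(matrix(rep(1 / 7, 7), 7, 1,
                               dimnames = list(enumerate_types(sch7), "flat")))
  out <- strip_cpg(tab, sigs)
  expect_equal(ncol(out$spectrum), 6)
  expect_false("CpG>TpG" %in% colnames(out$spectrum))
  expect_equal(unname(colSums(out$signatures)), 1)
  # idempotence
  again <- strip_cpg(out$spectrum)
  expect_equal(unclass(again), unclass(out$spectrum))
  # k = 3: 96 -> 92
  t3 <- spectrum_table(matrix(1, 1, 96), spectrum_schema(3))
  expect_equal(ncol(strip_cpg(t3)), 92)
})

test_that("signature TSV I/O understands COSMIC-style labels", {
  sch <- spectrum_schema(3)
  sigs <- two_signatures(sch, seed = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signatures_tsv(sigs, f)
  back <- read_signatures_tsv(f)
  expect_equal(unclass(back), unclass(sigs), tolerance = 1e-12)
  # COSMIC bracket notation
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("type\tS1", "A[C>T]G\t0.75", "T[A>G]C\t0.25"), f2)
  s2 <- read_signatures_tsv(f2)
  expect_setequal(rownames(s2), c("ACG>ATG", "TAC>TGC"))
  expect_equal(s2["ACG>ATG", "S1"], 0.75)
})
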