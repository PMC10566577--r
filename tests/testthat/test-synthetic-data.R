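test_that("genome simulation respects its configuration", {
  sim0 <- simulate_reference_and_ancestral(length = 5000, substitution_fraction = 0,
                                           mask_fraction = 0, seed = 1)
  expect_identical(sim0$ancestral, sim0$reference)
  expect_length(sim0$masks, 0)
  sim <- simulate_reference_and_ancestral(length = 20000, substitution_fraction = 0.02,
                                          mask_fraction = 0.1, seed = 2)
  ndiff <- sum(strsplit(sim$ancestral[[1]], "")[[1]] !=
               strsplit(sim$reference[[1]], "")[[1]])
  expect_equal(ndiff, round(0.02 * 20000), tolerance = 0.2)
  expect_gt(sum(GenomicRanges::width(sim$masks)), 0)
  # base composition within 3 SE of the configured weights
  w <- c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)
  sim2 <- simulate_reference_and_ancestral(length = 50000, base_weights = w,
                                           mask_fraction = 0, seed = 3)
  freq <- table(strsplit(sim2$ancestral[[1]], "")[[1]]) / 50000
  se <- sqrt(w * (1 - w) / 50000)
  expect_true(all(abs(freq[names(w)] - w) <= 3 * se))
  # determinism
  simA <- simulate_reference_and_ancestral(length = 3000, seed = 9)
  simB <- simulate_reference_and_ancestral(length = 3000, seed = 9)
  expect_identical(simA, simB)
  # files are written when a directory is given
  d <- withr::local_tempdir()
  simF <- simulate_reference_and_ancestral(length = 2000, seed = 4, out_dir = d)
  expect_true(all(file.exists(unlist(simF$paths))))
  reread <- spectratree:::.load_genome(simF$paths$ancestral)
  expect_identical(unname(reread), unname(simF$ancestral))
})

test_that("CLR Brownian evolution scales with cophenetic distance", {
  tree <- example_mammal_tree()
  sch <- spectrum_schema(1)
  root <- uniform_comp(sch)
  # sigma2 = 0 leaves every leaf at the root composition
  flat <- evolve_spectra_on_tree(tree, root, sigma2 = 0, seed = 1)
  expect_true(all(abs(flat - 1 / 6) < 1e-12))
  expect_error(evolve_spectra_on_tree(tree, root, sigma2 = -1), "non-negative")
  # mean squared Aitchison distance grows linearly in cophenetic distance
  dc <- cophenetic_matrix(tree)
  lt <- lower.tri(dc)
  msd <- matrix(0, 13, 13)
  nrep <- 60
  for (i in seq_len(nrep)) {
    comp <- evolve_spectra_on_tree(tree, root, sigma2 = 1, seed = 100 + i)
    d <- aitchison_distance_matrix(clr(comp))[rownames(dc), colnames(dc)]
    msd <- msd + d^2 / nrep
  }
  fitl <- stats::lm(msd[lt] ~ dc[lt])
  expect_gt(stats::coef(fitl)[2], 0)
  expect_lt(abs(stats::coef(fitl)[1]), 0.1 * max(msd))
  expect_gt(stats::cor(msd[lt], dc[lt]), 0.9)
  # sister leaves end up closer than distant leaves on average
  expect_lt(msd["Polar_bear", "Brown_bear"], msd["Polar_bear", "Mouse_musculus"])
})

test_that("emitted VCFs match the generator's truth bookkeeping exactly", {
  bundle <- sim_bundle(length = 30000, seed = 51)
  sch <- spectrum_schema(3)
  comp <- rand_comp(96, seed = 52)
  names(comp) <- enumerate_types(sch)
  path <- withr::local_tempfile(fileext = ".vcf")
  ev <- emit_vcf(comp, bundle$sim$ancestral, bundle$regions, sch,
                 n_individuals = 4, n_snps = 800, species = "wolf",
                 seed = 53, path = path)
  expect_equal(sum(ev$truth), 800)
  tab <- classify_variants(path, bundle$sim$ancestral, bundle$regions, sch, seed = 54)
  agg <- aggregate_species(tab)
  expect_equal(as.numeric(agg), as.numeric(ev$truth))
  expect_equal(attr(tab, "n_sites"), 800)
  # per-individual assignment split the same 800 sites
  expect_equal(sum(tab), 800)
  # determinism: identical seeds give byte-identical VCF lines
  ev2 <- emit_vcf(comp, bundle$sim$ancestral, bundle$regions, sch,
                  n_individuals = 4, n_snps = 800, species = "wolf", seed = 53)
  expect_identical(ev2$vcf_lines, ev$vcf_lines)
  # n_snps = 0 gives a header-only VCF
  ev0 <- emit_vcf(comp, bundle$sim$ancestral, bundle$regions, sch,
                  n_individuals = 2, n_snps = 0, seed = 55)
  expect_true(all(startsWith(ev0$vcf_lines, "#")))
  expect_equal(sum(ev0$truth), 0)
})

test_that("truth identity holds for the CpG-aware 1-mer schema", {
  bundle <- sim_bundle(length = 20000, seed = 61)
  sch <- spectrum_schema(1, "separate")
  comp <- stats::setNames(c(0.1, 0.2, 0.1, 0.15, 0.05, 0.2, 0.2),
                          enumerate_types(sch))
  path <- withr::local_tempfile(fileext = ".vcf")
  ev <- emit_vcf(comp, bundle$sim$ancestral, bundle$regions, sch,
                 n_individuals = 3, n_snps = 500, seed = 62, path = path)
  tab <- classify_variants(path, bundle$sim$ancestral, bundle$regions, sch, seed = 63)
  expect_equal(as.numeric(aggregate_species(tab)), as.numeric(ev$truth))
  expect_gt(ev$truth[["CpG>TpG"]], 0)
})

test_that("covariate simulation is phylogenetic in brownian mode only", {
  tree <- example_mammal_tree()
  cov0 <- simulate_covariates(tree, "brownian", sigma2 = 0, seed = 1)
  expect_true(all(cov0 == cov0[1]))
  covb <- simulate_covariates(tree, "brownian", sigma2 = 5, seed = 2)
  covi <- simulate_covariates(tree, "independent", sigma2 = 5, seed = 3)
  expect_setequal(names(covb), tree$tip.label)
  dc <- cophenetic_matrix(tree, sqrt_transform = TRUE)
  # brownian scalars correlate with the phylogeny far more often than not
  rej_b <- mean(sapply(1:20, function(i) {
    v <- simulate_covariates(tree, "brownian", sigma2 = 1, seed = 200 + i)
    mantel_test(scalar_distance_matrix(v), dc, n_perm = 99, seed = i)$p < 0.05
  }))
  rej_i <- mean(sapply(1:40, function(i) {
    v <- simulate_covariates(tree, "independent", sigma2 = 1, seed = 300 + i)
    mantel_test(scalar_distance_matrix(v), dc, n_perm = 99, seed = i)$p < 0.05
  }))
  expect_gt(rej_b, 0.7)
  expect_lt(rej_i, 0.3)
})

test_that("signature-mixture simulation matches its distribution", {
  sch <- spectrum_schema(3)
  sigs <- two_signatures(sch, seed = 70)
  # single signature, large n: proportions within 3 SE
  one <- simulate_signature_mixture(sigs, c(sigA = 1, sigB = 0), 5e5, sch, seed = 71)
  p <- unclass(sigs)[, "sigA"]
  phat <- as.numeric(one) / 5e5
  se <- sqrt(p * (1 - p) / 5e5)
  expect_true(mean(abs(phat - p) <= 3 * se + 1e-12) > 0.99)
  # zero counts give a zero table
  z <- simulate_signature_mixture(sigs, c(sigA = 0.5, sigB = 0.5), 0, sch, seed = 72)
  expect_equal(sum(z), 0)
  # mixing identical signatures equals a single signature distribution
  twin <- signature_set(cbind(a = unclass(sigs)[, 1], b = unclass(sigs)[, 1]))
  m1 <- simulate_signature_mixture(twin, c(a = 0.5, b = 0.5), 1e4, sch, seed = 73)
  m2 <- simulate_signature_mixture(twin, c(a = 1, b = 0), 1e4, sch, seed = 73)
  expect_equal(unclass(m1), unclass(m2))
})
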