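# Shared fixture builders. Everything is generated in code at test time.

# strictly positive random composition over D parts
rand_comp <- function(D, seed = NULL) {
  f <- function() {
    w <- stats::rgamma(D, 5, 1) + 1e-3
    w / sum(w)
  }
  if (is.null(seed)) f() else spectratree:::.with_seed(seed, f())
}

uniform_comp <- function(schema) {
  t <- enumerate_types(schema)
  stats::setNames(rep(1 / length(t), length(t)), t)
}

# hand-built 30-bp classification fixture with hand-enumerated expectations:
# three classifiable SNPs (one CpG transition) and four that must be dropped
# (masked, N in window, ancestral mismatch, non-PASS)
toy_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  #        1         2         3
  # 123456789012345678901234567890
  anc <- "TTACGTTAAACCGGATTTCAGCTNAGCTAA"
  genome <- c(chr1 = anc)
  mask <- file.path(dir, "mask.bed")
  writeLines("chr1\t0\t2", mask)  # masks bases 1-2
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=30>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "ind1", "ind2"), collapse = "\t"),
    "chr1\t2\t.\tT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",   # masked position
    "chr1\t4\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/0",   # ACG>ATG (CpG transition)
    "chr1\t9\t.\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/1",   # AAA>AGA, shared
    "chr1\t17\t.\tT\tG\t.\tPASS\t.\tGT\t0/0\t0/1",  # revcomp: AAA>ACA
    "chr1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t0/1\t0/0",  # ancestral A: mismatch
    "chr1\t23\t.\tT\tC\t.\tPASS\t.\tGT\t0/1\t0/0",  # window touches N at 24
    "chr1\t27\t.\tC\tA\t.\tq10\t.\tGT\t0/1\t0/0"    # non-PASS filter
  ), vcf)
  list(genome = genome, mask = mask, vcf = vcf,
       regions = accessible_regions(genome, list(mask)))
}

# small simulated genome bundle reused across pipeline tests
sim_bundle <- function(length = 20000, seed = 11, mask_fraction = 0.05, k = 3) {
  sim <- simulate_reference_and_ancestral(length = length, seed = seed,
                                          mask_fraction = mask_fraction)
  regions <- accessible_regions(sim$ancestral, list(sim$masks))
  list(sim = sim, regions = regions,
       targets = count_targets(sim$ancestral, regions, k = k))
}

# multi-species k=3 count table whose 1-mer class totals vary across species;
# within-class distribution follows each species' target fractions exactly in
# expectation (the conditional null of the nesting test) unless perturbed
make_nested_fixture <- function(n_species = 8, n_snps = 20000, seed = 1,
                                perturb = NULL, perturb_species = character(0)) {
  sch <- spectrum_schema(3)
  types <- enumerate_types(sch)
  cls <- nested_classes(types)
  spectratree:::.with_seed(seed, {
    targets <- lapply(seq_len(n_species), function(i)
      simulate_target_counts(3, 1e6, seed = NULL) + 1)
    names(targets) <- paste0("sp", seq_len(n_species))
    m <- matrix(0, n_species, length(types),
                dimnames = list(names(targets), types))
    for (i in seq_len(n_species)) {
      class_probs <- rand_comp(6)               # species-specific 1-mer spectrum
      names(class_probs) <- levels(cls)
      frac <- spectratree:::.class_fractions(types, targets[[i]])
      p <- stats::setNames(class_probs[as.character(cls)] * frac, types)
      if (!is.null(perturb) && names(targets)[i] %in% perturb_species) {
        p[names(perturb)] <- p[names(perturb)] * perturb
      }
      m[i, ] <- as.numeric(stats::rmultinom(1, n_snps, prob = p / sum(p)))
    }
    list(tab = spectrum_table(m, sch), targets = targets)
  })
}

# distinct, well-separated signature pair over a schema
two_signatures <- function(schema, seed = 21) {
  t <- enumerate_types(schema)
  spectratree:::.with_seed(seed, {
    a <- stats::rgamma(length(t), 0.5, 1) + 1e-4
    b <- stats::rgamma(length(t), 0.5, 1) + 1e-4
    signature_set(matrix(c(a / sum(a), b / sum(b)), ncol = 2,
                         dimnames = list(t, c("sigA", "sigB"))))
  })
}
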