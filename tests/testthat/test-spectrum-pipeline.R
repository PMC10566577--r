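test_that("mask subtraction does exact interval arithmetic", {
  genome <- c(chr1 = paste(rep("A", 100), collapse = ""))
  gr <- function(s, e) GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
  acc <- accessible_regions(genome, list(gr(11, 20)))  # BED [10,20)
  expect_equal(sum(GenomicRanges::width(acc)), 90)
  acc2 <- accessible_regions(genome, list(gr(1, 50), gr(41, 60)))
  expect_equal(GenomicRanges::start(acc2), 61)
  expect_equal(GenomicRanges::end(acc2), 100)
  acc3 <- accessible_regions(genome, list())
  expect_equal(sum(GenomicRanges::width(acc3)), 100)
  expect_warning(
    accessible_regions(genome, list(GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 5)))),
    "skipped")
})

test_that("target counting slides windows, skips N, and is strand symmetric", {
  g <- c(chr1 = "AAAA")
  t <- count_targets(g, k = 3)
  expect_equal(unname(t["AAA"]), 2)
  expect_equal(attr(t, "total"), 2)
  tn <- count_targets(c(chr1 = "NNNNNN"), k = 3)
  expect_equal(attr(tn, "total"), 0)
  # strand-collapse symmetry: counts invariant under revcomp of the chromosome
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  t1 <- count_targets(c(chr1 = s), k = 3)
  t2 <- count_targets(c(chr1 = reverse_complement(s)), k = 3)
  expect_equal(as.numeric(t1), as.numeric(t2))
})

test_that("variant classification reproduces a hand-enumerated toy fixture", {
  fx <- toy_fixture()
  tab <- classify_variants(fx$vcf, fx$genome, fx$regions, spectrum_schema(3), seed = 1)
  agg <- aggregate_species(tab)
  expect_equal(attr(tab, "n_sites"), 3)
  expect_equal(sum(agg), 3)
  expect_equal(unname(agg[1, "ACG>ATG"]), 1)   # the CpG transition
  expect_equal(unname(agg[1, "AAA>AGA"]), 1)
  expect_equal(unname(agg[1, "AAA>ACA"]), 1)
  # non-shared variants go to their carrier regardless of seed
  expect_equal(unname(tab["ind1", "ACG>ATG"]), 1)
  expect_equal(unname(tab["ind2", "AAA>ACA"]), 1)
  # determinism of shared-variant assignment
  tab2 <- classify_variants(fx$vcf, fx$genome, fx$regions, spectrum_schema(3), seed = 1)
  expect_equal(unclass(tab2), unclass(tab))
  # CpG-aware 1-mer schema reads a 3-mer window
  t1 <- classify_variants(fx$vcf, fx$genome, fx$regions,
                          spectrum_schema(1, "separate"), seed = 1)
  a1 <- aggregate_species(t1)
  expect_equal(unname(a1[1, c("CpG>TpG", "A>G", "A>C")]), c(1, 1, 1))
  expect_equal(sum(a1), 3)
  # excluded policy drops the CpG transition
  t0 <- classify_variants(fx$vcf, fx$genome, fx$regions,
                          spectrum_schema(1, "excluded"), seed = 1)
  expect_equal(sum(t0), 2)
  expect_error(
    classify_variants(fx$vcf, fx$genome, fx$regions, spectrum_schema(3),
                      individuals = "nope"),
    "not in VCF")
})

test_that("aggregation sums rows and commutes with projection", {
  sch <- spectrum_schema(3)
  types <- enumerate_types(sch)
  set.seed(7)
  m <- matrix(rpois(5 * 96, 4), 5, 96, dimnames = list(paste0("i", 1:5), types))
  tab <- spectrum_table(m, sch)
  agg <- aggregate_species(tab)
  expect_equal(as.numeric(agg), unname(colSums(m)))
  expect_equal(sum(agg), sum(m))
  # aggregate-then-project equals project-then-aggregate
  a1 <- project_to_smaller_k(aggregate_species(tab), 1)
  a2 <- aggregate_species(project_to_smaller_k(tab, 1))
  expect_equal(unclass(a1), unclass(a2), ignore_attr = TRUE)
  expect_error(aggregate_species(clr(add_pseudocount(tab))), "count-stage")
})

test_that("projection marginalises flanks, preserves totals, and matches direct classification", {
  bundle <- sim_bundle(length = 12000, seed = 31, k = 5)
  sch5 <- spectrum_schema(5)
  comp <- uniform_comp(sch5)
  ev <- emit_vcf(comp, bundle$sim$ancestral, bundle$regions, sch5,
                 n_individuals = 2, n_snps = 400, seed = 32,
                 path = withr::local_tempfile(fileext = ".vcf"))
  t5 <- classify_variants(ev$path, bundle$sim$ancestral, bundle$regions, sch5, seed = 33)
  t3_direct <- classify_variants(ev$path, bundle$sim$ancestral, bundle$regions,
                                 spectrum_schema(3), seed = 33)
  t3_proj <- project_to_smaller_k(t5, 3)
  expect_equal(unclass(aggregate_species(t3_proj)),
               unclass(aggregate_species(t3_direct)), ignore_attr = TRUE)
  expect_equal(rowSums(t3_proj), rowSums(t5))
  # simple example: all mass on one type projects onto its central class
  m <- matrix(0, 1, 96, dimnames = list("s", enumerate_types(spectrum_schema(3))))
  m[1, "ACG>ATG"] <- 5
  p1 <- project_to_smaller_k(spectrum_table(m, spectrum_schema(3)), 1)
  expect_equal(unname(p1[1, "C>T"]), 5)
  expect_error(project_to_smaller_k(spectrum_table(m, spectrum_schema(3)), 3), "smaller")
})

test_that("adding a mask never increases any target or SNP count", {
  bundle <- sim_bundle(length = 10000, seed = 41, mask_fraction = 0)
  sch <- spectrum_schema(3)
  ev <- emit_vcf(uniform_comp(sch), bundle$sim$ancestral, bundle$regions, sch,
                 n_individuals = 2, n_snps = 300, seed = 42,
                 path = withr::local_tempfile(fileext = ".vcf"))
  extra_mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 4000))
  regions2 <- accessible_regions(bundle$sim$ancestral, list(extra_mask))
  t_full <- count_targets(bundle$sim$ancestral, bundle$regions, k = 3)
  t_masked <- count_targets(bundle$sim$ancestral, regions2, k = 3)
  expect_true(all(as.numeric(t_masked) <= as.numeric(t_full)))
  s_full <- aggregate_species(
    classify_variants(ev$path, bundle$sim$ancestral, bundle$regions, sch, seed = 43))
  s_masked <- aggregate_species(
    classify_variants(ev$path, bundle$sim$ancestral, regions2, sch, seed = 43))
  expect_true(all(as.numeric(s_masked) <= as.numeric(s_full)))
})

test_that("spectrum and target TSV round-trips preserve content and metadata", {
  sch <- spectrum_schema(3, "excluded")
  set.seed(9)
  m <- matrix(rpois(2 * 92, 3), 2, 92,
              dimnames = list(c("a", "b"), enumerate_types(sch)))
  tab <- spectrum_table(m, sch)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(tab, f)
  back <- read_spectrum_tsv(f)
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  expect_equal(table_schema(back)$cpg_policy, "excluded")
  expect_equal(table_provenance(back), "raw")
  tg <- simulate_target_counts(3, total = 1000, seed = 2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_targets_tsv(tg, f2)
  expect_equal(read_targets_tsv(f2), tg, ignore_attr = TRUE)
})
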