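#' Read a BED file of exclusion intervals
#'
#' BED intervals are 0-based half-open; they are converted to 1-based closed
#' coordinates internally.
#'
#' @param path Path to a BED file (first three columns used).
#' @return A `GRanges` of intervals.
#' @export
read_bed <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df)) {             # empty BED: no masked intervals
    return(GenomicRanges::GRanges())
  }
  if (ncol(df) < 3L || !is.numeric(df[[2]]) || !is.numeric(df[[3]]) ||
      any(df[[3]] < df[[2]])) {
    stop("malformed BED line in ", path)
  }
  GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
}

#' Accessible regions after subtracting exclusion masks
#'
#' Subtracts the union of all mask intervals from each chromosome of the
#' reference, yielding sorted non-overlapping intervals. Mask intervals on
#' chromosomes absent from the reference are skipped with a warning.
#'
#' @param reference FASTA path, named character vector, or `DNAStringSet`.
#' @param masks List of BED paths and/or `GRanges` objects (may be empty).
#' @return A `GRanges` of accessible intervals with seqlengths set.
#' @export
accessible_regions <- function(reference, masks = list()) {
  genome <- .load_genome(reference)
  lens <- nchar(genome)
  if (is.character(masks) || methods::is(masks, "GRanges")) masks <- list(masks)
  grs <- lapply(masks, function(m) if (methods::is(m, "GRanges")) m else read_bed(m))
  mask <- if (length(grs)) GenomicRanges::reduce(do.call(c, grs)) else GenomicRanges::GRanges()
  unknown <- !as.character(GenomicRanges::seqnames(mask)) %in% names(genome)
  if (any(unknown)) {
    warning("mask intervals on chromosomes absent from the reference were skipped")
    mask <- mask[!unknown]
  }
  full <- GenomicRanges::GRanges(names(genome), IRanges::IRanges(1L, lens))
  if (length(mask) == 0) return(sort(full))
  # rebuild so stray seqlevels from skipped chromosomes don't linger
  mask <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(mask)),
                                 IRanges::IRanges(GenomicRanges::start(mask),
                                                  GenomicRanges::end(mask)))
  acc <- GenomicRanges::setdiff(full, mask, ignore.strand = TRUE)
  sort(acc)
}

# per-chromosome logical accessibility vectors over a genome
.access_logical <- function(genome, regions) {
  out <- lapply(names(genome), function(chr) {
    v <- rep(FALSE, nchar(genome[[chr]]))
    r <- regions[as.logical(GenomicRanges::seqnames(regions) == chr)]
    if (length(r)) {
      st <- GenomicRanges::start(r); en <- GenomicRanges::end(r)
      for (i in seq_along(st)) v[st[i]:en[i]] <- TRUE
    }
    v
  })
  names(out) <- names(genome)
  out
}

# central positions whose k-window is fully accessible and N-free
.ok_centers <- function(seq_chr, acc_chr, k) {
  L <- nchar(seq_chr)
  if (L < k) return(integer(0))
  base_ok <- acc_chr & (strsplit(seq_chr, "", fixed = TRUE)[[1]] %in% BASES)
  cs <- cumsum(c(0L, as.integer(base_ok)))
  h <- (k - 1L) %/% 2L
  centers <- (h + 1L):(L - h)
  win_full <- (cs[centers + h + 1L] - cs[centers - h]) == k
  centers[win_full]
}

#' All strand-collapsed ancestral k-mers
#'
#' @param k Odd context size.
#' @return Sorted character vector of the `2 * 4^(k-1)` k-mers whose central
#'   base is A or C.
#' @export
canonical_kmers <- function(k) {
  if (k == 1L) return(c("A", "C"))
  grid <- do.call(expand.grid, c(rep(list(BASES), k), KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE))
  km <- do.call(paste0, grid)
  km <- km[substr(km, (k + 1L) %/% 2L, (k + 1L) %/% 2L) %in% c("A", "C")]
  sort(km)
}

#' Count ancestral k-mer targets in the accessible genome
#'
#' Slides a k-window across every chromosome of the ancestral genome and
#' counts, for each strand-collapsed ancestral k-mer, the number of windows
#' that are fully accessible and N-free. These target counts are the
#' denominators of context-specific mutation rates and the inputs to
#' [rescale_counts()].
#'
#' @param ancestral FASTA path, named character vector, or `DNAStringSet`.
#' @param regions `GRanges` of accessible intervals (see
#'   [accessible_regions()]); `NULL` means the whole genome.
#' @param k Odd context size.
#' @return Named numeric vector over [canonical_kmers()] (zeros included),
#'   with attribute `total` = sum of all counts.
#' @export
count_targets <- function(ancestral, regions = NULL, k = 3) {
  genome <- .load_genome(ancestral)
  if (is.null(regions)) regions <- accessible_regions(genome)
  acc <- .access_logical(genome, regions)
  h <- (k - 1L) %/% 2L
  tall <- stats::setNames(numeric(length(canonical_kmers(k))), canonical_kmers(k))
  for (chr in names(genome)) {
    centers <- .ok_centers(genome[[chr]], acc[[chr]], k)
    if (!length(centers)) next
    km <- substring(genome[[chr]], centers - h, centers + h)
    ctr <- substr(km, h + 1L, h + 1L)
    flip <- ctr %in% c("G", "T")
    if (any(flip)) km[flip] <- reverse_complement(km[flip])
    tab <- table(km)
    tall[names(tab)] <- tall[names(tab)] + as.numeric(tab)
  }
  attr(tall, "total") <- sum(tall)
  tall
}

#' Classify VCF variants into a per-individual spectrum table
#'
#' Each biallelic SNP passing all filters contributes exactly one count to
#' exactly one individual's row: the derived allele (the VCF allele that
#' differs from the ancestral-genome base) is assigned uniformly at random
#' to one of its carriers. Sites are excluded when they fall outside the
#' accessible regions, their context window touches masked or N bases, the
#' ancestral base matches neither REF nor ALT, the record is not a biallelic
#' SNP, or FILTER is neither PASS nor ".". The classifier always reads at
#' least a 3-mer window so CpG status is known even for 1-mer schemas.
#'
#' @param vcf Path to a VCF file (or a `vcfR` object).
#' @param ancestral Ancestral genome (FASTA path or named character vector).
#' @param regions `GRanges` of accessible intervals.
#' @param schema A [spectrum_schema()].
#' @param individuals Sample names to use (default: all samples in the VCF).
#' @param seed Seed for the random assignment of shared variants.
#' @return A count-stage `spectrum_table` with one row per individual and
#'   attribute `n_sites` = number of classified SNPs.
#' @export
classify_variants <- function(vcf, ancestral, regions, schema,
                              individuals = NULL, seed = NULL) {
  stopifnot(inherits(schema, "spectrum_schema"))
  genome <- .load_genome(ancestral)
  v <- if (methods::is(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- matrix(as.character(fix), ncol = ncol(fix), dimnames = dimnames(fix))
  gt <- if (nrow(v@gt) > 0 && ncol(v@gt) > 1) {
    vcfR::extract.gt(v, element = "GT")
  } else {
    stop("VCF contains no genotype columns")
  }
  if (is.null(individuals)) individuals <- colnames(gt)
  missing_ind <- setdiff(individuals, colnames(gt))
  if (length(missing_ind)) {
    stop("sample(s) not in VCF: ", paste(missing_ind, collapse = ", "))
  }
  gt <- gt[, individuals, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(individuals),
                                     dimnames = list(NULL, individuals))

  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]; filt <- fix[, "FILTER"]
  missing_contig <- setdiff(unique(chrom), names(genome))
  if (length(missing_contig)) {
    stop("ancestral genome lacks contig(s): ", paste(missing_contig, collapse = ", "))
  }
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES &
    (is.na(filt) | filt %in% c("PASS", "."))

  k <- schema$k
  w <- if (schema$cpg_policy == "merged") k else max(k, 3L)
  acc <- .access_logical(genome, regions)
  ok_centers <- lapply(names(genome), function(chr)
    .ok_centers(genome[[chr]], acc[[chr]], w))
  names(ok_centers) <- names(genome)
  in_window <- logical(length(pos))
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    in_window[sel] <- pos[sel] %in% ok_centers[[chr]]
  }
  keep <- keep & in_window

  hw <- (w - 1L) %/% 2L
  ctx <- rep(NA_character_, length(pos))
  ctx[keep] <- substring(genome[chrom[keep]], pos[keep] - hw, pos[keep] + hw)
  anc_base <- substr(ctx, hw + 1L, hw + 1L)
  polarized <- keep & (anc_base == ref | anc_base == alt)
  derived <- ifelse(anc_base == ref, alt, ref)

  types <- enumerate_types(schema)
  counts <- matrix(0L, length(individuals), length(types),
                   dimnames = list(individuals, types))
  idx <- which(polarized)
  labels <- rep(NA_character_, length(idx))
  if (length(idx)) {
    cc <- collapse_strand(ctx[idx], derived[idx])
    cpg <- substr(cc$anc_kmer, hw + 1L, hw + 1L) == "C" &
      cc$derived_base == "T" &
      substr(cc$anc_kmer, hw + 2L, hw + 2L) == "G"
    anc_k <- substr(cc$anc_kmer, hw - (k - 1L) %/% 2L + 1L, hw + (k - 1L) %/% 2L + 1L)
    labels <- type_label(anc_k, cc$derived_base)
    if (schema$cpg_policy == "excluded") {
      labels[cpg] <- NA_character_
    } else if (schema$cpg_policy == "separate" && k == 1L) {
      labels[cpg] <- "CpG>TpG"
    }
    if (schema$folded) {
      plain <- !is.na(labels) & labels != "CpG>TpG"
      labels[plain] <- fold_type(labels[plain])
    }
  }

  n_classified <- 0L
  .with_seed(seed, {
    for (j in seq_along(idx)) {
      if (is.na(labels[j])) next
      i <- idx[j]
      code <- if (derived[i] == ref[i]) "0" else "1"
      g <- gt[i, ]
      carrier <- !is.na(g) & grepl(code, g, fixed = TRUE)
      if (!any(carrier)) next
      who <- which(carrier)
      pick <- if (length(who) == 1L) who else who[sample.int(length(who), 1L)]
      counts[pick, labels[j]] <- counts[pick, labels[j]] + 1L
      n_classified <- n_classified + 1L
    }
  })
  out <- spectrum_table(counts, schema, provenance = "raw")
  attr(out, "n_sites") <- n_classified
  out
}
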