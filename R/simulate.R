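#' A fixed 13-leaf mammal-like phylogeny
#'
#' The default study-shaped fixture tree: 13 leaves in 4 clades (great
#' apes, murid rodents on a long stem, carnivores, cetaceans), branch
#' lengths on an expected-substitutions-per-site scale. Used throughout the
#' package's simulations so clade-level clustering behaviour is
#' reproducible.
#'
#' @return An `ape::phylo` tree.
#' @export
example_mammal_tree <- function() {
  nwk <- paste0(
    "(((((Human:0.006,(Chimpanzee:0.003,Bonobo:0.003):0.004):0.002,",
    "Gorilla:0.008):0.007,(Orangutan_Bornean:0.002,Orangutan_Sumatran:0.002):0.013):0.055,",
    "(Mouse_musculus:0.012,Mouse_spretus:0.014):0.175):0.012,",
    "(((Polar_bear:0.004,Brown_bear:0.004):0.025,Wolf:0.032):0.022,",
    "(Fin_whale:0.018,Vaquita:0.02):0.035):0.03);")
  ape::read.tree(text = nwk)
}

#' Simulate an ancestral/reference genome pair with masks
#'
#' Draws an ancestral genome i.i.d. from the base weights, derives the
#' reference by substituting a configurable fraction of bases uniformly at
#' random, and lays down non-overlapping exclusion-mask intervals covering
#' approximately the requested fraction of each chromosome.
#'
#' @param length Chromosome length in bp (recycled over `n_chrom`).
#' @param n_chrom Number of chromosomes.
#' @param base_weights Sampling weights for A, C, G, T.
#' @param substitution_fraction Fraction of reference bases differing from
#'   the ancestral genome.
#' @param mask_fraction Fraction of each chromosome covered by masks.
#' @param mask_interval_bp Approximate mask interval width.
#' @param seed RNG seed.
#' @param out_dir Optional directory; writes `ancestral.fa`, `reference.fa`
#'   and `mask.bed` when given.
#' @return List with `ancestral`, `reference` (named character vectors),
#'   `masks` (`GRanges`), and `paths` (when written).
#' @export
simulate_reference_and_ancestral <- function(length = 100000, n_chrom = 1,
                                             base_weights = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                                             substitution_fraction = 0.01,
                                             mask_fraction = 0.1,
                                             mask_interval_bp = 500,
                                             seed = NULL, out_dir = NULL) {
  if (length(base_weights) != 4L || any(base_weights < 0) || sum(base_weights) <= 0) {
    stop("base_weights must be 4 non-negative weights with positive sum")
  }
  lens <- rep_len(length, n_chrom)
  chroms <- paste0("chr", seq_len(n_chrom))
  out <- .with_seed(seed, {
    anc <- vapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE, prob = base_weights), collapse = ""),
      character(1))
    names(anc) <- chroms
    ref <- anc
    for (chr in chroms) {
      L <- nchar(ref[[chr]])
      nsub <- round(substitution_fraction * L)
      if (nsub > 0) {
        pos <- sample.int(L, nsub)
        cur <- substring(ref[[chr]], pos, pos)
        new <- vapply(cur, function(b) sample(setdiff(BASES, b), 1), character(1))
        s <- strsplit(ref[[chr]], "", fixed = TRUE)[[1]]
        s[pos] <- new
        ref[chr] <- paste(s, collapse = "")
      }
    }
    masks <- GenomicRanges::GRanges()
    if (mask_fraction > 0) {
      grl <- lapply(chroms, function(chr) {
        L <- nchar(anc[[chr]])
        n_int <- max(1L, round(mask_fraction * L / mask_interval_bp))
        starts <- sort(sample.int(max(1L, L - mask_interval_bp), n_int))
        GenomicRanges::reduce(GenomicRanges::GRanges(
          chr, IRanges::IRanges(starts, width = mask_interval_bp)))
      })
      masks <- do.call(c, grl)
    }
    list(ancestral = anc, reference = ref, masks = masks)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(ancestral = file.path(out_dir, "ancestral.fa"),
                  reference = file.path(out_dir, "reference.fa"),
                  mask = file.path(out_dir, "mask.bed"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$ancestral), paths$ancestral)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$reference), paths$reference)
    write_bed(out$masks, paths$mask)
    out$paths <- paths
  }
  out
}

#' Write a GRanges as a BED file (0-based half-open)
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Evolve mutation-rate compositions along a tree by CLR Brownian motion
#'
#' Starting from a root composition over the schema's mutation types, each
#' branch adds independent Gaussian increments (variance `sigma2` times the
#' branch length per coordinate) in CLR space, projected onto the zero-sum
#' subspace; leaf compositions are recovered by the inverse CLR (softmax).
#' Expected squared Aitchison distance between two leaves is proportional
#' to their cophenetic distance.
#'
#' @param tree Phylogeny (`phylo`, Newick string, or path).
#' @param root_composition Strictly positive named vector over mutation
#'   types (normalised internally).
#' @param sigma2 Brownian rate per unit branch length (>= 0).
#' @param seed RNG seed.
#' @return Matrix of leaf compositions (rows = tip labels, rows sum to 1).
#' @export
evolve_spectra_on_tree <- function(tree, root_composition, sigma2 = 0.1, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  tree <- .as_tree(tree)
  p0 <- root_composition / sum(root_composition)
  if (any(p0 <= 0)) stop("root composition must be strictly positive")
  D <- length(p0)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  vals <- matrix(NA_real_, nnode, D)
  root <- ntip + 1L
  vals[root, ] <- clr(as.numeric(p0))
  tr <- stats::reorder(tree)               # cladewise: parent precedes child
  .with_seed(seed, {
    for (e in seq_len(nrow(tr$edge))) {
      inc <- stats::rnorm(D, 0, sqrt(sigma2 * tr$edge.length[e]))
      inc <- inc - mean(inc)               # stay in the zero-sum subspace
      vals[tr$edge[e, 2], ] <- vals[tr$edge[e, 1], ] + inc
    }
  })
  leaf_clr <- vals[seq_len(ntip), , drop = FALSE]
  comp <- t(apply(leaf_clr, 1, function(v) { e <- exp(v); e / sum(e) }))
  dimnames(comp) <- list(tree$tip.label, names(root_composition))
  comp
}

#' Simulate per-species scalar covariates on a tree
#'
#' `"brownian"` mode evolves a scalar by Brownian motion along the tree
#' (phylogenetically correlated values); `"independent"` mode draws
#' exchangeable i.i.d. normals.
#'
#' @param tree Phylogeny.
#' @param mode `"brownian"` or `"independent"`.
#' @param sigma2 Brownian rate, or the i.i.d. variance.
#' @param root Root value (brownian mode).
#' @param seed RNG seed.
#' @return Named numeric vector over tip labels.
#' @export
simulate_covariates <- function(tree, mode = c("brownian", "independent"),
                                sigma2 = 1, root = 0, seed = NULL) {
  mode <- match.arg(mode)
  tree <- .as_tree(tree)
  ntip <- length(tree$tip.label)
  .with_seed(seed, {
    if (mode == "independent") {
      return(stats::setNames(stats::rnorm(ntip, 0, sqrt(sigma2)), tree$tip.label))
    }
    nnode <- ntip + tree$Nnode
    vals <- rep(NA_real_, nnode)
    vals[ntip + 1L] <- root
    tr <- stats::reorder(tree)
    for (e in seq_len(nrow(tr$edge))) {
      vals[tr$edge[e, 2]] <- vals[tr$edge[e, 1]] +
        stats::rnorm(1, 0, sqrt(sigma2 * tr$edge.length[e]))
    }
    stats::setNames(vals[seq_len(ntip)], tree$tip.label)
  })
}

#' Simulate counts from a signature mixture
#'
#' @param sigs A `signature_set`.
#' @param exposures Matrix (genomes x signatures) of simplex rows, or a
#'   single exposure vector.
#' @param n_counts Total counts per genome (recycled).
#' @param schema Schema of the output table (types must match `sigs`).
#' @param seed RNG seed.
#' @return A count-stage `spectrum_table`.
#' @export
simulate_signature_mixture <- function(sigs, exposures, n_counts, schema, seed = NULL) {
  stopifnot(inherits(sigs, "signature_set"))
  if (is.null(dim(exposures))) exposures <- matrix(exposures, 1,
                                                   dimnames = list("sample1", names(exposures)))
  if (ncol(exposures) != ncol(sigs)) stop("exposure/signature mismatch")
  types <- enumerate_types(schema)
  S <- .align_signatures(sigs, types)
  P <- exposures %*% t(S)
  n_counts <- rep_len(n_counts, nrow(P))
  out <- .with_seed(seed, {
    m <- matrix(0, nrow(P), length(types), dimnames = list(rownames(exposures), types))
    for (i in seq_len(nrow(P))) {
      if (n_counts[i] > 0) m[i, ] <- as.numeric(stats::rmultinom(1, n_counts[i], prob = P[i, ]))
    }
    m
  })
  spectrum_table(out, schema, provenance = "raw")
}

#' Simulate ancestral k-mer target counts
#'
#' Draws a random genome-composition profile (Gamma weights over the
#' canonical k-mers, i.e. a Dirichlet direction) and allocates `total`
#' targets multinomially. A cheap stand-in for counting targets on a full
#' simulated genome when only the composition matters.
#'
#' @param k Odd context size.
#' @param total Total target count.
#' @param concentration Gamma shape; larger = more even composition.
#' @param seed RNG seed.
#' @return Named numeric vector over [canonical_kmers()].
#' @export
simulate_target_counts <- function(k, total = 1e6, concentration = 20, seed = NULL) {
  km <- canonical_kmers(k)
  .with_seed(seed, {
    w <- stats::rgamma(length(km), concentration, 1)
    stats::setNames(as.numeric(stats::rmultinom(1, total, prob = w)), km)
  })
}

#' Emit a synthetic VCF for one species with exact truth bookkeeping
#'
#' Samples `n_snps` mutation types from the species' type composition
#' (optionally multiplying planted motifs' rates by a fold factor), places
#' each mutation at a genomic position whose ancestral context matches the
#' type's ancestral k-mer (fully accessible, N-free window), assigns
#' derived-allele genotypes from a neutral-shaped frequency spectrum with
#' at least one derived carrier per site, and writes a minimal VCFv4.2
#' file. REF is the ancestral base and ALT the derived base on the forward
#' strand of the genome.
#'
#' @param composition Named probability vector over a schema's type labels.
#' @param ancestral Ancestral genome (named character vector or FASTA path).
#' @param regions Accessible `GRanges` (see [accessible_regions()]).
#' @param schema The [spectrum_schema()] of the composition.
#' @param n_individuals Number of diploid samples.
#' @param n_snps Number of SNPs to place.
#' @param planted_motifs Optional named numeric vector: type label ->
#'   fold multiplier applied to that type's rate.
#' @param species Sample-name prefix and truth label.
#' @param seed RNG seed.
#' @param path Optional output VCF path (plain text).
#' @return List with `vcf_lines` (character), `truth` (named count vector
#'   over the schema's types), `positions` (data.frame), and `path`.
#' @export
emit_vcf <- function(composition, ancestral, regions, schema,
                     n_individuals = 5, n_snps = 1000,
                     planted_motifs = NULL, species = "sp",
                     seed = NULL, path = NULL) {
  stopifnot(inherits(schema, "spectrum_schema"))
  genome <- .load_genome(ancestral)
  types <- enumerate_types(schema)
  if (!all(names(composition) %in% types)) stop("composition names must be schema types")
  pr <- stats::setNames(numeric(length(types)), types)
  pr[names(composition)] <- composition
  if (!is.null(planted_motifs)) {
    if (!all(names(planted_motifs) %in% types)) stop("planted motif not in schema")
    pr[names(planted_motifs)] <- pr[names(planted_motifs)] * planted_motifs
  }
  pr <- pr / sum(pr)
  k <- schema$k
  w <- if (schema$cpg_policy == "merged") k else max(k, 3L)
  hw <- (w - 1L) %/% 2L
  acc <- .access_logical(genome, regions)

  # catalogue candidate positions by canonical ancestral w-mer
  cand <- list()
  for (chr in names(genome)) {
    centers <- .ok_centers(genome[[chr]], acc[[chr]], w)
    if (!length(centers)) next
    km <- substring(genome[[chr]], centers - hw, centers + hw)
    ctr <- substr(km, hw + 1L, hw + 1L)
    flip <- ctr %in% c("G", "T")
    km[flip] <- reverse_complement(km[flip])
    df <- data.frame(chrom = chr, pos = centers, flipped = flip,
                     kmer = km, stringsAsFactors = FALSE)
    cand[[chr]] <- df
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand)) stop("no accessible candidate positions")

  p_t <- parse_types(types)
  trim_lo <- hw - (k - 1L) %/% 2L
  cand_key <- substr(cand$kmer, trim_lo + 1L, trim_lo + k)
  type_key <- p_t$anc
  if (k == 1L && schema$cpg_policy != "merged") {
    # the context window is a 3-mer here: split the central-C pool by CpG
    # status so CpG transitions land in CpG contexts and every other
    # central-C type in non-CpG contexts, keeping truth bookkeeping exact
    isC <- substr(cand$kmer, hw + 1L, hw + 1L) == "C"
    cpgC <- isC & substr(cand$kmer, hw + 2L, hw + 2L) == "G"
    cand_key[cpgC] <- "C.cpg"
    cand_key[isC & !cpgC] <- "C.non"
    type_key <- ifelse(types == "CpG>TpG", "C.cpg",
                       ifelse(p_t$central == "C", "C.non", p_t$anc))
  }

  out <- .with_seed(seed, {
    draw_ok <- FALSE
    avail <- table(cand_key)
    for (try in 1:10) {
      counts <- as.numeric(stats::rmultinom(1, n_snps, prob = pr))
      names(counts) <- types
      need_by_key <- tapply(counts, type_key, sum)
      have <- avail[names(need_by_key)]
      have[is.na(have)] <- 0
      if (all(need_by_key <= have)) { draw_ok <- TRUE; break }
    }
    if (!draw_ok) {
      warning("insufficient genomic targets after bounded retries; ",
              "capping counts to the available pools")
    }
    # assign positions: for each pool key, shuffle its candidate pool and
    # hand slices to the types that need it
    rows <- integer(0); row_type <- character(0)
    pool_by_anc <- split(seq_len(nrow(cand)), cand_key)
    for (anck in unique(type_key)) {
      type_idx <- which(type_key == anck)
      need <- counts[type_idx]
      tot <- sum(need)
      if (tot == 0) next
      pool <- pool_by_anc[[anck]]
      if (is.null(pool) || length(pool) < tot) {
        cap <- if (is.null(pool)) 0L else length(pool)
        # cap proportionally, largest remainders first
        scaled <- floor(need * cap / tot)
        rem <- cap - sum(scaled)
        if (rem > 0) {
          ord <- order(need * cap / tot - scaled, decreasing = TRUE)
          scaled[ord[seq_len(rem)]] <- scaled[ord[seq_len(rem)]] + 1L
        }
        need <- scaled
        tot <- sum(need)
        if (tot == 0) next
      }
      picked <- sample(pool, tot)
      rows <- c(rows, picked)
      row_type <- c(row_type, rep(types[type_idx], times = need))
    }
    ord <- order(cand$chrom[rows], cand$pos[rows])
    rows <- rows[ord]; row_type <- row_type[ord]

    n_sites <- length(rows)
    der_base <- parse_types(row_type)$der
    flipped <- cand$flipped[rows]
    der_genome <- ifelse(flipped, unname(.comp[der_base]), der_base)
    anc_genome <- substring(genome[cand$chrom[rows]], cand$pos[rows], cand$pos[rows])

    # derived allele counts from a 1/i (neutral) frequency spectrum
    nchrom <- 2L * n_individuals
    freq_probs <- 1 / seq_len(max(nchrom - 1L, 1L))
    dac <- sample(seq_len(max(nchrom - 1L, 1L)), n_sites, replace = TRUE,
                  prob = freq_probs)
    gt <- matrix("0", n_sites, n_individuals)
    for (i in seq_len(n_sites)) {
      carriers_chrom <- sample.int(nchrom, dac[i])
      a1 <- as.integer(seq_len(n_individuals) * 2L - 1L) %in% carriers_chrom
      a2 <- as.integer(seq_len(n_individuals) * 2L) %in% carriers_chrom
      gt[i, ] <- paste0(as.integer(a1), "/", as.integer(a2))
    }
    list(rows = rows, row_type = row_type, der_genome = der_genome,
         anc_genome = anc_genome, gt = gt)
  })

  samples <- paste0(species, "_", seq_len(n_individuals))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- if (length(out$rows)) {
    paste(cand$chrom[out$rows], cand$pos[out$rows], ".",
          out$anc_genome, out$der_genome, ".", "PASS", ".", "GT",
          apply(out$gt, 1, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  lines <- c(hdr, body)
  truth <- stats::setNames(numeric(length(types)), types)
  if (length(out$row_type)) {
    tb <- table(factor(out$row_type, levels = types))
    truth[] <- as.numeric(tb)
  }
  if (!is.null(path)) writeLines(lines, path)
  list(vcf_lines = lines, truth = truth,
       positions = data.frame(chrom = cand$chrom[out$rows],
                              pos = cand$pos[out$rows],
                              type = out$row_type,
                              stringsAsFactors = FALSE),
       path = path)
}
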