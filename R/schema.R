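#' Spectrum schema
#'
#' A schema fixes the mutation-type universe used by every downstream table:
#' the context size `k` (an odd number of bases centred on the mutating
#' site), how CpG transitions are handled, and whether the spectrum is
#' "folded" to remove dependence on ancestral-allele polarization.
#'
#' With `cpg_policy = "merged"` the unfolded universe contains
#' `6 * 4^(k-1)` types (6, 96, 1536 and 24576 for k = 1, 3, 5, 7).
#' `"separate"` splits CpG transitions into their own class; at `k = 1` this
#' yields the 7-class spectrum with an explicit `"CpG>TpG"` label, while for
#' `k >= 3` CpG context is already encoded in the type so the enumeration is
#' unchanged. `"excluded"` drops CpG-transition types (and, at `k = 1`, drops
#' CpG transitions from the C>T class at classification time).
#'
#' @param k Odd context size, one of 1, 3, 5, 7.
#' @param cpg_policy One of `"merged"`, `"separate"`, `"excluded"`.
#' @param folded Logical; fold each type with its ancestral/derived swap.
#' @return An object of class `spectrum_schema`.
#' @examples
#' length(enumerate_types(spectrum_schema(3)))  # 96
#' @export
spectrum_schema <- function(k = 3, cpg_policy = c("merged", "separate", "excluded"),
                            folded = FALSE) {
  cpg_policy <- match.arg(cpg_policy)
  if (!k %in% c(1L, 3L, 5L, 7L)) {
    stop("unsupported context size k = ", k, " (must be 1, 3, 5 or 7)")
  }
  if (folded && k == 1L && cpg_policy == "separate") {
    stop("folding is not defined for the 1-mer + CpG schema")
  }
  structure(list(k = as.integer(k), cpg_policy = cpg_policy,
                 folded = isTRUE(folded)),
            class = "spectrum_schema")
}

#' @export
print.spectrum_schema <- function(x, ...) {
  cat(sprintf("<spectrum_schema> k=%d, cpg=%s, %s (%d types)\n",
              x$k, x$cpg_policy, if (x$folded) "folded" else "unfolded",
              length(enumerate_types(x))))
  invisible(x)
}

BASES <- c("A", "C", "G", "T")
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; accepts A, C, G, T and N.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACG")  # "CGT"
#' @export
reverse_complement <- function(x) {
  if (!is.character(x)) stop("x must be a character vector")
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-IUPAC characters in: ", paste(utils::head(x[bad], 3), collapse = ", "))
  }
  comp <- chartr("ACGTN", "TGCAN", x)
  # reverse each string; strsplit path is fast enough at the scales used here
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.central_index <- function(kmer) (nchar(kmer) + 1L) %/% 2L

.central_base <- function(kmer) substr(kmer, .central_index(kmer), .central_index(kmer))

#' Collapse a mutation onto the canonical strand
#'
#' Mutation types are recorded so that the central ancestral base is A or C;
#' a mutation observed with central G or T is replaced by the reverse
#' complement of its ancestral k-mer together with the complemented derived
#' base. Idempotent.
#'
#' @param anc_kmer Odd-length ancestral k-mer (character vector).
#' @param derived_base Derived central base (character vector, recycled).
#' @return A list with components `anc_kmer` and `derived_base`, both
#'   canonical.
#' @examples
#' collapse_strand("GTT", "A")  # canonical form AAC with derived T, i.e. AAC>ATC
#' @export
collapse_strand <- function(anc_kmer, derived_base) {
  k <- nchar(anc_kmer)
  if (any(k %% 2L == 0L)) stop("ancestral k-mer must have odd length")
  n <- max(length(anc_kmer), length(derived_base))
  anc_kmer <- rep_len(anc_kmer, n)
  derived_base <- rep_len(derived_base, n)
  cb <- .central_base(anc_kmer)
  if (any(cb == "N" | derived_base == "N")) stop("central or derived base is N")
  if (any(cb == derived_base)) stop("derived base must differ from the central base")
  flip <- cb %in% c("G", "T")
  if (any(flip)) {
    anc_kmer[flip] <- reverse_complement(anc_kmer[flip])
    derived_base[flip] <- unname(.comp[derived_base[flip]])
  }
  list(anc_kmer = anc_kmer, derived_base = derived_base)
}

#' Format a mutation type label
#'
#' Labels are `"<ancestral k-mer>><derived k-mer>"`, e.g. `"TAC>TGC"`; the
#' derived k-mer differs from the ancestral only at the central position.
#'
#' @param anc_kmer Canonical ancestral k-mer(s).
#' @param derived_base Derived central base(s).
#' @return Character vector of labels.
#' @export
type_label <- function(anc_kmer, derived_base) {
  i <- .central_index(anc_kmer)
  der <- anc_kmer
  substr(der, i, i) <- derived_base
  paste0(anc_kmer, ">", der)
}

#' Split mutation type labels into ancestral k-mer and derived base
#'
#' @param labels Character vector of labels such as `"ACG>ATG"` or `"C>T"`.
#' @return A data.frame with columns `anc`, `der` (derived central base),
#'   `central` (ancestral central base) and `k`.
#' @export
parse_types <- function(labels) {
  special <- labels == "CpG>TpG"
  out <- data.frame(anc = NA_character_, der = NA_character_,
                    central = NA_character_, k = NA_integer_,
                    row.names = NULL, stringsAsFactors = FALSE)[rep(1, length(labels)), , drop = FALSE]
  rownames(out) <- NULL
  parts <- strsplit(labels[!special], ">", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed type label")
  anc <- vapply(parts, `[`, character(1), 1L)
  der <- vapply(parts, `[`, character(1), 2L)
  if (any(nchar(anc) != nchar(der))) stop("malformed type label")
  i <- .central_index(anc)
  out$anc[!special] <- anc
  out$der[!special] <- substr(der, i, i)
  out$central[!special] <- substr(anc, i, i)
  out$k[!special] <- nchar(anc)
  out$anc[special] <- "C"
  out$der[special] <- "T"
  out$central[special] <- "C"
  out$k[special] <- 1L
  out
}

.central_subs <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")

.enumerate_merged <- function(k) {
  if (k == 1L) {
    return(.central_subs)
  }
  h <- (k - 1L) %/% 2L
  flank <- do.call(expand.grid,
                   c(rep(list(BASES), k - 1L), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE))
  # columns 1..h are the 5' flank, h+1..2h the 3' flank; build contexts in
  # lexicographic order of the full ancestral k-mer
  labs <- character(0)
  for (cs in .central_subs) {
    ctr <- substr(cs, 1, 1)
    der <- substr(cs, 3, 3)
    left <- do.call(paste0, flank[, seq_len(h), drop = FALSE])
    right <- do.call(paste0, flank[, h + seq_len(h), drop = FALSE])
    anc <- paste0(left, ctr, right)
    anc <- sort(anc)
    labs <- c(labs, type_label(anc, der))
  }
  labs
}

.is_cpg_label <- function(labels) {
  p <- parse_types(labels)
  k <- p$k
  out <- logical(length(labels))
  ge3 <- !is.na(k) & k >= 3L
  if (any(ge3)) {
    i <- .central_index(p$anc[ge3])
    three_prime <- substr(p$anc[ge3], i + 1L, i + 1L)
    out[ge3] <- p$central[ge3] == "C" & p$der[ge3] == "T" & three_prime == "G"
  }
  out[labels == "CpG>TpG"] <- TRUE
  out
}

#' Enumerate the mutation-type universe of a schema
#'
#' The ordering is total and deterministic: types are sorted first by
#' central substitution (A>C, A>G, A>T, C>A, C>G, C>T) and then
#' lexicographically by ancestral k-mer context; at `k = 3` this matches the
#' COSMIC 96-type convention so external signature tables align column for
#' column. The `k = 1` "separate" schema appends `"CpG>TpG"` after `"C>T"`.
#'
#' @param schema A [spectrum_schema()].
#' @return Character vector of type labels.
#' @examples
#' length(enumerate_types(spectrum_schema(5)))  # 1536
#' @export
enumerate_types <- function(schema) {
  stopifnot(inherits(schema, "spectrum_schema"))
  labs <- .enumerate_merged(schema$k)
  if (schema$cpg_policy == "excluded" && schema$k >= 3L) {
    labs <- labs[!.is_cpg_label(labs)]
  }
  if (schema$cpg_policy == "separate" && schema$k == 1L) {
    labs <- append(labs, "CpG>TpG", after = match("C>T", labs))
  }
  if (schema$folded) {
    labs <- unique(fold_type(labs))
  }
  labs
}

#' Is a mutation type a CpG transition?
#'
#' True iff the central substitution is C>T and the base immediately 3' of
#' the central C is G. For `k = 1` only the explicit `"CpG>TpG"` label
#' qualifies; bare `"C>T"` carries no context and returns `FALSE`.
#'
#' @param labels Character vector of type labels.
#' @return Logical vector.
#' @examples
#' is_cpg_transition(c("ACG>ATG", "ACC>ATC", "AAG>AGG"))
#' @export
is_cpg_transition <- function(labels) .is_cpg_label(labels)

#' Fold a mutation type with its ancestral/derived swap
#'
#' Folding merges each type X>Y with the strand-collapsed form of Y>X (the
#' same context with ancestral and derived central bases exchanged), which
#' removes any dependence on ancestral-allele polarization. Each fold pair is
#' labelled by whichever member comes first in the canonical type ordering,
#' so the map is deterministic and idempotent. At `k = 1` the six types
#' collapse to four folded classes: {A>C, C>A}, {A>G, C>T}, {A>T}, {C>G}.
#'
#' @param labels Character vector of canonical type labels.
#' @return Character vector of folded class labels.
#' @export
fold_type <- function(labels) {
  if (any(labels == "CpG>TpG")) stop("folding is not defined for the CpG>TpG class")
  p <- parse_types(labels)
  k <- unique(p$k)
  if (length(k) != 1L) stop("mixed k in labels")
  # swap ancestral and derived central bases, re-canonicalise
  i <- .central_index(p$anc)
  swapped <- p$anc
  substr(swapped, i, i) <- p$der
  cc <- collapse_strand(swapped, p$central)
  partner <- type_label(cc$anc_kmer, cc$derived_base)
  ord <- .enumerate_merged(k)
  idx_self <- match(labels, ord)
  idx_part <- match(partner, ord)
  if (anyNA(idx_self) || anyNA(idx_part)) stop("labels must be canonical types")
  ord[pmin(idx_self, idx_part)]
}

#' Central 1-mer substitution of a type
#'
#' @param labels Character vector of type labels (any k).
#' @return Character vector of 1-mer labels such as `"A>G"`.
#' @examples
#' central_1mer("AAG>AGG")  # "A>G"
#' @export
central_1mer <- function(labels) {
  p <- parse_types(labels)
  out <- paste0(p$central, ">", p$der)
  out[labels == "CpG>TpG"] <- "C>T"
  out
}

#' Project a k-mer type label onto a smaller context size
#'
#' Trims `(k - k_target)/2` bases from each side of the ancestral k-mer.
#'
#' @param labels Character vector of type labels.
#' @param k_target Target (smaller) odd context size.
#' @return Character vector of `k_target` labels.
#' @export
trim_type <- function(labels, k_target) {
  p <- parse_types(labels)
  if (any(p$k < k_target)) stop("k_target exceeds the labels' context size")
  drop <- (p$k - k_target) %/% 2L
  anc <- substr(p$anc, drop + 1L, p$k - drop)
  type_label(anc, p$der)
}
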