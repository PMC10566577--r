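#' Spectrum tables
#'
#' A spectrum table is a numeric matrix with one row per genome (individual
#' or species) and one column per mutation type of a fixed schema, plus a
#' provenance trail recording which pipeline stages have been applied
#' (`"raw"`, `"rescaled"`, `"downsampled"`, `"pseudocount"`, `"proportions"`,
#' `"clr"`, `"ilr"`). Downstream functions check provenance so that, e.g.,
#' Aitchison distances are only computed from CLR rows.
#'
#' @param counts Numeric matrix; column names must equal
#'   `enumerate_types(schema)` (columns are reordered if needed).
#' @param schema A [spectrum_schema()].
#' @param provenance Character vector of applied stages.
#' @return An object of class `spectrum_table` (a matrix with attributes).
#' @export
spectrum_table <- function(counts, schema, provenance = "raw") {
  stopifnot(inherits(schema, "spectrum_schema"))
  types <- enumerate_types(schema)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    if (ncol(counts) != length(types)) stop("column count does not match schema")
    colnames(counts) <- types
  }
  if (!setequal(colnames(counts), types)) {
    stop("column names do not match the schema's type universe")
  }
  counts <- counts[, types, drop = FALSE]
  if (is.null(rownames(counts))) rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  structure(counts, schema = schema, provenance = provenance,
            class = c("spectrum_table", "matrix", "array"))
}

#' @export
print.spectrum_table <- function(x, ...) {
  s <- attr(x, "schema")
  cat(sprintf("<spectrum_table> %d x %d (k=%d, cpg=%s%s); provenance: %s\n",
              nrow(x), ncol(x), s$k, s$cpg_policy,
              if (s$folded) ", folded" else "",
              paste(attr(x, "provenance"), collapse = " -> ")))
  invisible(x)
}

#' Schema of a spectrum table
#' @param x A `spectrum_table`.
#' @return The table's [spectrum_schema()].
#' @export
table_schema <- function(x) attr(x, "schema")

#' Provenance trail of a spectrum table
#' @param x A `spectrum_table`.
#' @return Character vector of applied stages.
#' @export
table_provenance <- function(x) attr(x, "provenance")

.push_provenance <- function(x, stage, counts = unclass(x)) {
  spectrum_table(counts, attr(x, "schema"),
                 provenance = c(attr(x, "provenance"), stage))
}

.assert_counts <- function(x, what) {
  prov <- attr(x, "provenance")
  if (any(prov %in% c("proportions", "clr", "ilr"))) {
    stop(what, " requires a count-stage table, got provenance: ",
         paste(prov, collapse = " -> "))
  }
}

#' Aggregate per-individual spectra into one species row
#'
#' Column-wise sum; equivalent to classifying all of the species' variants
#' into a single spectrum because each variant contributes to exactly one
#' individual.
#'
#' @param x A count-stage `spectrum_table` (rows = individuals).
#' @param label Row label for the aggregate.
#' @return A one-row `spectrum_table`.
#' @export
aggregate_species <- function(x, label = "species") {
  stopifnot(inherits(x, "spectrum_table"))
  .assert_counts(x, "aggregate_species()")
  out <- matrix(colSums(x), nrow = 1, dimnames = list(label, colnames(x)))
  spectrum_table(out, attr(x, "schema"), provenance = attr(x, "provenance"))
}

#' Project a spectrum onto a smaller context size
#'
#' Sums counts over the marginalised flanking positions; row totals are
#' preserved. The target schema keeps the source's CpG policy (at
#' `k_target = 1` with policy `"separate"`, CpG-transition types map to the
#' `"CpG>TpG"` class; with `"excluded"` they are dropped, which is only
#' lossless if the source schema already excluded them).
#'
#' @param x A count-stage `spectrum_table`.
#' @param k_target Target odd context size, smaller than the source k.
#' @return A `spectrum_table` over the `k_target` schema.
#' @export
project_to_smaller_k <- function(x, k_target) {
  stopifnot(inherits(x, "spectrum_table"))
  s <- attr(x, "schema")
  if (s$folded) stop("projection of folded spectra is not supported")
  if (k_target >= s$k) stop("k_target must be smaller than the source k")
  .assert_counts(x, "project_to_smaller_k()")
  target_schema <- spectrum_schema(k_target, s$cpg_policy)
  tgt <- trim_type(colnames(x), k_target)
  if (k_target == 1L && s$cpg_policy == "separate") {
    tgt[is_cpg_transition(colnames(x))] <- "CpG>TpG"
  }
  types <- enumerate_types(target_schema)
  out <- matrix(0, nrow(x), length(types), dimnames = list(rownames(x), types))
  keep <- tgt %in% types
  grp <- factor(tgt[keep], levels = types)
  for (i in seq_len(nrow(x))) {
    out[i, ] <- as.numeric(rowsum(as.numeric(x[i, keep]), grp)[types, 1])
  }
  spectrum_table(out, target_schema, provenance = attr(x, "provenance"))
}

#' Write a spectrum table to TSV
#'
#' The file begins with a single `#`-prefixed JSON header recording the
#' schema and provenance, followed by a header row and one row per sample.
#'
#' @param x A `spectrum_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(x, path) {
  s <- attr(x, "schema")
  hdr <- jsonlite::toJSON(list(k = s$k, cpg_policy = s$cpg_policy,
                               folded = s$folded,
                               provenance = attr(x, "provenance")),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  df <- data.frame(sample = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum table written by [write_spectrum_tsv()]
#'
#' @param path Input path.
#' @return A `spectrum_table`.
#' @export
read_spectrum_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) stop("missing JSON schema header line")
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  spectrum_table(m, spectrum_schema(meta$k, meta$cpg_policy, meta$folded),
                 provenance = meta$provenance)
}

#' Write target counts to TSV
#' @param targets Named numeric vector of ancestral k-mer counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_tsv <- function(targets, path) {
  utils::write.table(data.frame(kmer = names(targets), count = as.numeric(targets)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read target counts written by [write_targets_tsv()]
#' @param path Input path.
#' @return Named numeric vector.
#' @export
read_targets_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(df$count, df$kmer)
}
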