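# internal helpers shared across modules

# evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# load a genome as a named character vector of upper-case sequences
.load_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(x) && !is.null(names(x))) return(toupper(x))
  if (methods::is(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  stop("genome must be a FASTA path or a named character vector")
}
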