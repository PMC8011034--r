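#' @importFrom methods new validObject is slot
#' @importFrom stats t.test ks.test rbinom runif setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a base seed and a stream index
#'
#' Deterministic arithmetic derivation kept inside 32-bit integer range so
#' that results are reproducible across platforms.
#'
#' @param base_seed integer base seed.
#' @param index non-negative integer stream index.
#' @return An integer seed.
#' @export
deriveSeed <- function(base_seed, index) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  as.integer((as.double(base_seed) + as.double(index)) %% 2147483629)
}

## run expr with a local, restored RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## required-column check for the internal tabular model
checkColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

## canonical empty tables of the internal model
emptyGeneTable <- function() {
  data.frame(genome_id = character(), contig_id = character(),
             rank = integer(), start = integer(), end = integer(),
             strand = character(), protein_id = character(),
             stringsAsFactors = FALSE)
}

emptyDomainTable <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             accession = character(), evalue = numeric(),
             env_start = integer(), env_end = integer(),
             protein_length = integer(), stringsAsFactors = FALSE)
}

emptyOGTable <- function() {
  data.frame(protein_id = character(), og_label = character(),
             stringsAsFactors = FALSE)
}

emptyRMTable <- function() {
  data.frame(domain_name = character(), rm_types = character(),
             multi = logical(), stringsAsFactors = FALSE)
}

emptyTaxonomyTable <- function() {
  data.frame(genome_id = character(), phylum = character(),
             class = character(), order = character(), family = character(),
             genus = character(), species = character(),
             stringsAsFactors = FALSE)
}

RM_TYPE_LABELS <- c("I", "II", "III", "IV", "V-gene", "multi")
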