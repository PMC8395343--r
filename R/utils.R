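#' @keywords internal
"_PACKAGE"

# Derive a per-stage seed from the global run seed so stages are
# reproducible independently of each other. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    genome = 11L, counts = 23L, snps = 37L, expression = 41L,
    mirna = 43L, probability = 53L, permutation = 59L, pipeline = 61L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 101L + offsets[[stage]]
}

# Reverse complement of a plain character DNA string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract genomic sequence in a given orientation
#'
#' Coordinates are 0-based half-open on the forward strand; for `strand ==
#' "-"` the reverse complement is returned, so the result always reads in
#' sense (5' to 3') orientation of the feature.
#'
#' @param genome a named `Biostrings::DNAStringSet` (one entry per contig).
#' @param chrom contig name.
#' @param start0,end0 0-based half-open interval on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @return a character scalar.
#' @export
get_sequence <- function(genome, chrom, start0, end0, strand = "+") {
  stopifnot(inherits(genome, "DNAStringSet"))
  if (!chrom %in% names(genome)) stop("contig not in genome: ", chrom)
  if (start0 < 0 || end0 > length(genome[[chrom]]) || end0 < start0) {
    stop(sprintf("interval [%d,%d) out of range for %s", start0, end0, chrom))
  }
  if (end0 == start0) return("")
  s <- as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
  if (identical(strand, "-")) revcomp(s) else s
}

# write a data frame as TSV deterministically
write_tsv_strict <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
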