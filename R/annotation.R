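#' Genome annotation container
#'
#' A `genome_annotation` is a light S3 container with four data frames:
#'
#' * `genes`: `gene_id`, `symbol`, `chrom`, `strand`
#' * `transcripts`: `transcript_id`, `gene_id`
#' * `exons`: `transcript_id`, `start0`, `end0` (0-based half-open, forward
#'   strand), one row per exon, sorted 5' to 3' in transcript orientation
#' * `cds`: `transcript_id`, `cds_start0`, `cds_end0` — the genomic span of
#'   the coding region (absent rows mean non-coding)
#'
#' All genomic coordinates inside the package are 0-based half-open; the
#' GTF reader/writer is the only place where 1-based closed coordinates
#' appear. "Upstream"/"downstream" always refer to transcript (5' to 3')
#' orientation, obtained by flipping genomic order on the minus strand.
#'
#' @param genes,transcripts,exons,cds data frames as described above.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, transcripts, exons, cds = NULL) {
  if (is.null(cds)) {
    cds <- data.frame(transcript_id = character(), cds_start0 = integer(),
                      cds_end0 = integer())
  }
  genes <- as.data.frame(genes)
  transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons)
  cds <- as.data.frame(cds)
  stopifnot(all(c("gene_id", "symbol", "chrom", "strand") %in% names(genes)),
            all(c("transcript_id", "gene_id") %in% names(transcripts)),
            all(c("transcript_id", "start0", "end0") %in% names(exons)))
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(exons$end0 <= exons$start0) || any(exons$start0 < 0)) {
    stop("exon coordinates must satisfy 0 <= start < end")
  }
  orphan <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(orphan) > 0) {
    stop("transcript(s) without exons: ", paste(orphan, collapse = ", "))
  }
  ann <- structure(
    list(genes = genes, transcripts = transcripts,
         exons = order_exons(exons, transcripts, genes), cds = cds),
    class = "genome_annotation"
  )
  validate_annotation(ann)
  ann
}

# sort exons genomically within transcript, then flip on minus strand so
# storage order is 5'->3' in transcript orientation
order_exons <- function(exons, transcripts, genes) {
  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  tx_strand <- strand_of[transcripts$gene_id[
    match(exons$transcript_id, transcripts$transcript_id)]]
  parts <- split(seq_len(nrow(exons)), exons$transcript_id)
  idx <- unlist(lapply(parts, function(i) {
    o <- i[order(exons$start0[i])]
    if (tx_strand[o[1]] == "-") rev(o) else o
  }), use.names = FALSE)
  rownames(exons) <- NULL
  exons[idx, , drop = FALSE]
}

validate_annotation <- function(ann) {
  # exons within a transcript must not overlap
  for (tx in unique(ann$exons$transcript_id)) {
    e <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start0), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start0[-1] < e$end0[-nrow(e)])) {
      stop("overlapping exons in transcript ", tx)
    }
  }
  # CDS must lie within the transcript's exonic span
  for (i in seq_len(nrow(ann$cds))) {
    tx <- ann$cds$transcript_id[i]
    e <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
    if (nrow(e) == 0) stop("CDS for unknown transcript ", tx)
    if (ann$cds$cds_start0[i] < min(e$start0) ||
        ann$cds$cds_end0[i] > max(e$end0)) {
      stop("CDS of transcript ", tx, " extends past its exons")
    }
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d exons (%d CDS)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Read a GTF/GFF gene annotation
#'
#' Parses an ENSEMBL-dialect GTF via [rtracklayer::import()] and converts
#' the 1-based closed coordinates to the package's internal 0-based
#' half-open convention. Exons are grouped per transcript and stored 5' to
#' 3' in transcript orientation.
#'
#' @param path path to a GTF file.
#' @return a [genome_annotation()] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  keep <- meta$type %in% c("exon", "CDS")
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  if (length(gr) == 0) stop("no exon rows in ", path)
  if (any(is.na(meta$gene_id)) || any(is.na(meta$transcript_id))) {
    stop("rows without gene_id/transcript_id attributes in ", path)
  }
  df <- data.frame(
    type = as.character(meta$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(meta$gene_id),
    transcript_id = as.character(meta$transcript_id),
    symbol = if ("gene_name" %in% names(meta)) {
      as.character(meta$gene_name)
    } else {
      as.character(meta$gene_id)
    },
    stringsAsFactors = FALSE
  )
  df$symbol[is.na(df$symbol)] <- df$gene_id[is.na(df$symbol)]
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("no exon rows in ", path)
  genes <- unique(ex[, c("gene_id", "symbol", "chrom", "strand")])
  names(genes) <- c("gene_id", "symbol", "chrom", "strand")
  if (anyDuplicated(genes$gene_id)) {
    stop("inconsistent gene metadata for: ",
         paste(genes$gene_id[duplicated(genes$gene_id)], collapse = ", "))
  }
  transcripts <- unique(ex[, c("transcript_id", "gene_id")])
  cd <- df[df$type == "CDS", , drop = FALSE]
  cds <- if (nrow(cd) > 0) {
    agg <- stats::aggregate(cbind(cds_start0 = start0) ~ transcript_id, cd, min)
    agg2 <- stats::aggregate(cbind(cds_end0 = end0) ~ transcript_id, cd, max)
    merge(agg, agg2, by = "transcript_id")
  } else {
    NULL
  }
  genome_annotation(
    genes = genes,
    transcripts = transcripts,
    exons = ex[, c("transcript_id", "start0", "end0")],
    cds = cds
  )
}

# light structural validation so malformed rows are reported with their
# line number (rtracklayer's errors do not carry one)
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop(sprintf("malformed GTF row at line %d of %s", i, path))
    }
  }
  invisible(TRUE)
}

#' Write a genome annotation as GTF
#'
#' Inverse of [read_annotation()]: internal 0-based half-open exon/CDS
#' coordinates are emitted as 1-based closed GTF rows, so a read/write
#' round trip reproduces coordinates exactly.
#'
#' @param ann a [genome_annotation()].
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  gene_of <- stats::setNames(ann$transcripts$gene_id,
                             ann$transcripts$transcript_id)
  gi <- match(gene_of[ann$exons$transcript_id], ann$genes$gene_id)
  attr9 <- function(g, tx) sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
    g, tx, ann$genes$symbol[match(g, ann$genes$gene_id)]
  )
  ex_lines <- sprintf("%s\tpsikit\texon\t%d\t%d\t.\t%s\t.\t%s",
                      ann$genes$chrom[gi], ann$exons$start0 + 1L,
                      ann$exons$end0, ann$genes$strand[gi],
                      attr9(gene_of[ann$exons$transcript_id],
                            ann$exons$transcript_id))
  cds_lines <- character(0)
  if (nrow(ann$cds) > 0) {
    # emit CDS clipped to exons so coordinates are consistent
    cds_lines <- unlist(lapply(seq_len(nrow(ann$cds)), function(i) {
      tx <- ann$cds$transcript_id[i]
      g <- gene_of[[tx]]
      gidx <- match(g, ann$genes$gene_id)
      e <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
      s <- pmax(e$start0, ann$cds$cds_start0[i])
      en <- pmin(e$end0, ann$cds$cds_end0[i])
      keep <- en > s
      sprintf("%s\tpsikit\tCDS\t%d\t%d\t.\t%s\t.\t%s",
              ann$genes$chrom[gidx], s[keep] + 1L, en[keep],
              ann$genes$strand[gidx], attr9(g, tx))
    }))
  }
  writeLines(c(ex_lines, cds_lines), path)
  invisible(path)
}

#' Spliced (mature) transcript sequence
#'
#' Concatenates the exon sequences of a transcript in 5' to 3' order; on
#' the minus strand each exon is reverse complemented.
#'
#' @param ann a [genome_annotation()].
#' @param genome a named `DNAStringSet`.
#' @param transcript_id transcript to assemble.
#' @return character scalar, the mature mRNA sequence (DNA alphabet).
#' @export
spliced_sequence <- function(ann, genome, transcript_id) {
  e <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) == 0) stop("unknown transcript: ", transcript_id)
  g <- ann$transcripts$gene_id[match(transcript_id,
                                     ann$transcripts$transcript_id)]
  gi <- match(g, ann$genes$gene_id)
  paste(vapply(seq_len(nrow(e)), function(i) {
    get_sequence(genome, ann$genes$chrom[gi], e$start0[i], e$end0[i],
                 ann$genes$strand[gi])
  }, character(1)), collapse = "")
}

# convenience lookups used across modules
transcript_strand <- function(ann, transcript_id) {
  g <- ann$transcripts$gene_id[match(transcript_id,
                                     ann$transcripts$transcript_id)]
  ann$genes$strand[match(g, ann$genes$gene_id)]
}

gene_strand <- function(ann, gene_id) {
  ann$genes$strand[match(gene_id, ann$genes$gene_id)]
}

gene_chrom <- function(ann, gene_id) {
  ann$genes$chrom[match(gene_id, ann$genes$gene_id)]
}
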