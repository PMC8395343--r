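#' Read SNPs from a VCF file
#'
#' Reads single-nucleotide variants from a VCF v4.x file. Multi-allelic
#' rows are split into one record per ALT allele; indels (REF or ALT
#' longer than one base) are skipped and their count reported as a
#' message and in the `"n_indels_skipped"` attribute.
#'
#' Positions are kept 1-based as printed in the VCF; `pos0` carries the
#' internal 0-based coordinate.
#'
#' @param path path to a (plain-text) VCF.
#' @return data frame with columns `chrom`, `pos` (1-based), `pos0`,
#'   `ref`, `alt`, `strain`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) == 0) stop("not a VCF: missing #CHROM header in ", path)
  body <- lines[seq_along(lines) > hdr[1] & !grepl("^#", lines)]
  body <- body[nzchar(body)]
  empty <- data.frame(chrom = character(), pos = integer(), pos0 = integer(),
                      ref = character(), alt = character(),
                      strain = character())
  if (length(body) == 0) {
    attr(empty, "n_indels_skipped") <- 0L
    return(empty)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 8)) {
    stop("malformed VCF row at line ",
         hdr[1] + which(lengths(f) < 8)[1], " of ", path)
  }
  skipped <- 0L
  recs <- lapply(f, function(x) {
    ref <- x[4]
    alts <- strsplit(x[5], ",", fixed = TRUE)[[1]]
    snv <- nchar(ref) == 1 & nchar(alts) == 1 & alts %in% c("A", "C", "G", "T")
    skipped <<- skipped + sum(!snv)
    if (nchar(ref) != 1 || !ref %in% c("A", "C", "G", "T")) {
      skipped <<- skipped + sum(snv)
      snv[] <- FALSE
    }
    if (!any(snv)) return(NULL)
    strain <- sub("^.*STRAIN=([^;]+).*$", "\\1", x[8])
    if (identical(strain, x[8])) strain <- NA_character_
    data.frame(chrom = x[1], pos = as.integer(x[2]),
               pos0 = as.integer(x[2]) - 1L, ref = ref, alt = alts[snv],
               strain = strain)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  if (skipped > 0) message(skipped, " non-SNV allele(s) skipped")
  attr(out, "n_indels_skipped") <- skipped
  out
}

#' Write SNPs as a minimal VCF v4.2
#'
#' @param snps data frame with `chrom`, `pos` (1-based), `ref`, `alt`, and
#'   optionally `strain`.
#' @param path output path.
#' @export
write_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=STRAIN,Number=1,Type=String,Description=\"Strain\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- if ("strain" %in% names(snps) && nrow(snps) > 0) {
    ifelse(is.na(snps$strain), ".", paste0("STRAIN=", snps$strain))
  } else {
    rep(".", nrow(snps))
  }
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  snps$chrom, snps$pos, snps$ref, snps$alt, info)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read per-event inclusion/exclusion junction counts
#'
#' The table has one row per splicing event and one column per sample;
#' each cell holds `"inclusion,exclusion"` read counts. Missing cells
#' become `(0,0)` with a warning.
#'
#' @param path TSV path; first column `event_id`, remaining columns named
#'   by sample.
#' @return long-format data frame: `event_id`, `sample`, `inc`, `exc`.
#' @export
read_junction_counts <- function(path) {
  wide <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
  if (nrow(wide) == 0 || ncol(wide) < 2) {
    return(data.frame(event_id = character(), sample = character(),
                      inc = integer(), exc = integer()))
  }
  if (anyDuplicated(wide[[1]])) {
    stop("duplicate event id(s): ",
         paste(unique(wide[[1]][duplicated(wide[[1]])]), collapse = ", "))
  }
  samples <- names(wide)[-1]
  out <- do.call(rbind, lapply(samples, function(s) {
    cell <- wide[[s]]
    missing <- is.na(cell) | !nzchar(cell)
    if (any(missing)) {
      warning(sum(missing), " missing cell(s) in column ", s,
              " set to 0,0", call. = FALSE)
      cell[missing] <- "0,0"
    }
    parts <- strsplit(cell, ",", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("malformed count cell in column ", s)
    inc <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    exc <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    if (any(is.na(inc)) || any(is.na(exc)) || any(inc < 0) || any(exc < 0)) {
      stop("counts must be non-negative integers (column ", s, ")")
    }
    data.frame(event_id = wide[[1]], sample = s, inc = inc, exc = exc)
  }))
  rownames(out) <- NULL
  out
}

#' Write junction counts in the wide `"inc,exc"` layout
#'
#' @param counts long-format data frame as returned by
#'   [read_junction_counts()].
#' @param path output TSV path.
#' @export
write_junction_counts <- function(counts, path) {
  samples <- unique(counts$sample)
  events <- unique(counts$event_id)
  wide <- data.frame(event_id = events, check.names = FALSE)
  for (s in samples) {
    sub <- counts[counts$sample == s, ]
    m <- match(events, sub$event_id)
    wide[[s]] <- sprintf("%d,%d", sub$inc[m], sub$exc[m])
  }
  write_tsv_strict(wide, path)
}

#' Read an RBP motif definition table
#'
#' @param path TSV with columns `name`, `region` (comma-separated subset
#'   of `upstream_intron,exon,downstream_intron`), `patterns`
#'   (comma-separated IUPAC k-mers, 5-8 nt).
#' @return list of motif models (`name`, `regions`, `patterns`).
#' @export
read_motifs <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("name", "region", "patterns") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    motif_model(df$name[i],
                strsplit(df$patterns[i], ",", fixed = TRUE)[[1]],
                strsplit(df$region[i], ",", fixed = TRUE)[[1]])
  })
}

#' @rdname read_motifs
#' @param motifs list of motif models.
#' @export
write_motifs <- function(motifs, path) {
  df <- data.frame(
    name = vapply(motifs, `[[`, "", "name"),
    region = vapply(motifs, function(m) paste(m$regions, collapse = ","), ""),
    patterns = vapply(motifs, function(m) paste(m$patterns, collapse = ","), "")
  )
  write_tsv_strict(df, path)
}

#' Read an expression matrix with sample-group assignments
#'
#' @param path TSV; first column `feature_id`, remaining columns samples.
#' @param groups named character vector or data frame (`sample`, `group`)
#'   mapping every sample to one of exactly two groups.
#' @return an `expression_matrix`: list with `values` (features x samples
#'   numeric matrix) and `groups` (named vector).
#' @export
read_expression <- function(path, groups) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, groups)
}

#' @rdname read_expression
#' @param values numeric matrix, features x samples.
#' @export
expression_matrix <- function(values, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  if (!all(colnames(values) %in% names(groups))) {
    stop("samples without group assignment: ",
         paste(setdiff(colnames(values), names(groups)), collapse = ", "))
  }
  groups <- groups[colnames(values)]
  if (length(unique(groups)) != 2) stop("exactly two groups required")
  if (any(values < 0)) stop("expression values must be non-negative")
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  invisible(x)
}

#' Read a one-symbol-per-line gene list
#' @param path text file, one gene symbol per line.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Read an ortholog map (external symbol to native symbol)
#' @param path TSV with columns `external_symbol`, `native_symbol`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("external_symbol", "native_symbol") %in% names(df)))
  df
}

#' Read a target-exon coordinate list (e.g. curated microexon targets)
#' @param path TSV with columns `chrom`, `start0`, `end0`.
#' @export
read_target_exons <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("chrom", "start0", "end0") %in% names(df)))
  df
}
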