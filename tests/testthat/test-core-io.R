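gtf_line <- function(chrom, type, start, end, strand, gene, tx) {
  sprintf("%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
          chrom, type, start, end, strand, gene, tx, toupper(gene))
}

test_that("GTF 1-based closed coordinates become 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 101, 200, "+", "gA", "gA_t1"),
    gtf_line("chr1", "exon", 301, 400, "+", "gA", "gA_t1")
  ), f)
  ann <- read_annotation(f)
  e <- ann$exons[ann$exons$transcript_id == "gA_t1", ]
  expect_equal(e$start0, c(100, 300))
  expect_equal(e$end0, c(200, 400))
  expect_equal(e$end0 - e$start0, c(100, 100))
})

test_that("minus-strand exons are stored 5' to 3' in transcript orientation", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 101, 200, "-", "gB", "gB_t1"),
    gtf_line("chr1", "exon", 301, 400, "-", "gB", "gB_t1")
  ), f)
  ann <- read_annotation(f)
  e <- ann$exons[ann$exons$transcript_id == "gB_t1", ]
  # 5'-most exon of a minus-strand transcript is the genomic-right one
  expect_equal(e$start0, c(300, 100))
})

test_that("CDS extending past the exons is rejected", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    gtf_line("chr1", "exon", 101, 200, "+", "gC", "gC_t1"),
    gtf_line("chr1", "CDS", 150, 260, "+", "gC", "gC_t1")
  ), f)
  expect_error(read_annotation(f), "extends past")
})

test_that("malformed GTF rows are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "exon", 101, 200, "+", "g", "t"),
               "chr1\tonly\tthree"), f)
  expect_error(read_annotation(f), "line 2")
})

test_that("annotation write/read round trip reproduces coordinates exactly", {
  ann <- demo_bundle$annotation
  f <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(ann, f)
  back <- read_annotation(f)
  key <- function(a) {
    e <- a$exons[order(a$exons$transcript_id, a$exons$start0), ]
    paste(e$transcript_id, e$start0, e$end0)
  }
  expect_identical(key(back), key(ann))
  ckey <- function(a) {
    x <- a$cds[order(a$cds$transcript_id), ]
    paste(x$transcript_id, x$cds_start0, x$cds_end0)
  }
  expect_identical(ckey(back), ckey(ann))
})

test_that("spliced sequence length equals the sum of exon lengths", {
  ann <- demo_bundle$annotation
  genome <- demo_bundle$genome
  for (tx in ann$transcripts$transcript_id[c(1, 5, 10, 20)]) {
    e <- ann$exons[ann$exons$transcript_id == tx, ]
    expect_equal(nchar(spliced_sequence(ann, genome, tx)),
                 sum(e$end0 - e$start0))
  }
})

test_that("minus-strand sequence access returns the reverse complement", {
  g <- Biostrings::DNAStringSet("ACGTTGCA")
  names(g) <- "c"
  expect_equal(get_sequence(g, "c", 0, 4, "+"), "ACGT")
  expect_equal(get_sequence(g, "c", 0, 4, "-"), "ACGT")
  expect_equal(get_sequence(g, "c", 1, 5, "+"), "CGTT")
  expect_equal(get_sequence(g, "c", 1, 5, "-"), "AACG")
})

test_that("VCF reader splits multi-allelic rows and skips indels", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t500\t.\tG\tA\t.\tPASS\t.",
    "chr1\t600\t.\tC\tA,T\t.\tPASS\t.",
    "chr1\t700\t.\tA\tAT\t.\tPASS\t."
  ), f)
  v <- suppressMessages(read_vcf(f))
  expect_equal(nrow(v), 3)
  expect_equal(v$pos[1], 500)
  expect_equal(v$pos0[1], 499)
  expect_equal(v[v$pos == 600, "alt"], c("A", "T"))
  expect_equal(attr(v, "n_indels_skipped"), 1L)
})

test_that("VCF without a #CHROM header is rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chr1\t500\t.\tG\tA\t.\t.\t."), f)
  expect_error(read_vcf(f), "#CHROM")
})

test_that("VCF write/read round trip preserves all SNP records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(demo_bundle$snps, f)
  back <- read_vcf(f)
  expect_equal(back[, c("chrom", "pos", "ref", "alt")],
               demo_bundle$snps[, c("chrom", "pos", "ref", "alt")],
               ignore_attr = TRUE)
})

test_that("junction-count reader parses inc,exc cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\ts1\ts2", "ev1\t10,2\t8,4"), f)
  x <- read_junction_counts(f)
  expect_equal(x$inc, c(10, 8))
  expect_equal(x$exc, c(2, 4))
  expect_equal(x$sample, c("s1", "s2"))
})

test_that("junction-count reader enforces its contracts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\ts1", "ev1\t1,2", "ev1\t3,4"), f)
  expect_error(read_junction_counts(f), "duplicate")

  writeLines(c("event_id\ts1", "ev1\t-1,2"), f)
  expect_error(read_junction_counts(f), "non-negative")

  writeLines("event_id\ts1", f)
  expect_equal(nrow(read_junction_counts(f)), 0)

  writeLines(c("event_id\ts1\ts2", "ev1\t1,2\t"), f)
  expect_warning(x <- read_junction_counts(f), "missing")
  expect_equal(x$inc[x$sample == "s2"], 0)
})

test_that("junction counts survive a write/read round trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_junction_counts(demo_bundle$counts, f)
  back <- read_junction_counts(f)
  orig <- demo_bundle$counts[order(demo_bundle$counts$sample,
                                   demo_bundle$counts$event_id), ]
  back <- back[order(back$sample, back$event_id), ]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back, orig)
})
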