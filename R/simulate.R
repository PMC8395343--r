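#' Configuration of a synthetic two-group splicing study
#'
#' Bundles every knob of the synthetic-study generator. Defaults emulate
#' the design of a two-strain islet RNA-seq comparison: two groups of 5
#' animals, a mixed panel of cassette-exon / intron-retention /
#' alternative-splice-site events with planted group PSI values
#' (including curated-target microexons preferentially skipped in group
#' 1), strain SNPs planted in defined positional windows, RBP-motif
#' occurrences with and without allele disruption, and log-normal
#' expression with planted group effects.
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param n_per_group samples per group (default 5).
#' @param depth mean junction coverage per event and sample (default
#'   200, a typical well-covered junction).
#' @param noise_sd standard deviation of log-normal expression noise on
#'   the natural-log scale (default 0.25).
#' @param n_null_genes,n_null_mirnas extra features without group effect.
#' @param events optional event plan overriding [default_event_plan()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_per_group = 5, depth = 200,
                              noise_sd = 0.25, n_null_genes = 40,
                              n_null_mirnas = 26, events = NULL) {
  if (depth <= 0) stop("depth must be positive")
  ev <- if (is.null(events)) default_event_plan() else events
  if (any(ev$psi_g1 < 0 | ev$psi_g1 > 1 | ev$psi_g2 < 0 | ev$psi_g2 > 1)) {
    stop("planted PSI values must lie in [0,1]")
  }
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 depth = depth, noise_sd = noise_sd,
                 n_null_genes = n_null_genes,
                 n_null_mirnas = n_null_mirnas, events = ev),
            class = "simulation_config")
}

#' Default synthetic event panel
#'
#' One gene per event (two genes host two frameshifting exons each, so
#' that co-skipping can rescue the frame). Columns: `event_id`, `type`,
#' `length` (alternative segment), `psi_g1`, `psi_g2`, `region` (planted
#' CDS/UTR localisation), `target` (curated microexon-target flag),
#' `gene` (grouping key; events sharing it share a gene).
#'
#' @return data frame, one row per event.
#' @export
default_event_plan <- function() {
  df <- rbind(
    # coding cassette exons: preserved / shift frames, both directions
    data.frame(event_id = "ce01", type = "CE", length = 90,  psi_g1 = 0.20, psi_g2 = 0.90, region = "CDS", target = FALSE, gene = "ce01"),
    data.frame(event_id = "ce02", type = "CE", length = 120, psi_g1 = 0.90, psi_g2 = 0.20, region = "CDS", target = FALSE, gene = "ce02"),
    data.frame(event_id = "ce03", type = "CE", length = 100, psi_g1 = 0.30, psi_g2 = 0.60, region = "CDS", target = FALSE, gene = "ce03"),
    data.frame(event_id = "ce04", type = "CE", length = 110, psi_g1 = 0.65, psi_g2 = 0.35, region = "CDS", target = FALSE, gene = "ce04"),
    data.frame(event_id = "ce05", type = "CE", length = 75,  psi_g1 = 0.50, psi_g2 = 0.50, region = "CDS", target = FALSE, gene = "ce05"),
    data.frame(event_id = "ce06", type = "CE", length = 82,  psi_g1 = 0.50, psi_g2 = 0.48, region = "CDS", target = FALSE, gene = "ce06"),
    data.frame(event_id = "ce07", type = "CE", length = 93,  psi_g1 = 0.15, psi_g2 = 0.85, region = "CDS", target = FALSE, gene = "ce07"),
    data.frame(event_id = "ce08", type = "CE", length = 121, psi_g1 = 0.80, psi_g2 = 0.30, region = "CDS", target = FALSE, gene = "ce08"),
    # two rescue genes: paired frameshifting exons, same direction
    data.frame(event_id = "rg1a", type = "CE", length = 97,  psi_g1 = 0.20, psi_g2 = 0.80, region = "CDS", target = FALSE, gene = "rg1"),
    data.frame(event_id = "rg1b", type = "CE", length = 98,  psi_g1 = 0.25, psi_g2 = 0.85, region = "CDS", target = FALSE, gene = "rg1"),
    data.frame(event_id = "rg2a", type = "CE", length = 100, psi_g1 = 0.75, psi_g2 = 0.25, region = "CDS", target = FALSE, gene = "rg2"),
    data.frame(event_id = "rg2b", type = "CE", length = 104, psi_g1 = 0.80, psi_g2 = 0.30, region = "CDS", target = FALSE, gene = "rg2"),
    # UTR and non-coding cassette exons
    data.frame(event_id = "ceu5", type = "CE", length = 60,  psi_g1 = 0.30, psi_g2 = 0.80, region = "5UTR", target = FALSE, gene = "ceu5"),
    data.frame(event_id = "ceu3", type = "CE", length = 66,  psi_g1 = 0.70, psi_g2 = 0.20, region = "3UTR", target = FALSE, gene = "ceu3"),
    data.frame(event_id = "cenc", type = "CE", length = 45,  psi_g1 = 0.20, psi_g2 = 0.70, region = "noncoding", target = FALSE, gene = "cenc"),
    # curated-target microexons, preferentially skipped in group 1
    data.frame(event_id = "met1", type = "CE", length = 9,   psi_g1 = 0.20, psi_g2 = 0.90, region = "CDS", target = TRUE, gene = "met1"),
    data.frame(event_id = "met2", type = "CE", length = 12,  psi_g1 = 0.15, psi_g2 = 0.90, region = "CDS", target = TRUE, gene = "met2"),
    data.frame(event_id = "met3", type = "CE", length = 15,  psi_g1 = 0.25, psi_g2 = 0.85, region = "CDS", target = TRUE, gene = "met3"),
    data.frame(event_id = "met4", type = "CE", length = 18,  psi_g1 = 0.20, psi_g2 = 0.95, region = "CDS", target = TRUE, gene = "met4"),
    data.frame(event_id = "met5", type = "CE", length = 21,  psi_g1 = 0.10, psi_g2 = 0.90, region = "CDS", target = TRUE, gene = "met5"),
    data.frame(event_id = "met6", type = "CE", length = 24,  psi_g1 = 0.20, psi_g2 = 0.90, region = "CDS", target = TRUE, gene = "met6"),
    # non-target microexons
    data.frame(event_id = "men1", type = "CE", length = 6,   psi_g1 = 0.80, psi_g2 = 0.80, region = "CDS", target = FALSE, gene = "men1"),
    data.frame(event_id = "men2", type = "CE", length = 27,  psi_g1 = 0.50, psi_g2 = 0.50, region = "CDS", target = FALSE, gene = "men2"),
    data.frame(event_id = "men3", type = "CE", length = 30,  psi_g1 = 0.85, psi_g2 = 0.90, region = "CDS", target = FALSE, gene = "men3"),
    # intron retention
    data.frame(event_id = "ir01", type = "IR", length = 450, psi_g1 = 0.60, psi_g2 = 0.10, region = "CDS", target = FALSE, gene = "ir01"),
    data.frame(event_id = "ir02", type = "IR", length = 450, psi_g1 = 0.10, psi_g2 = 0.60, region = "CDS", target = FALSE, gene = "ir02"),
    data.frame(event_id = "ir03", type = "IR", length = 450, psi_g1 = 0.40, psi_g2 = 0.40, region = "CDS", target = FALSE, gene = "ir03"),
    data.frame(event_id = "ir04", type = "IR", length = 450, psi_g1 = 0.70, psi_g2 = 0.25, region = "CDS", target = FALSE, gene = "ir04"),
    data.frame(event_id = "ir05", type = "IR", length = 450, psi_g1 = 0.30, psi_g2 = 0.30, region = "CDS", target = FALSE, gene = "ir05"),
    data.frame(event_id = "ir06", type = "IR", length = 450, psi_g1 = 0.90, psi_g2 = 0.50, region = "CDS", target = FALSE, gene = "ir06"),
    # alternative 5' and 3' splice sites (45-nt extensions)
    data.frame(event_id = "a501", type = "alt5ss", length = 45, psi_g1 = 0.70, psi_g2 = 0.20, region = "CDS", target = FALSE, gene = "a501"),
    data.frame(event_id = "a502", type = "alt5ss", length = 45, psi_g1 = 0.20, psi_g2 = 0.70, region = "CDS", target = FALSE, gene = "a502"),
    data.frame(event_id = "a503", type = "alt5ss", length = 45, psi_g1 = 0.50, psi_g2 = 0.50, region = "CDS", target = FALSE, gene = "a503"),
    data.frame(event_id = "a504", type = "alt5ss", length = 45, psi_g1 = 0.80, psi_g2 = 0.40, region = "CDS", target = FALSE, gene = "a504"),
    data.frame(event_id = "a301", type = "alt3ss", length = 45, psi_g1 = 0.70, psi_g2 = 0.20, region = "CDS", target = FALSE, gene = "a301"),
    data.frame(event_id = "a302", type = "alt3ss", length = 45, psi_g1 = 0.20, psi_g2 = 0.70, region = "CDS", target = FALSE, gene = "a302"),
    data.frame(event_id = "a303", type = "alt3ss", length = 45, psi_g1 = 0.45, psi_g2 = 0.55, region = "CDS", target = FALSE, gene = "a303"),
    data.frame(event_id = "a304", type = "alt3ss", length = 45, psi_g1 = 0.35, psi_g2 = 0.75, region = "CDS", target = FALSE, gene = "a304")
  )
  # alternate strands across genes so orientation logic is exercised
  genes <- unique(df$gene)
  strand_of <- stats::setNames(rep(c("+", "-"), length.out = length(genes)),
                               genes)
  df$strand <- unname(strand_of[df$gene])
  df
}

#' Default SNP placement plan
#'
#' One planted SNP per (event, category) pair; categories are recovered
#' exactly by [classify_snp_position()] because planting uses the same
#' window definitions from the opposite direction. Distances (nt from the
#' exon edge, transcript orientation): intronic upstream 100, 3'ss 8,
#' exonic center, 5'ss 5, intronic downstream 200.
#'
#' @return data frame `event_id`, `category`.
#' @export
default_snp_plan <- function() {
  rbind(
    data.frame(event_id = "ce01", category = c("intronic_upstream",
      "ss3_adjacent", "exonic", "ss5_adjacent", "intronic_downstream")),
    data.frame(event_id = "ce02", category = c("intronic_upstream",
      "ss5_adjacent", "intronic_downstream")),
    data.frame(event_id = "ce03", category = c("exonic",
      "intronic_downstream")),
    data.frame(event_id = "ce07", category = c("ss3_adjacent",
      "intronic_upstream")),
    data.frame(event_id = "rg1a", category = "ss5_adjacent"),
    data.frame(event_id = "ir01", category = c("intronic_upstream",
      "intronic_downstream")),
    data.frame(event_id = "a501", category = "intronic_downstream"),
    data.frame(event_id = "a301", category = "intronic_upstream"),
    data.frame(event_id = "met1", category = "ss3_adjacent"),
    data.frame(event_id = "ce05", category = "ss5_adjacent")
  )
}

#' Default motif plant plan
#'
#' Motif occurrences written into event regions; `effect` is `"none"`
#' (plain occurrence), `"disrupt"` (a planted SNP breaks the match) or
#' `"create"` (the planted ALT allele completes the match).
#'
#' @return data frame `event_id`, `motif`, `region`, `effect`.
#' @export
default_motif_plan <- function() {
  rbind(
    data.frame(event_id = "ce01", motif = "SRSF1_like",
               region = "downstream_intron", effect = "disrupt"),
    data.frame(event_id = "ce02", motif = "SRSF1_like",
               region = "downstream_intron", effect = "none"),
    data.frame(event_id = "ce03", motif = "PCBP1_like",
               region = "upstream_intron", effect = "disrupt"),
    data.frame(event_id = "ce04", motif = "SRSF1_like",
               region = "exon", effect = "disrupt"),
    data.frame(event_id = "ce07", motif = "PCBP1_like",
               region = "upstream_intron", effect = "none"),
    data.frame(event_id = "ce08", motif = "SRSF1_like",
               region = "downstream_intron", effect = "create"),
    data.frame(event_id = "ir02", motif = "PCBP1_like",
               region = "upstream_intron", effect = "disrupt"),
    data.frame(event_id = "a502", motif = "SRSF1_like",
               region = "downstream_intron", effect = "none")
  )
}

#' Demonstration RBP motif set
#'
#' Two degenerate k-mer motifs in the style of SR-protein (purine-rich)
#' and poly-pyrimidine/poly-C binders. Identifiers are labels only; real
#' analyses should supply a curated motif file via [read_motifs()].
#' Pattern alphabets are chosen so the generator's neutral planting
#' contexts can never extend or fake a match.
#'
#' @return list of [motif_model()]s.
#' @export
demo_motifs <- function() {
  list(
    motif_model("SRSF1_like", "GGAGGAM",
                c("upstream_intron", "exon", "downstream_intron")),
    motif_model("PCBP1_like", "CCYCCY",
                c("upstream_intron", "exon", "downstream_intron"))
  )
}

# ---- internal geometry -----------------------------------------------------

.sim_flank <- 600L   # chromosome padding outside the gene
.sim_e1 <- 150L      # first constitutive exon
.sim_intron <- 800L  # introns flanking the alternative segment
.sim_e3 <- 150L      # last constitutive exon

# per-gene layout: flank | exon1 | intron | [alt segment] | intron | exon3 |
# flank; returns exon coordinates and chromosome length for one event gene
sim_gene_layout <- function(type, len) {
  fl <- .sim_flank; e1 <- .sim_e1; it <- .sim_intron; e3 <- .sim_e3
  e1_s <- fl; e1_e <- fl + e1
  if (type == "CE") {
    ex2_s <- e1_e + it; ex2_e <- ex2_s + len
    e3_s <- ex2_e + it; e3_e <- e3_s + e3
    list(chrom_len = e3_e + fl, seg = c(ex2_s, ex2_e),
         e1 = c(e1_s, e1_e), ex2 = c(ex2_s, ex2_e), e3 = c(e3_s, e3_e))
  } else if (type == "IR") {
    e2_s <- e1_e + len; e2_e <- e2_s + e3
    list(chrom_len = e2_e + fl, seg = c(e1_e, e2_s),
         e1 = c(e1_s, e1_e), e3 = c(e2_s, e2_e))
  } else if (type == "alt5ss" || type == "alt3ss") {
    # exon2 with a variable boundary; the segment is the 'len' extension
    ex2_s <- e1_e + it; ex2_core <- 120L
    ex2_e <- ex2_s + ex2_core
    ext_e <- ex2_e + len
    e3_s <- ext_e + it; e3_e <- e3_s + e3
    list(chrom_len = e3_e + fl, core = c(ex2_s, ex2_e), ext = c(ex2_s, ext_e),
         seg_right = c(ex2_e, ext_e),
         e1 = c(e1_s, e1_e), e3 = c(e3_s, e3_e))
  } else {
    stop("unknown event type: ", type)
  }
}

# write `seq` (sense orientation) into chromosome character vector `chars`
# at sense offset `off` of the forward-strand interval iv = c(s, e)
plant_sense <- function(chars, iv, strand, off, seq) {
  k <- nchar(seq)
  if (off + k > iv[2] - iv[1]) stop("planted sequence exceeds region")
  if (strand == "+") {
    pos <- (iv[1] + off + 1):(iv[1] + off + k)
    chars[pos] <- strsplit(seq, "")[[1]]
  } else {
    pos <- (iv[2] - off - k + 1):(iv[2] - off)
    chars[pos] <- strsplit(revcomp(seq), "")[[1]]
  }
  chars
}

# genomic 0-based position of a SNP planted at transcript-oriented distance
# d from the segment: side is "up" (upstream intron), "down", or "exon_center"
sim_snp_pos <- function(seg, strand, where, d = NULL) {
  s <- seg[1]; e <- seg[2]
  if (where == "exon_center") return(s + (e - s) %/% 2)
  left <- (where == "up") == (strand == "+")
  if (left) s - d else e + d - 1L
}

#' Generate a complete synthetic study bundle
#'
#' Builds a toy genome, annotation, junction counts, strain VCF, motif
#' file, expression matrices, miRNA/UTR sequences, auxiliary gene lists
#' and ground-truth tables, and writes everything under `out_dir` in
#' exactly the formats the package readers consume.
#'
#' Planted features are placed in neutral sequence contexts (the
#' generator scrubs the immediate neighbourhood of planted motifs and
#' SNPs) so every planted SNP positional category, motif effect and CpG
#' loss is recovered exactly by the downstream classifiers, for any seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible list with the in-memory objects (`annotation`,
#'   `genome`, `counts`, `groups`, `events`, `snps`, `motifs`,
#'   `gene_expr`, `mirna_expr`, `mirna_seqs`, `utr`, truth tables) and
#'   all file `paths`.
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  plan <- config$events

  old <- local_seed(stage_seed(config$seed, "genome"))
  on.exit(old())

  chroms <- list(); exons <- list(); transcripts <- list()
  genes <- list(); cds <- list(); events <- list()
  for (g in unique(plan$gene)) {
    sub <- plan[plan$gene == g, , drop = FALSE]
    strand <- sub$strand[1]
    chrom <- paste0("chr_", g)
    if (nrow(sub) == 1) {
      lay <- sim_gene_layout(sub$type[1], sub$length[1])
      chars <- sample(c("A", "C", "G", "T"), lay$chrom_len, replace = TRUE)
      if (sub$type[1] == "CE") {
        ex_inc <- rbind(lay$e1, lay$ex2, lay$e3)
        ex_exc <- rbind(lay$e1, lay$e3)
        seg <- lay$seg
      } else if (sub$type[1] == "IR") {
        ex_inc <- rbind(c(lay$e1[1], lay$e3[2]))       # retained
        ex_exc <- rbind(lay$e1, lay$e3)                # spliced
        seg <- lay$seg
      } else {
        long_first <- (sub$type[1] == "alt5ss") == (strand == "+")
        # the boundary that varies sits at the genomic right edge for
        # alt5ss(+)/alt3ss(-); mirror the exon around the core otherwise
        if (long_first) {
          ex_inc <- rbind(lay$e1, lay$ext, lay$e3)
          ex_exc <- rbind(lay$e1, lay$core, lay$e3)
          seg <- lay$seg_right
        } else {
          # variable left edge: extend the core to the left instead
          core <- c(lay$core[1] + sub$length[1], lay$core[2] + sub$length[1])
          ext <- c(lay$core[1], core[2])
          ex_inc <- rbind(lay$e1, ext, lay$e3)
          ex_exc <- rbind(lay$e1, core, lay$e3)
          seg <- c(ext[1], core[1])
        }
      }
      tx <- data.frame(
        transcript_id = paste0(g, c("_tA", "_tB")), gene_id = g
      )
      ex <- rbind(
        data.frame(transcript_id = paste0(g, "_tA"),
                   start0 = ex_inc[, 1], end0 = ex_inc[, 2]),
        data.frame(transcript_id = paste0(g, "_tB"),
                   start0 = ex_exc[, 1], end0 = ex_exc[, 2])
      )
      span <- c(min(ex$start0), max(ex$end0))
      cd <- sim_cds(sub$region[1], strand, span, seg, lay)
      if (!is.null(cd)) {
        cds[[g]] <- data.frame(transcript_id = paste0(g, c("_tA", "_tB")),
                               cds_start0 = cd[1], cds_end0 = cd[2])
      }
      events[[length(events) + 1]] <- data.frame(
        event_id = sub$event_id[1], gene_id = g, chrom = chrom,
        strand = strand, seg_start0 = seg[1], seg_end0 = seg[2],
        type = sub$type[1], target = sub$target[1],
        psi_g1 = sub$psi_g1[1], psi_g2 = sub$psi_g2[1],
        region = sub$region[1]
      )
    } else {
      # rescue gene: two cassette exons in tandem
      fl <- .sim_flank; e1 <- .sim_e1; it <- .sim_intron; e3 <- .sim_e3
      l1 <- sub$length[1]; l2 <- sub$length[2]
      e1_s <- fl; e1_e <- fl + e1
      x1 <- c(e1_e + it, e1_e + it + l1)
      x2 <- c(x1[2] + it, x1[2] + it + l2)
      e3_s <- x2[2] + it; e3_e <- e3_s + e3
      chars <- sample(c("A", "C", "G", "T"), e3_e + fl, replace = TRUE)
      tx <- data.frame(
        transcript_id = paste0(g, c("_tA", "_tB")), gene_id = g
      )
      ex <- rbind(
        data.frame(transcript_id = paste0(g, "_tA"),
                   start0 = c(e1_s, x1[1], x2[1], e3_s),
                   end0 = c(e1_e, x1[2], x2[2], e3_e)),
        data.frame(transcript_id = paste0(g, "_tB"),
                   start0 = c(e1_s, e3_s), end0 = c(e1_e, e3_e))
      )
      cds[[g]] <- data.frame(transcript_id = paste0(g, c("_tA", "_tB")),
                             cds_start0 = e1_s + 30L, cds_end0 = e3_e - 30L)
      segs <- list(x1, x2)
      for (k in 1:2) {
        events[[length(events) + 1]] <- data.frame(
          event_id = sub$event_id[k], gene_id = g, chrom = chrom,
          strand = strand, seg_start0 = segs[[k]][1],
          seg_end0 = segs[[k]][2], type = "CE", target = FALSE,
          psi_g1 = sub$psi_g1[k], psi_g2 = sub$psi_g2[k],
          region = "CDS"
        )
      }
    }
    genes[[g]] <- data.frame(gene_id = g, symbol = paste0("Sym", g),
                             chrom = chrom, strand = strand)
    transcripts[[g]] <- tx
    exons[[g]] <- ex
    chroms[[chrom]] <- chars
  }
  events <- do.call(rbind, events)
  motifs <- demo_motifs()

  # ---- plant motifs and motif-affecting SNPs -------------------------------
  mplan <- default_motif_plan()
  mplan <- mplan[mplan$event_id %in% events$event_id, , drop = FALSE]
  snp_rows <- list()
  for (i in seq_len(nrow(mplan))) {
    ev <- events[events$event_id == mplan$event_id[i], ]
    chars <- chroms[[ev$chrom]]
    iv <- plant_region_interval(ev, mplan$region[i], length(chars))
    motif <- motifs[[which(vapply(motifs, `[[`, "", "name") ==
                             mplan$motif[i])]]
    instance <- if (motif$name == "SRSF1_like") "GGAGGAC" else "CCTCCT"
    off <- 30L
    scrub <- strrep("T", max(nchar(motif$patterns)) - 1)
    if (mplan$effect[i] == "create") {
      # write a near-miss; the ALT allele completes the match
      broken <- sub("^(.{5}).", "\\1T", instance)  # position 6 -> T
      chars <- plant_sense(chars, iv, ev$strand,
                           off - nchar(scrub), scrub)
      chars <- plant_sense(chars, iv, ev$strand, off, broken)
      chars <- plant_sense(chars, iv, ev$strand, off + nchar(instance),
                           scrub)
      snp_pos <- sense_offset_to_pos0(iv, ev$strand, off + 5L)
      ref_sense <- "T"; alt_sense <- substr(instance, 6, 6)
    } else {
      chars <- plant_sense(chars, iv, ev$strand,
                           off - nchar(scrub), scrub)
      chars <- plant_sense(chars, iv, ev$strand, off, instance)
      chars <- plant_sense(chars, iv, ev$strand, off + nchar(instance),
                           scrub)
      snp_pos <- NA
      if (mplan$effect[i] == "disrupt") {
        # break an invariant position: index 4 (1-based) of the instance
        snp_pos <- sense_offset_to_pos0(iv, ev$strand, off + 3L)
        ref_sense <- substr(instance, 4, 4)
        alt_sense <- if (ref_sense == "G") "A" else "A"
      }
    }
    chroms[[ev$chrom]] <- chars
    if (mplan$effect[i] != "none") {
      ref <- if (ev$strand == "+") ref_sense else revcomp(ref_sense)
      alt <- if (ev$strand == "+") alt_sense else revcomp(alt_sense)
      snp_rows[[length(snp_rows) + 1]] <- data.frame(
        chrom = ev$chrom, pos = snp_pos + 1L, pos0 = snp_pos,
        ref = ref, alt = alt, strain = "strain1",
        purpose = paste0("motif_", mplan$effect[i]),
        event_id = ev$event_id, category = NA_character_,
        motif = motif$name, region = mplan$region[i]
      )
    }
  }

  # ---- plant positional-category SNPs (neutral T[A]T context) --------------
  splan <- default_snp_plan()
  splan <- splan[splan$event_id %in% events$event_id, , drop = FALSE]
  for (i in seq_len(nrow(splan))) {
    ev <- events[events$event_id == splan$event_id[i], ]
    seg <- c(ev$seg_start0, ev$seg_end0)
    cat <- splan$category[i]
    pos0 <- switch(cat,
      intronic_upstream = sim_snp_pos(seg, ev$strand, "up", 100L),
      ss3_adjacent = sim_snp_pos(seg, ev$strand, "up", 8L),
      exonic = sim_snp_pos(seg, ev$strand, "exon_center"),
      ss5_adjacent = sim_snp_pos(seg, ev$strand, "down", 5L),
      intronic_downstream = sim_snp_pos(seg, ev$strand, "down", 200L),
      stop("unknown category: ", cat)
    )
    chars <- chroms[[ev$chrom]]
    # neutral T[A]T context: neither allele can sit inside a motif match
    # or a CpG dinucleotide
    chars[(pos0):(pos0 + 2L)] <- c("T", "A", "T")  # 1-based; A at pos0
    chroms[[ev$chrom]] <- chars
    snp_rows[[length(snp_rows) + 1]] <- data.frame(
      chrom = ev$chrom, pos = pos0 + 1L, pos0 = pos0,
      ref = "A", alt = "G", strain = "strain1",
      purpose = "positional", event_id = ev$event_id, category = cat,
      motif = NA_character_, region = NA_character_
    )
  }

  # ---- plant CpG-destroying SNPs (A[C]G context, C>T) ----------------------
  cpg_plan <- data.frame(
    event_id = c("ce01", "ce01", "ce01", "ce02", "ir01"),
    d = c(150L, 160L, 170L, 150L, 150L)  # nt into the upstream intron
  )
  cpg_plan <- cpg_plan[cpg_plan$event_id %in% events$event_id, , drop = FALSE]
  for (i in seq_len(nrow(cpg_plan))) {
    ev <- events[events$event_id == cpg_plan$event_id[i], ]
    seg <- c(ev$seg_start0, ev$seg_end0)
    pos0 <- sim_snp_pos(seg, ev$strand, "up", cpg_plan$d[i])
    chars <- chroms[[ev$chrom]]
    # TA[C]GT: forward-strand CpG at pos0; the T flanks stop either
    # allele from completing a degenerate motif match
    chars[(pos0 - 1L):(pos0 + 3L)] <- c("T", "A", "C", "G", "T")
    chroms[[ev$chrom]] <- chars
    snp_rows[[length(snp_rows) + 1]] <- data.frame(
      chrom = ev$chrom, pos = pos0 + 1L, pos0 = pos0,
      ref = "C", alt = "T", strain = "strain1",
      purpose = "cpg_loss", event_id = ev$event_id,
      category = NA_character_, motif = NA_character_,
      region = NA_character_
    )
  }
  snps <- do.call(rbind, snp_rows)

  # ---- assemble annotation + genome ----------------------------------------
  ann <- genome_annotation(
    genes = do.call(rbind, genes),
    transcripts = do.call(rbind, transcripts),
    exons = do.call(rbind, exons),
    cds = do.call(rbind, cds)
  )
  genome <- Biostrings::DNAStringSet(vapply(chroms, paste, "",
                                            collapse = ""))

  # generation-time audit: planted SNP effects must be recovered exactly
  audit_planted_snps(genome, events, snps, motifs)

  # ---- junction counts -----------------------------------------------------
  old2 <- local_seed(stage_seed(config$seed, "counts"))
  samples <- c(paste0("g1_", seq_len(config$n_per_group)),
               paste0("g2_", seq_len(config$n_per_group)))
  groups <- data.frame(
    sample = samples,
    group = rep(c("group1", "group2"), each = config$n_per_group)
  )
  counts <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    psi <- c(rep(events$psi_g1[i], config$n_per_group),
             rep(events$psi_g2[i], config$n_per_group))
    n <- stats::rpois(length(samples), config$depth)
    inc <- stats::rbinom(length(samples), n, psi)
    data.frame(event_id = events$event_id[i], sample = samples,
               inc = inc, exc = n - inc)
  }))
  old2()

  # ---- expression ----------------------------------------------------------
  exprs <- generate_expression(config, gene_ids = unique(events$gene_id))

  # ---- write files ---------------------------------------------------------
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    annotation = file.path(out_dir, "annotation.gtf"),
    junctions = file.path(out_dir, "junctions.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    vcf = file.path(out_dir, "snps.vcf"),
    motifs = file.path(out_dir, "motifs.tsv"),
    events = file.path(out_dir, "events.tsv"),
    gene_expr = file.path(out_dir, "gene_expression.tsv"),
    mirna_expr = file.path(out_dir, "mirna_expression.tsv"),
    mirnas = file.path(out_dir, "mirnas.fa"),
    utr = file.path(out_dir, "utr.fa"),
    targets = file.path(out_dir, "target_exons.tsv"),
    gwas = file.path(out_dir, "gwas_genes.txt"),
    orthologs = file.path(out_dir, "ortholog_map.tsv"),
    truth_events = file.path(out_dir, "truth", "events.tsv"),
    truth_snps = file.path(out_dir, "truth", "snps.tsv"),
    truth_motifs = file.path(out_dir, "truth", "motif_effects.tsv"),
    truth_expression = file.path(out_dir, "truth", "expression.tsv"),
    truth_mirna = file.path(out_dir, "truth", "mirna_regulators.tsv")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  write_annotation(ann, paths$annotation)
  write_junction_counts(counts, paths$junctions)
  write_tsv_strict(groups, paths$samples)
  write_vcf(snps, paths$vcf)
  write_motifs(motifs, paths$motifs)
  write_tsv_strict(events[, c("event_id", "gene_id", "chrom", "strand",
                              "seg_start0", "seg_end0")], paths$events)
  gm <- as.data.frame(exprs$genes$values)
  gm <- cbind(feature_id = rownames(exprs$genes$values), gm)
  write_tsv_strict(gm, paths$gene_expr)
  mm <- as.data.frame(exprs$mirnas$values)
  mm <- cbind(feature_id = rownames(exprs$mirnas$values), mm)
  write_tsv_strict(mm, paths$mirna_expr)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(exprs$mirna_seqs), paths$mirnas)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(factor_utr = exprs$utr)), paths$utr)
  tg <- events[events$target, c("chrom", "seg_start0", "seg_end0")]
  names(tg) <- c("chrom", "start0", "end0")
  write_tsv_strict(tg, paths$targets)
  writeLines(exprs$gwas_genes, paths$gwas)
  write_tsv_strict(exprs$ortholog_map, paths$orthologs)

  truth_events <- events[, c("event_id", "gene_id", "type", "region",
                             "target", "psi_g1", "psi_g2")]
  write_tsv_strict(truth_events, paths$truth_events)
  write_tsv_strict(snps[, c("chrom", "pos", "ref", "alt", "purpose",
                            "event_id", "category")], paths$truth_snps)
  truth_motifs <- snps[snps$purpose %in% c("motif_disrupt", "motif_create"),
                       c("event_id", "motif", "region", "purpose")]
  truth_motifs$effect <- sub("motif_", "", truth_motifs$purpose)
  truth_motifs$purpose <- NULL
  write_tsv_strict(truth_motifs, paths$truth_motifs)
  write_tsv_strict(exprs$truth_expression, paths$truth_expression)
  write_tsv_strict(exprs$truth_mirna, paths$truth_mirna)

  invisible(list(
    annotation = ann, genome = genome, counts = counts, groups = groups,
    events = events, snps = snps, motifs = motifs,
    gene_expr = exprs$genes, mirna_expr = exprs$mirnas,
    mirna_seqs = exprs$mirna_seqs, utr = exprs$utr,
    gwas_genes = exprs$gwas_genes, ortholog_map = exprs$ortholog_map,
    truth = list(events = truth_events, snps = snps,
                 motifs = truth_motifs,
                 expression = exprs$truth_expression,
                 mirna = exprs$truth_mirna),
    paths = paths
  ))
}

# CDS span for a single-event gene, honouring the planted localisation
sim_cds <- function(region, strand, span, seg, lay) {
  if (region == "noncoding") return(NULL)
  if (region == "CDS") {
    return(c(span[1] + 30L, span[2] - 30L))
  }
  # UTR events: confine the CDS to the constitutive exon on the coding
  # side so the alternative exon falls in the requested UTR
  left_exon <- lay$e1; right_exon <- lay$e3
  if ((region == "5UTR") == (strand == "+")) {
    c(right_exon[1] + 10L, right_exon[2] - 10L)   # CDS in genomic-right exon
  } else {
    c(left_exon[1] + 10L, left_exon[2] - 10L)
  }
}

# forward-strand interval of a motif-planting region (flank fixed at 250)
plant_region_interval <- function(ev, region, chrom_len, flank_nt = 250) {
  region_interval0(ev, region, chrom_len, flank_nt)
}

# map a sense-orientation offset inside interval iv to a forward-strand
# 0-based genomic position
sense_offset_to_pos0 <- function(iv, strand, off) {
  if (strand == "+") iv[1] + off else iv[2] - off - 1L
}

# verify that every planted SNP is recovered by the classifiers; the
# generator refuses to emit a bundle whose truth tables would not hold
audit_planted_snps <- function(genome, events, snps, motifs) {
  for (i in seq_len(nrow(snps))) {
    sn <- snps[i, ]
    ev <- events[events$event_id == sn$event_id, ]
    if (sn$purpose == "positional") {
      got <- classify_snp_position(sn$pos0, ev$seg_start0, ev$seg_end0,
                                   ev$strand)$category
      if (got != sn$category) {
        stop(sprintf("planted %s SNP recovered as %s (event %s)",
                     sn$category, got, sn$event_id))
      }
    } else if (sn$purpose %in% c("motif_disrupt", "motif_create")) {
      m <- motifs[[which(vapply(motifs, `[[`, "", "name") == sn$motif)]]
      iv <- event_region_interval(genome, ev, sn$region, 250)
      got <- snp_motif_effect(genome, sn$chrom, sn$pos0, sn$ref, sn$alt,
                              m, iv[1], iv[2], ev$strand)
      want <- sub("motif_", "", sn$purpose)
      if (got != want) {
        stop(sprintf("planted %s SNP recovered as %s (event %s)",
                     want, got, sn$event_id))
      }
    } else if (sn$purpose == "cpg_loss") {
      got <- count_cpg_loss(sn, genome)$calls
      if (!got) stop("planted CpG-loss SNP not recovered (event ",
                     sn$event_id, ")")
    }
  }
  invisible(TRUE)
}

#' Generate synthetic expression matrices (genes and miRNAs)
#'
#' Log-normal expression with planted group effects. The splicing-factor
#' gene `factor_gene` is down in group 1 (mirroring reduced microexon
#' inclusion there); two miRNAs are up in group 1 and carry seed sites in
#' the factor's 3'UTR; decoy miRNAs are up with only a 6mer site, or
#' changed in the wrong direction. The 3'UTR background alphabet is A/T
#' and all miRNA seeds contain G or C, so no unplanned seed site can
#' arise; the generator additionally re-samples decoy miRNAs until none
#' has a 7mer-or-better site.
#'
#' @param config a [simulation_config()].
#' @param gene_ids gene identifiers to include alongside the null genes.
#' @return list with `genes` and `mirnas` ([expression_matrix()]s),
#'   `mirna_seqs`, `utr`, `gwas_genes`, `ortholog_map`, and truth tables.
#' @export
generate_expression <- function(config, gene_ids = character(0),
                                gene_effects = NULL, mir_effects = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$depth <= 0) stop("depth must be positive")
  n <- config$n_per_group
  samples <- c(paste0("g1_", seq_len(n)), paste0("g2_", seq_len(n)))
  groups <- stats::setNames(rep(c("group1", "group2"), each = n), samples)
  is_g1 <- groups == "group1"

  old <- local_seed(stage_seed(config$seed, "expression"))
  on.exit(old())

  if (is.null(gene_effects)) {
    gene_effects <- c(factor_gene = -2, eff_up1 = 3, eff_up2 = 1.5,
                      eff_dn1 = -3)
  }
  null_genes <- sprintf("null_g%02d", seq_len(config$n_null_genes))
  all_genes <- c(names(gene_effects), gene_ids, null_genes)
  l2fc <- stats::setNames(rep(0, length(all_genes)), all_genes)
  l2fc[names(gene_effects)] <- gene_effects

  draw <- function(l2) {
    mu <- log(50) + log(2) * ifelse(is_g1, l2 / 2, -l2 / 2)
    exp(stats::rnorm(length(samples), mu, config$noise_sd))
  }
  gv <- t(vapply(all_genes, function(g) draw(l2fc[[g]]),
                 numeric(length(samples))))
  colnames(gv) <- samples

  # miRNAs: two true regulators (seed site in the factor UTR), one 6mer
  # decoy, one wrong-direction, the rest null
  if (is.null(mir_effects)) {
    mir_effects <- c(mir_up_a = 4, mir_up_b = 4, mir_up_6mer = 4,
                     mir_down = -3)
  }
  null_mirnas <- sprintf("mir_null%02d", seq_len(config$n_null_mirnas))
  all_mirnas <- c(names(mir_effects), null_mirnas)
  ml2 <- stats::setNames(rep(0, length(all_mirnas)), all_mirnas)
  ml2[names(mir_effects)] <- mir_effects
  mv <- t(vapply(all_mirnas, function(m) draw(ml2[[m]]),
                 numeric(length(samples))))
  colnames(mv) <- samples

  old_m <- local_seed(stage_seed(config$seed, "mirna"))
  utr <- sim_factor_utr()
  seqs <- sim_mirna_sequences(all_mirnas, utr)
  old_m()

  gwas_genes <- c(toupper(gene_ids[seq_len(min(3, length(gene_ids)))]),
                  "EXTGENE1", "EXTGENE2", "EXTGENE3")
  ortholog_map <- data.frame(
    external_symbol = gwas_genes,
    native_symbol = c(gene_ids[seq_len(min(3, length(gene_ids)))],
                      "other1", "other2", "other3")
  )

  list(
    genes = expression_matrix(gv, groups),
    mirnas = expression_matrix(mv, groups),
    mirna_seqs = seqs, utr = utr,
    gwas_genes = gwas_genes, ortholog_map = ortholog_map,
    truth_expression = data.frame(feature_id = all_genes,
                                  log2fc = unname(l2fc)),
    truth_mirna = data.frame(
      mirna = all_mirnas, log2fc = unname(ml2),
      true_regulator = all_mirnas %in% c("mir_up_a", "mir_up_b")
    )
  )
}

# fixed miRNAs with known seed relationships to the factor UTR
.sim_fixed_mirnas <- c(
  mir_up_a = "TAGCGCAGTCAAAGAATGGTGT",
  mir_up_b = "TCCGTGACAGTAAAGAATGGTG",
  mir_up_6mer = "TGACCTAGTTAAAGAATGGTGT",
  mir_down = "TGGTCACGTTAAAGAATGGTGT"
)

# 3'UTR of the splicing-factor gene: A/T background with planted sites
# for the two true regulators (8mer, 7mer-m8) and a 6mer-only decoy
# site. Every miRNA seed contains G or C, so the background cannot form
# chance seed matches.
sim_factor_utr <- function() {
  seqs <- .sim_fixed_mirnas
  bg <- function(n) paste(sample(c("A", "T"), n, replace = TRUE),
                          collapse = "")
  site8 <- function(m) paste0(revcomp(substr(m, 2, 8)), "A")   # 8mer
  site7m8 <- function(m) {
    paste0(revcomp(substr(m, 2, 8)), "T")                      # 7mer-m8
  }
  site6only <- function(m) {
    # wrong base opposite position 8, non-A opposite position 1
    paste0("T", revcomp(substr(m, 2, 7)), "T")
  }
  utr <- paste0(
    bg(120), site8(seqs[["mir_up_a"]]),
    bg(110), site7m8(seqs[["mir_up_b"]]),
    bg(110), site6only(seqs[["mir_up_6mer"]]),
    bg(140)
  )
  # deterministic guarantees for the fixed decoys
  stopifnot(
    nrow(find_seed_sites(seqs[["mir_up_a"]], utr)) > 0,
    nrow(find_seed_sites(seqs[["mir_up_b"]], utr)) > 0
  )
  for (id in c("mir_up_6mer", "mir_down")) {
    s <- find_seed_sites(seqs[[id]], utr)
    stopifnot(nrow(s) == 0 || min(seed_site_priority(s$site_type)) == 4)
  }
  utr
}

# 22-nt miRNA sequences; null miRNAs are re-sampled until their seed is
# GC-containing, distinct from the fixed seeds, and without a
# 7mer-or-better site in the UTR
sim_mirna_sequences <- function(ids, utr) {
  fixed <- .sim_fixed_mirnas
  out <- character(length(ids))
  names(out) <- ids
  for (id in ids) {
    if (id %in% names(fixed)) {
      out[[id]] <- fixed[[id]]
      next
    }
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                 collapse = "")
      seed <- substr(s, 2, 8)
      if (!grepl("[GC]", seed) || seed %in% substr(fixed, 2, 8)) next
      sites <- find_seed_sites(s, utr)
      if (nrow(sites) == 0 ||
          min(seed_site_priority(sites$site_type)) == 4) break
    }
    out[[id]] <- s
  }
  out
}
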