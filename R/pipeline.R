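#' Run configuration for the full pipeline
#'
#' Collects input paths, thresholds and the seed. Thresholds default to
#' the values used throughout the event filtering and annotation:
#' delta-PSI cutoff 0.1, posterior-probability cutoff 0.9, strong/
#' moderate boundary 0.5, 15-nt splice-site windows, 15-500-nt intronic
#' windows, 250-nt motif-scan flanks, microexon range 3-30 nt, alpha
#' 0.05.
#'
#' @param annotation,genome,junctions,samples GTF / FASTA / junction TSV
#'   / sample-group TSV paths (required).
#' @param vcf,motifs,gene_expr,mirna_expr,mirnas,utr,targets,gwas,orthologs
#'   optional input paths; stages missing their inputs are skipped with a
#'   manifest note.
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param dpsi_cutoff,prob_cutoff,strong_cutoff,ss_window,intron_window,
#'   flank_nt,microexon_range,alpha thresholds (see above).
#' @param n_draws posterior draws per event.
#' @return a `run_config` list.
#' @export
run_config <- function(annotation, genome, junctions, samples,
                       vcf = NULL, motifs = NULL, gene_expr = NULL,
                       mirna_expr = NULL, mirnas = NULL, utr = NULL,
                       targets = NULL, gwas = NULL, orthologs = NULL,
                       out_dir = "results", seed = 1,
                       dpsi_cutoff = 0.1, prob_cutoff = 0.9,
                       strong_cutoff = 0.5, ss_window = 15,
                       intron_window = c(15, 500), flank_nt = 250,
                       microexon_range = c(3, 30), alpha = 0.05,
                       n_draws = 10000) {
  stopifnot(dpsi_cutoff >= 0, dpsi_cutoff <= 1,
            prob_cutoff >= 0, prob_cutoff <= 1,
            strong_cutoff >= 0, strong_cutoff <= 1,
            ss_window >= 0, length(intron_window) == 2,
            microexon_range[1] >= 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Simulate a study bundle and build a matching run configuration
#'
#' Convenience wrapper: generates the synthetic study under
#' `bundle_dir` and returns a [run_config()] pointing at its files.
#'
#' @param config a [simulation_config()].
#' @param bundle_dir where to write the bundle.
#' @param out_dir pipeline output directory.
#' @param ... further arguments to [run_config()].
#' @return a `run_config`.
#' @export
simulate_study <- function(config, bundle_dir, out_dir = "results", ...) {
  b <- generate_study(config, bundle_dir)
  run_config(
    annotation = b$paths$annotation, genome = b$paths$genome,
    junctions = b$paths$junctions, samples = b$paths$samples,
    vcf = b$paths$vcf, motifs = b$paths$motifs,
    gene_expr = b$paths$gene_expr, mirna_expr = b$paths$mirna_expr,
    mirnas = b$paths$mirnas, utr = b$paths$utr,
    targets = b$paths$targets, gwas = b$paths$gwas,
    orthologs = b$paths$orthologs, out_dir = out_dir,
    seed = config$seed, ...
  )
}

#' Run the full downstream splicing pipeline
#'
#' Executes, in order: event quantification (PSI, delta PSI, posterior,
#' filter), event typing, consequence annotation (region, frame, rescue
#' groups, frameshift test), microexon profiling, SNP positional
#' classification and enrichment, CpG-loss calls, motif enrichment and
#' SNP-motif effects, miRNA differential expression and target
#' prediction, and gene-level differential expression with the external
#' gene-list overlap. Writes one TSV per stage plus `manifest.json`
#' recording every output, its row count, skipped stages and the exact
#' configuration. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return invisible list of in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[!vapply(config, is.null, TRUE)],
                   outputs = list(), skipped = list())
  results <- list()
  note_output <- function(name, path, n) {
    manifest$outputs[[name]] <<- list(path = path, rows = n)
  }

  ann <- read_annotation(config$annotation)
  genome <- Biostrings::readDNAStringSet(config$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  counts <- read_junction_counts(config$junctions)
  groups <- utils::read.delim(config$samples)

  # --- splicing quantification ---------------------------------------------
  quant <- quantify_events(counts, groups,
                           n_draws = config$n_draws,
                           seed = stage_seed(config$seed, "probability"),
                           dpsi_cutoff = config$dpsi_cutoff,
                           prob_cutoff = config$prob_cutoff,
                           strong_cutoff = config$strong_cutoff)
  ev_path <- file.path(dirname(config$junctions), "events.tsv")
  events <- if (file.exists(ev_path)) {
    merge(utils::read.delim(ev_path), quant, by = "event_id")
  } else {
    quant
  }
  if (all(c("seg_start0", "seg_end0") %in% names(events))) {
    events$type <- vapply(seq_len(nrow(events)), function(i)
      classify_event_type(events[i, ], ann), character(1))
  }
  p <- file.path(config$out_dir, "events_quantified.tsv")
  write_tsv_strict(events, p)
  note_output("events", p, nrow(events))
  results$events <- events

  # --- consequences ---------------------------------------------------------
  if (all(c("seg_start0", "seg_end0", "type") %in% names(events))) {
    cons <- annotate_consequences(events, ann)
    null_rate <- random_skipping_null(ann)
    sig_ce <- cons[!is.na(cons$significant) & cons$significant &
                     cons$type == "CE" & cons$region == "CDS" &
                     !is.na(cons$frame), , drop = FALSE]
    n_pres <- sum(sig_ce$frame == "preserved")
    n_resc <- sum(sig_ce$frame == "rescue-group")
    n_shift <- sum(sig_ce$frame == "shift")
    summary <- list(
      frame = frame_summary(n_pres, n_shift, n_resc),
      null_shift_rate = null_rate,
      p_enrichment = if (n_pres + n_shift + n_resc > 0) {
        frameshift_enrichment_test(n_shift + n_resc,
                                   n_pres + n_shift + n_resc, null_rate)
      } else {
        NA_real_
      }
    )
    p <- file.path(config$out_dir, "consequences.tsv")
    write_tsv_strict(cons[, c("event_id", "gene_id", "type", "region",
                              "frame", "rescue_group_id")], p)
    note_output("consequences", p, nrow(cons))
    jsonlite::write_json(
      list(frame = summary$frame,
           null_shift_rate = summary$null_shift_rate,
           p_enrichment = summary$p_enrichment),
      file.path(config$out_dir, "frame_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    results$consequences <- cons
    results$frame_summary <- summary

    # --- microexons ---------------------------------------------------------
    micro <- detect_microexons(ann, config$microexon_range[1],
                               config$microexon_range[2])
    p <- file.path(config$out_dir, "microexons.tsv")
    write_tsv_strict(micro, p)
    note_output("microexons", p, nrow(micro))
    results$microexons <- micro
    if (!is.null(config$targets)) {
      targets <- read_target_exons(config$targets)
      ti <- summarize_target_inclusion(cons, targets)
      results$target_inclusion <- ti
      if (nrow(ti$events) > 0) {
        p <- file.path(config$out_dir, "target_inclusion.tsv")
        write_tsv_strict(ti$events[, c("event_id", "psi_g1", "psi_g2",
                                       "delta_psi", "skipped_in")], p)
        note_output("target_inclusion", p, nrow(ti$events))
      }
    } else {
      manifest$skipped$target_inclusion <- "no target list supplied"
    }
  } else {
    manifest$skipped$consequences <- "no event coordinates supplied"
  }

  # --- SNP context ----------------------------------------------------------
  have_coords <- all(c("seg_start0", "seg_end0") %in% names(events))
  if (!is.null(config$vcf) && file.exists(config$vcf) && have_coords) {
    snps <- read_vcf(config$vcf)
    cnt <- t(vapply(seq_len(nrow(events)), function(i)
      per_event_snp_counts(snps, events[i, ],
                           ss_window = config$ss_window,
                           intron_window = config$intron_window[2]),
      numeric(6)))
    snp_table <- cbind(events[, c("event_id", "gene_id")],
                       as.data.frame(cnt))
    p <- file.path(config$out_dir, "snp_counts.tsv")
    write_tsv_strict(snp_table, p)
    note_output("snp_counts", p, nrow(snp_table))
    results$snp_counts <- snp_table

    # enrichment of local density vs the genome-wide baseline
    win_len <- sum(vapply(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      2 * config$intron_window[2] + (ev$seg_end0 - ev$seg_start0)
    }, numeric(1)))
    n_near <- sum(snp_table$n_total)
    enr <- enrichment_chi2(n_near, win_len, nrow(snps),
                           sum(Biostrings::width(genome)))
    jsonlite::write_json(enr, file.path(config$out_dir,
                                        "snp_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    results$snp_enrichment <- enr

    ss_genes <- flag_splice_site_snp_genes(snps, events,
                                           ss_window = config$ss_window)
    p <- file.path(config$out_dir, "splice_site_snp_genes.tsv")
    write_tsv_strict(data.frame(gene_id = ss_genes), p)
    note_output("splice_site_snp_genes", p, length(ss_genes))
    results$ss_genes <- ss_genes

    cpg <- cpg_loss_per_gene(snps, events, genome,
                             intron_window = config$intron_window[2])
    p <- file.path(config$out_dir, "cpg_loss.tsv")
    write_tsv_strict(cpg, p)
    note_output("cpg_loss", p, nrow(cpg))
    results$cpg_loss <- cpg

    # --- motifs -------------------------------------------------------------
    if (!is.null(config$motifs)) {
      motifs <- read_motifs(config$motifs)
      sig <- !is.na(events$significant) & events$significant
      if (any(sig) && any(!sig)) {
        fg_up <- events[sig & events$delta_psi > 0, , drop = FALSE]
        fg_dn <- events[sig & events$delta_psi < 0, , drop = FALSE]
        bg <- events[!sig, , drop = FALSE]
        enrich <- list()
        if (nrow(fg_up) > 0) {
          e <- motif_enrichment_table(genome, motifs, fg_up, bg,
                                      config$flank_nt)
          e$direction <- "inclusion_up"
          enrich[[length(enrich) + 1]] <- e
        }
        if (nrow(fg_dn) > 0) {
          e <- motif_enrichment_table(genome, motifs, fg_dn, bg,
                                      config$flank_nt)
          e$direction <- "inclusion_down"
          enrich[[length(enrich) + 1]] <- e
        }
        if (length(enrich) > 0) {
          enrich <- do.call(rbind, enrich)
          p <- file.path(config$out_dir, "motif_enrichment.tsv")
          write_tsv_strict(enrich, p)
          note_output("motif_enrichment", p, nrow(enrich))
          results$motif_enrichment <- enrich
        }
      }
      aff <- count_affected_events(genome, events, snps, motifs,
                                   config$flank_nt)
      p <- file.path(config$out_dir, "motif_snp_effects.tsv")
      write_tsv_strict(aff$effects, p)
      note_output("motif_snp_effects", p, nrow(aff$effects))
      results$motif_effects <- aff
    } else {
      manifest$skipped$motifs <- "no motif file supplied"
    }
  } else {
    manifest$skipped$snps <-
      "no VCF (or no event coordinates): SNP and motif stages skipped"
  }

  # --- miRNA targeting ------------------------------------------------------
  if (!is.null(config$mirna_expr) && !is.null(config$mirnas) &&
      !is.null(config$utr)) {
    mex <- read_expression(config$mirna_expr, groups)
    diff_mir <- differential_mirnas(mex, alpha = config$alpha)
    p <- file.path(config$out_dir, "mirna_differential.tsv")
    write_tsv_strict(diff_mir, p)
    note_output("mirna_differential", p, nrow(diff_mir))
    seqs <- as.character(Biostrings::readDNAStringSet(config$mirnas))
    utr <- as.character(Biostrings::readDNAStringSet(config$utr))[[1]]
    cand <- candidate_regulators(diff_mir, seqs, utr,
                                 required_direction = 1)
    p <- file.path(config$out_dir, "mirna_candidates.tsv")
    write_tsv_strict(cand, p)
    note_output("mirna_candidates", p, nrow(cand))
    results$mirna <- list(differential = diff_mir, candidates = cand)
  } else {
    manifest$skipped$mirna <- "miRNA inputs missing"
  }

  # --- gene-level differential expression ----------------------------------
  if (!is.null(config$gene_expr)) {
    gex <- read_expression(config$gene_expr, groups)
    de <- differential_expression(gex, alpha = config$alpha)
    p <- file.path(config$out_dir, "gene_differential.tsv")
    write_tsv_strict(de, p)
    note_output("gene_differential", p, nrow(de))
    results$diffexp <- de
    if (!is.null(config$gwas) && !is.null(config$orthologs) &&
        "gene_id" %in% names(events)) {
      spliced <- unique(events$gene_id[!is.na(events$significant) &
                                         events$significant])
      overlap <- intersect_gene_lists(spliced,
                                      read_gene_list(config$gwas),
                                      read_ortholog_map(config$orthologs))
      p <- file.path(config$out_dir, "external_gene_overlap.tsv")
      write_tsv_strict(overlap, p)
      note_output("external_gene_overlap", p, nrow(overlap))
      results$gene_overlap <- overlap
    }
  } else {
    manifest$skipped$diffexp <- "no expression matrix supplied"
  }

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  results$manifest <- manifest
  invisible(results)
}
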