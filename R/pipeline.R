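#' Build a pipeline configuration
#'
#' Thresholds default to the values the analysis is defined with: at least 5
#' codons of novel CDS and 3 carriers for the occupancy analysis, autosomes
#' only, the 50-nt NMD rule, footprint lengths 26-32 nt with P-site offsets
#' 11/12, a 15-nt concatenation threshold, and a +/-10 codon metagene
#' window. All of them can be overridden.
#'
#' @param dir directory holding the standard input layout (as written by
#'   [make_fixture()]): species FASTAs, `human.gff3`, `chimpanzee.gff3`,
#'   `population.vcf`, `human_<species>.maf`, `blacklist.bed` and one SAM
#'   per sample under `ribo/`.
#' @param out_dir where stage outputs are written.
#' @param human_samples,chimp_samples sample names; default: every SAM whose
#'   name starts with `CHIMP` is a chimpanzee sample, the rest are human.
#' @param min_codons,min_carriers,nmd_distance,concat_min_len,window
#'   analysis thresholds (see description).
#' @param stages character subset of
#'   `c("startgain", "species", "riboprofile", "codon_evolution")`.
#' @param seed stored in the manifest; the pipeline itself is deterministic.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(dir, out_dir = file.path(dir, "out"),
                            human_samples = NULL, chimp_samples = NULL,
                            min_codons = 5L, min_carriers = 3L,
                            nmd_distance = 50L, concat_min_len = 15L,
                            window = 10L,
                            stages = c("startgain", "species", "riboprofile",
                                       "codon_evolution"),
                            seed = 1L) {
  sams <- list.files(file.path(dir, "ribo"), pattern = "\\.sam$",
                     full.names = TRUE)
  nm <- sub("\\.sam$", "", basename(sams))
  if (is.null(chimp_samples)) chimp_samples <- nm[startsWith(nm, "CHIMP")]
  if (is.null(human_samples)) human_samples <- setdiff(nm, chimp_samples)
  structure(list(
    paths = list(
      fasta_human = file.path(dir, "human.fa"),
      fasta_chimp = file.path(dir, "chimpanzee.fa"),
      fasta_gorilla = file.path(dir, "gorilla.fa"),
      fasta_orangutan = file.path(dir, "orangutan.fa"),
      gff_human = file.path(dir, "human.gff3"),
      gff_chimp = file.path(dir, "chimpanzee.gff3"),
      vcf = file.path(dir, "population.vcf"),
      maf_chimp = file.path(dir, "human_chimpanzee.maf"),
      maf_gorilla = file.path(dir, "human_gorilla.maf"),
      maf_orangutan = file.path(dir, "human_orangutan.maf"),
      blacklist = file.path(dir, "blacklist.bed"),
      sam = stats::setNames(file.path(dir, "ribo", paste0(nm, ".sam")), nm),
      out_dir = out_dir),
    human_samples = human_samples, chimp_samples = chimp_samples,
    min_codons = as.integer(min_codons),
    min_carriers = as.integer(min_carriers),
    nmd_distance = as.integer(nmd_distance),
    concat_min_len = as.integer(concat_min_len),
    window = as.integer(window), stages = stages,
    seed = as.integer(seed)), class = "run_config")
}

#' Run the full novel-start-codon analysis
#'
#' Executes the enabled stages in order — start-gain SNV discovery,
#' species-specific start-codon discovery, ribosome occupancy, codon branch
#' models — writing per-stage tables, a JSON report and a manifest (seed,
#' parameter values, md5 of every output) under `config$paths$out_dir`.
#' Stage input/output counts are narrated via `message()`.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @return the report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  p <- config$paths
  dir.create(p$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)
  genome_h <- read_fasta(p$fasta_human, "human")
  tx_h <- read_gff3(p$gff_human)
  snvs <- read_vcf(p$vcf)

  calls <- NULL
  if ("startgain" %in% config$stages) {
    message("startgain: ", nrow(snvs$sites), " biallelic SNVs in")
    calls <- call_start_gains(snvs, tx_h, genome_h)
    snv_level <- calls[!duplicated(calls$variant_id), , drop = FALSE]
    kept <- filter_for_occupancy(calls, config$min_codons,
                                 config$min_carriers)
    message("startgain: ", nrow(snv_level), " start-gain SNVs, ",
            nrow(kept[!duplicated(kept$variant_id), ]),
            " kept for occupancy analysis")
    summ <- population_summary(calls, snvs)
    nmd <- do.call(rbind, lapply(unique(calls$transcript_id), function(tid)
      as.data.frame(nmd_classify(tx_h[[tid]], config$nmd_distance))))
    write_tsv(calls, file.path(p$out_dir, "startgain_calls.tsv"))
    if (nrow(calls)) {
      bed <- data.frame(contig = calls$contig,
                        start = pmin(calls$novel_start_g,
                                     calls$novel_start_g +
                                       ifelse(calls$strand == "+", 2L, -2L)),
                        end = pmax(calls$novel_start_g,
                                   calls$novel_start_g +
                                     ifelse(calls$strand == "+", 2L, -2L)),
                        name = paste0(calls$variant_id, "|",
                                      calls$transcript_id),
                        score = 0, strand = calls$strand)
      write_bed(bed, file.path(p$out_dir, "startgain_calls.bed"))
    }
    write_tsv(summ$per_individual,
              file.path(p$out_dir, "startgain_burden.tsv"))
    if (!is.null(nmd)) write_tsv(nmd, file.path(p$out_dir, "startgain_nmd.tsv"))
    report$startgain <- list(
      n_snvs_in = nrow(snvs$sites),
      n_indels_skipped = snvs$n_skipped_indels,
      n_calls = nrow(snv_level),
      n_kept_occupancy = nrow(kept[!duplicated(kept$variant_id), ]),
      af_range = if (nrow(snv_level)) range(snv_level$allele_frequency)
                 else c(NA, NA),
      mean_carried_per_individual = mean(summ$per_individual$n_carried),
      median_novel_cds_nt = if (nrow(snv_level))
        stats::median(snv_level$novel_cds_len_nt) else NA,
      n_nmd_predicted = if (!is.null(nmd)) sum(nmd$nmd_predicted) else 0L)
    calls_kept <- kept
  }

  hss_calls <- NULL; panel <- NULL
  if ("species" %in% config$stages) {
    genome_c <- read_fasta(p$fasta_chimp, "chimpanzee")
    genome_g <- read_fasta(p$fasta_gorilla, "gorilla")
    genome_o <- read_fasta(p$fasta_orangutan, "orangutan")
    tx_c <- read_gff3(p$gff_chimp)
    bc <- read_maf(p$maf_chimp); bg <- read_maf(p$maf_gorilla)
    bo <- read_maf(p$maf_orangutan)
    n_in <- c(length(bc), length(bg), length(bo))
    bc <- filter_one_to_one(bc); bg <- filter_one_to_one(bg)
    bo <- filter_one_to_one(bo)
    message("species: one-to-one blocks ", n_in[1], " -> ", length(bc),
            " (chimp), ", n_in[2], " -> ", length(bg), " (gorilla), ",
            n_in[3], " -> ", length(bo), " (orangutan)")
    lk_c <- ortholog_lookup(bc)
    lk_g <- ortholog_lookup(bg)
    lk_o <- ortholog_lookup(bo)
    sites <- find_divergent_sites(bc, genome_h, genome_c)
    sites <- annotate_outgroups(sites, lk_g, lk_o)
    res <- call_species_starts(sites, tx_h, tx_c, lk_c, snvs)
    hss_calls <- lapply(res$calls, flag_cug_origin,
                        human_transcripts = tx_h, chimp_lookup = lk_c)
    message("species: ", nrow(sites), " divergent sites -> ",
            length(hss_calls), " fixed species-specific start codons (",
            nrow(res$rejected), " candidates rejected)")
    panel <- hssc_site_panel(hss_calls, tx_h, tx_c, lk_c, config$min_codons)
    tb <- hss_calls_table(hss_calls)
    write_tsv(tb, file.path(p$out_dir, "hss_calls.tsv"))
    write_tsv(res$rejected, file.path(p$out_dir, "hss_rejected.tsv"))
    write_tsv(panel, file.path(p$out_dir, "hss_anchor_panel.tsv"))
    n_analyzable <- sum(panel$analyzable[panel$anchor_class == "hSSC"])
    n_cug <- sum(tb$cug_origin, na.rm = TRUE)
    report$species <- list(
      n_divergent_sites = nrow(sites), n_calls = length(hss_calls),
      n_rejected = nrow(res$rejected),
      rejection_reasons = as.list(table(res$rejected$reason)),
      n_analyzable = n_analyzable, n_cug_origin = n_cug,
      n_analyzable_non_cug = sum(panel$analyzable & !panel$cug_origin &
                                   panel$anchor_class == "hSSC"),
      median_novel_cds_nt = stats::median(tb$novel_cds_len_nt, na.rm = TRUE))
    stage_env <- list(tx_c = tx_c, lk_c = lk_c, lk_g = lk_g,
                      genome_c = genome_c)
  }

  if ("riboprofile" %in% config$stages) {
    blacklist <- read_bed(p$blacklist)
    load_tracks <- function(samples, bl) {
      lapply(stats::setNames(samples, samples), function(s) {
        rd <- read_sam(p$sam[[s]], s, blacklist = bl)
        flt <- filter_reads(rd)
        message("riboprofile: ", s, " ", nrow(rd), " reads -> ",
                nrow(flt), " retained")
        build_rpm_track(flt, s)
      })
    }
    tracks_h <- load_tracks(config$human_samples, blacklist)
    report$riboprofile <- list()
    if (!is.null(calls)) {
      kept_snv <- calls_kept[!duplicated(calls_kept$variant_id), ,
                             drop = FALSE]
      if (nrow(kept_snv)) {
        anchors <- data.frame(anchor_id = kept_snv$variant_id,
                              transcript_id = kept_snv$transcript_id,
                              tpos = kept_snv$novel_start_tpos)
        groups <- do.call(rbind, lapply(seq_len(nrow(kept_snv)), function(i) {
          carr <- strsplit(kept_snv$carriers[i], ",", fixed = TRUE)[[1]]
          data.frame(sample_id = config$human_samples,
                     anchor_id = kept_snv$variant_id[i],
                     group = ifelse(config$human_samples %in% carr,
                                    "carrier", "noncarrier"))
        }))
        prof <- metagene(tracks_h, anchors, tx_h, groups, config$window)
        write_tsv(prof, file.path(p$out_dir, "metagene_startgain.tsv"))
        occ <- merge(occupancy_table(tracks_h, anchors, tx_h, 0L), groups)
        cmp <- compare_anchor_classes(occ$rpm[occ$group == "carrier"],
                                      occ$rpm[occ$group == "noncarrier"],
                                      paired = FALSE)
        report$riboprofile$carrier_vs_noncarrier <-
          cmp[c("statistic", "p_value", "fold_ratio", "n", "method")]
      }
    }
    if (!is.null(panel) && nrow(panel)) {
      tracks_c <- load_tracks(config$chimp_samples, NULL)
      pan <- panel[panel$analyzable & !is.na(panel$tpos), , drop = FALSE]
      paired_cmp <- function(pan, class_a, class_b, tracks, txs) {
        pa <- pan[pan$anchor_class == class_a, ]
        pb <- pan[pan$anchor_class == class_b, ]
        shared <- intersect(pa$call_id, pb$call_id)
        pa <- pa[match(shared, pa$call_id), ]
        pb <- pb[match(shared, pb$call_id), ]
        oa <- occupancy_table(tracks, data.frame(
          anchor_id = pa$call_id, transcript_id = pa$transcript_id,
          tpos = pa$tpos), txs, 0L)
        ob <- occupancy_table(tracks, data.frame(
          anchor_id = pb$call_id, transcript_id = pb$transcript_id,
          tpos = pb$tpos), txs, 0L)
        key <- paste(oa$sample_id, oa$anchor_id)
        m <- match(key, paste(ob$sample_id, ob$anchor_id))
        compare_anchor_classes(oa$rpm, ob$rpm[m], paired = TRUE)
      }
      hum_prof_anchors <- pan[pan$species == "human", ]
      chi_prof_anchors <- pan[pan$species == "chimpanzee", ]
      prof_h <- metagene(tracks_h,
        data.frame(anchor_id = hum_prof_anchors$anchor_id,
                   transcript_id = hum_prof_anchors$transcript_id,
                   tpos = hum_prof_anchors$tpos),
        tx_h,
        do.call(rbind, lapply(config$human_samples, function(s)
          data.frame(sample_id = s, anchor_id = hum_prof_anchors$anchor_id,
                     group = hum_prof_anchors$anchor_class))),
        config$window)
      prof_c <- metagene(tracks_c,
        data.frame(anchor_id = chi_prof_anchors$anchor_id,
                   transcript_id = chi_prof_anchors$transcript_id,
                   tpos = chi_prof_anchors$tpos),
        stage_env$tx_c,
        do.call(rbind, lapply(config$chimp_samples, function(s)
          data.frame(sample_id = s, anchor_id = chi_prof_anchors$anchor_id,
                     group = chi_prof_anchors$anchor_class))),
        config$window)
      write_tsv(rbind(prof_h, prof_c),
                file.path(p$out_dir, "metagene_species.tsv"))
      for (mode in c("all", "non_cug")) {
        pp <- if (mode == "all") pan else
          pan[!is.na(pan$cug_origin) & !pan$cug_origin, , drop = FALSE]
        r <- list(
          hssc_vs_hasc = paired_cmp(pp, "hSSC", "hASC", tracks_h, tx_h),
          cosc_vs_csc = paired_cmp(pp, "cOSC", "cSC", tracks_c,
                                   stage_env$tx_c))
        report$riboprofile[[paste0("species_", mode)]] <- lapply(r, function(x)
          x[c("statistic", "p_value", "fold_ratio", "n", "method")])
      }
    }
  }

  if ("codon_evolution" %in% config$stages && !is.null(hss_calls)) {
    genome_hc <- genome_h
    alns <- list()
    for (cl in hss_calls) {
      a <- extract_novel_cds_alignment(cl, tx_h[[cl$transcript_id]],
                                       genome_hc, stage_env$lk_c,
                                       stage_env$lk_g)
      if (!is.null(a)) alns[[length(alns) + 1L]] <- a
    }
    concat <- concatenate_alignments(alns, config$concat_min_len)
    message("codon_evolution: ", length(alns), " novel-CDS alignments, ",
            length(concat$source_cds_ids), " longer than ",
            config$concat_min_len, " nt concatenated to ", concat$n_codons,
            " codons")
    fits <- list(null = fit_codon_model(concat, "none"))
    for (fg in c("human", "chimpanzee", "gorilla"))
      fits[[fg]] <- fit_codon_model(concat, fg)
    lrts <- lapply(fits[c("human", "chimpanzee", "gorilla")],
                   function(f) codon_lrt(fits$null, f))
    report$codon_evolution <- list(
      n_alignments = length(alns),
      n_concatenated = length(concat$source_cds_ids),
      n_codons = concat$n_codons,
      omega_single = fits$null$omega0,
      kappa = fits$null$kappa,
      models = lapply(fits, function(f) list(
        foreground = f$foreground, log_likelihood = f$log_likelihood,
        kappa = f$kappa, omega0 = f$omega0, omega1 = f$omega1)),
      lrt = lapply(lrts, function(l) list(statistic = l$statistic,
                                          df = l$df, p_value = l$p_value)))
    jsonlite::write_json(report$codon_evolution,
                         file.path(p$out_dir, "kaks_fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  jsonlite::write_json(report, file.path(p$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  outputs <- setdiff(list.files(p$out_dir, full.names = TRUE),
                     file.path(p$out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("startscan")),
    seed = config$seed,
    parameters = config[c("min_codons", "min_carriers", "nmd_distance",
                          "concat_min_len", "window", "stages")],
    outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(p$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @rdname run_pipeline
#' @export
run_all <- run_pipeline
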