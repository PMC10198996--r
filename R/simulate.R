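#' Default fixture configuration
#'
#' The configuration is the set of study conditions the generator emulates at
#' toy scale: a population of diploid individuals genotyped at planted
#' start-gain SNVs (true events plus distractors of every rejection class), a
#' four-species comparative panel with planted fixed species-specific start
#' codons (including two CUG-origin codons among the analyzable ones, and
#' distractors of every rejection class), ribosome-profiling samples with a
#' four-fold start-codon peak over an elongation background with 3-nt
#' periodicity, and novel coding sequences evolved under branch-specific
#' omega values (purifying on the human branch, relaxed elsewhere).
#'
#' @param seed integer seed controlling every random choice of the fixture.
#' @param n_individuals population size in the VCF (default 40).
#' @param n_human_ribo,n_chimp_ribo ribosome-profiling sample counts; the
#'   human samples are the first individuals of the population.
#' @param reads_per_sample signal footprints simulated per sample.
#' @param peak_fold fold enrichment of P-site density at active start codons
#'   over the elongation background (default 4).
#' @param cug_residual_fold residual initiation at chimp CUG orthologs of
#'   CUG-origin codons (default 2).
#' @param periodicity probability mass of a codon's P-site signal on its
#'   first nucleotide; the remainder splits evenly between the preceding
#'   base (cleavage slop) and the second base (default 0.8).
#' @param kaks_tree,kaks_kappa,kaks_omega_human,kaks_omega_background
#'   branch lengths (expected substitutions per codon) and codon-model
#'   parameters used to evolve the planted novel CDSs.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_individuals = 40L,
                           n_human_ribo = 8L, n_chimp_ribo = 5L,
                           reads_per_sample = 30000L, peak_fold = 4,
                           cug_residual_fold = 2, periodicity = 0.8,
                           kaks_tree = c(human = 0.06, chimpanzee = 0.06,
                                         gorilla = 0.08),
                           kaks_kappa = 2, kaks_omega_human = 0.36,
                           kaks_omega_background = 2.74) {
  stopifnot(peak_fold >= 1, periodicity > 0, periodicity < 1,
            n_human_ribo <= n_individuals)
  # start-gain SNV plan: 5 true events and >=3 distractors per rejection
  # class (out-of-frame AUG, stop-interrupted, inside a CDS, no AUG created)
  sg <- data.frame(
    id      = c("T1","T2","T3","T4","T5",
                "F1","F2","F3", "S1","S2","S3",
                "C1","C2","C3", "N1","N2","N3"),
    class   = c(rep("true", 5), rep("frame", 3), rep("stop", 3),
                rep("cds", 3), rep("noatg", 3)),
    codons  = c(3L,16L,10L,16L,8L, 6L,9L,7L, 6L,8L,10L, 7L,9L,11L, 6L,6L,6L),
    contig  = c("chr1","chr1","chrX","chr1","chr2",
                "chr1","chr2","chr1", "chr2","chr1","chr2",
                "chr1","chr1","chr1", "chr2","chr1","chr2"),
    strand  = c("+","-","+","+","-", "+","-","+", "+","+","-",
                "+","+","+", "+","-","+"),
    ref_triplet = c("ACG","ATA","GTG","ACG","TTG", "ACG","ATA","ACG",
                    "ACG","GTG","ATA", "ACG","ACG","ATA", NA,NA,NA),
    n_ribo_carriers  = c(3L,2L,4L,4L,3L, 2L,2L,2L, 2L,2L,2L,
                         2L,2L,2L, 2L,2L,2L),
    n_extra_carriers = c(2L,0L,2L,0L,0L, 1L,1L,1L, 1L,1L,1L,
                         1L,1L,1L, 1L,1L,1L),
    stringsAsFactors = FALSE)
  # species-level plan: 26 true fixed start codons (16 analyzable with >= 5
  # codons of novel CDS, 2 of them CUG-origin), plus 2 distractors per
  # rejection class; novel-CDS lengths give a 30-nt median as in real
  # N-terminal extensions
  len_analyzable <- c(15L,27L,30L,30L,33L,36L,45L,48L,60L,75L,90L,102L,
                      120L,150L,168L,186L)
  len_short <- c(3L,6L,9L,12L,12L,9L,6L,3L,12L,9L)
  trip_pool <- c("CTG","GTG","ACG","CTG","GCG","ATA","TTG","ATC","AAG",
                 "GTG","ACG","ATA","TTG","ATC","AAG","GTG")
  hss <- data.frame(
    id = c(sprintf("H%02d", 1:26), "HP1","HP2","HO1","HO2","HU1","HU2",
           "HG1","HG2"),
    class = c(rep("true", 26), "polymorphic","polymorphic",
              "outgroup_shared","outgroup_shared",
              "chimp_not_5utr","chimp_not_5utr",
              "gap_broken","gap_broken"),
    L_nt = c(len_analyzable, len_short, rep(30L, 8)),
    chimp_triplet = c(trip_pool,
                      c("GTG","ACG","ATA","TTG","ATC","AAG","GTG","ACG","ATA",
                        "TTG"),
                      c("GTG","ACG", "GTG","GTG", "GTG","ACG", "GTG","ACG")),
    strand = rep(c("+","-","+"), length.out = 34L),
    contig = rep(c("chr1","chr2"), length.out = 34L),
    monomorphic_vcf = FALSE, inverted = FALSE,
    gorilla_stop = FALSE, gorilla_del = FALSE,
    stringsAsFactors = FALSE)
  hss$monomorphic_vcf[c(3, 11)] <- TRUE
  hss$inverted[5] <- TRUE
  hss$gorilla_stop[7] <- TRUE
  hss$gorilla_del[9] <- TRUE
  structure(list(
    seed = as.integer(seed), n_individuals = as.integer(n_individuals),
    n_human_ribo = as.integer(n_human_ribo),
    n_chimp_ribo = as.integer(n_chimp_ribo),
    reads_per_sample = as.integer(reads_per_sample),
    peak_fold = peak_fold, cug_residual_fold = cug_residual_fold,
    periodicity = periodicity, read_lengths = 26:32,
    distractor_reads = c(multi = 150L, short = 100L, long = 100L,
                         blacklist = 150L),
    kaks_tree = kaks_tree, kaks_kappa = kaks_kappa,
    kaks_omega_human = kaks_omega_human,
    kaks_omega_background = kaks_omega_background,
    sg_events = sg, hss_events = hss), class = "fixture_config")
}

# ---- sequence helpers -------------------------------------------------------

BAD_TRIPLES <- c("ATG", "TAA", "TAG", "TGA")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# random sequence with no ATG and no stop codon in any frame
rand_clean <- function(n) {
  ch <- character(n)
  for (i in seq_len(n)) {
    repeat {
      b <- sample(c("A", "C", "G", "T"), 1)
      if (i >= 3 && paste0(ch[i - 2], ch[i - 1], b) %in% BAD_TRIPLES) next
      ch[i] <- b; break
    }
  }
  paste(ch, collapse = "")
}

# random sense (non-stop) codons
rand_codons <- function(n) {
  tab <- codon_tables()
  paste(sample(tab$codons, n, TRUE), collapse = "")
}

# ---- transcript assembly ----------------------------------------------------

# Assemble a transcript-oriented locus from utr5/cds/utr3 plus introns
# (introns: list of list(after = tpos, seq = )). Returns the oriented locus
# sequence, oriented exon intervals, and a tpos -> oriented-position mapper.
assemble_tx <- function(utr5, cds, utr3, introns = list()) {
  tx_seq <- paste0(utr5, cds, utr3)
  L <- nchar(tx_seq)
  if (length(introns)) {
    af <- vapply(introns, `[[`, 0, "after")
    sq <- vapply(introns, `[[`, "", "seq")
    o <- order(af); af <- af[o]; sq <- sq[o]
    stopifnot(all(af >= 1 & af < L))
  } else { af <- integer(); sq <- character() }
  bounds <- c(0L, af, L)
  pieces <- character(); exons <- list(); cur <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    seg <- substring(tx_seq, bounds[k] + 1L, bounds[k + 1L])
    pieces <- c(pieces, seg)
    exons[[k]] <- c(cur + 1L, cur + nchar(seg))
    cur <- cur + nchar(seg)
    if (k <= length(sq)) { pieces <- c(pieces, sq[k]); cur <- cur + nchar(sq[k]) }
  }
  oseq <- paste(pieces, collapse = "")
  t2o <- function(t) {
    off <- vapply(t, function(tt) sum(nchar(sq)[af < tt]), 0)
    as.integer(t + off)
  }
  list(tx_seq = tx_seq, oseq = oseq,
       exons_o = do.call(rbind, exons), t2o = t2o, tx_len = L)
}

flip_point <- function(p, len) len - p + 1L
flip_interval <- function(se, len) c(len - se[2] + 1L, len - se[1] + 1L)

# ---- the fixture builder ----------------------------------------------------

#' Generate the complete synthetic fixture
#'
#' Writes every input the pipeline consumes — four species genomes (FASTA),
#' human and chimpanzee annotations (GFF3), a population VCF, three pairwise
#' MAFs, one SAM per ribosome-profiling sample and a non-coding-RNA blacklist
#' BED — together with a machine-readable truth set. Deterministic given
#' `config$seed`.
#'
#' @param config a `fixture_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `paths`, `truth`, in-memory `genomes`,
#'   `transcripts_human`, `transcripts_chimp`, and the `ribo` simulation
#'   spec.
#' @export
make_fixture <- function(config = fixture_config(), out_dir = tempfile("fx")) {
  if (any(config$sg_events$codons < 1L))
    stop("fixture config error: novel-CDS codon gap must be >= 1")
  if (any(config$hss_events$L_nt < 3L | config$hss_events$L_nt %% 3L != 0L))
    stop("fixture config error: novel-CDS lengths must be positive multiples of 3")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  species <- c("human", "chimpanzee", "gorilla", "orangutan")
  contigs <- c("chr1", "chr2", "chrX")
  gparts <- lapply(species, function(s)
    lapply(stats::setNames(contigs, contigs), function(c) list()))
  names(gparts) <- species
  gcur <- lapply(species, function(s)
    stats::setNames(rep(0L, length(contigs)), contigs))
  names(gcur) <- species
  maf <- list(chimpanzee = list(), gorilla = list(), orangutan = list())
  tx_h <- list(); tx_c <- list()
  vcf_rows <- list()
  truth_sg <- list(); truth_hss <- list()
  grid_h <- list(); grid_c <- list()
  anchors_h <- list(); anchors_c <- list()
  individuals <- sprintf("IND%02d", seq_len(config$n_individuals))
  ribo_h <- individuals[seq_len(config$n_human_ribo)]
  ribo_c <- sprintf("CHIMP%d", seq_len(config$n_chimp_ribo))

  append_seq <- function(sp, ctg, seq) {
    i <- length(gparts[[sp]][[ctg]]) + 1L
    gparts[[sp]][[ctg]][[i]] <<- seq
    start <- gcur[[sp]][[ctg]] + 1L
    gcur[[sp]][[ctg]] <<- gcur[[sp]][[ctg]] + nchar(seq)
    start
  }
  add_spacer <- function(ctg, n = 80L) {
    sp_seq <- rand_dna(n)
    for (sp in species) append_seq(sp, ctg, sp_seq)
    invisible(NULL)
  }
  add_maf_block <- function(qspecies, ctg, h_aln, q_aln, h0, q0, q_strand) {
    hlen <- nchar(gsub("-", "", h_aln, fixed = TRUE))
    qlen <- nchar(gsub("-", "", q_aln, fixed = TRUE))
    maf[[qspecies]][[length(maf[[qspecies]]) + 1L]] <<- list(
      target = list(species = "human", contig = ctg, start = h0,
                    end = h0 + hlen - 1L, strand = "+", size = hlen,
                    aln = h_aln),
      query = list(species = qspecies, contig = ctg, start = q0,
                   end = q0 + qlen - 1L, strand = q_strand, size = qlen,
                   aln = q_aln),
      block_id = paste0(qspecies, "_", length(maf[[qspecies]]) + 1L))
  }
  genotype_row <- function(carrier_ids, hom_ids = character(),
                           missing_ids = character()) {
    gt <- rep("0|0", config$n_individuals)
    gt[match(carrier_ids, individuals)] <- "0|1"
    gt[match(hom_ids, individuals)] <- "1|1"
    gt[match(missing_ids, individuals)] <- ".|."
    gt
  }
  add_vcf <- function(ctg, pos, ref, alt, gt, id) {
    vcf_rows[[length(vcf_rows) + 1L]] <<- list(
      contig = ctg, pos = pos, id = id, ref = ref, alt = alt, gt = gt)
  }

  # ---------------- start-gain loci ----------------
  sg <- config$sg_events
  sg_single <- setdiff(sg$id, c("C1", "C2", "C3"))
  next_ind <- config$n_human_ribo  # extra (non-ribo) carriers drawn from here
  plant_sg <- function(ev, utr, p_t, alt_t, s_call, tx) {
    # genotype plan
    rc <- ribo_h[sample.int(config$n_human_ribo,
                            min(ev$n_ribo_carriers, config$n_human_ribo))]
    extra <- character(0)
    if (ev$n_extra_carriers > 0) {
      extra <- individuals[next_ind + seq_len(ev$n_extra_carriers)]
      next_ind <<- next_ind + ev$n_extra_carriers
    }
    carriers <- c(rc, extra)
    hom <- if (ev$id == "T1") carriers[1] else character(0)
    missing <- if (ev$id == "T1") individuals[config$n_individuals] else character(0)
    g <- tx_to_genome(tx, p_t)
    ref_t <- substring(utr, p_t, p_t)
    stopifnot(ref_t != alt_t)
    ref_f <- if (tx$strand == "+") ref_t else complement_base(ref_t)
    alt_f <- if (tx$strand == "+") alt_t else complement_base(alt_t)
    add_vcf(ev$contig, g, ref_f, alt_f, genotype_row(carriers, hom, missing),
            ev$id)
    called <- 2L * (config$n_individuals - length(missing))
    af <- (length(carriers) + 2L * length(hom) - length(hom)) / called
    truth_sg[[ev$id]] <<- list(
      id = ev$id, class = ev$class, transcript_id = tx$transcript_id,
      contig = ev$contig, pos = g, variant_pos_t = p_t,
      expect_call = ev$class == "true",
      novel_start_tpos = if (ev$class == "true") s_call else NA,
      novel_cds_len_nt = 3L * ev$codons,
      novel_cds_len_codons = ev$codons,
      n_carriers = length(carriers),
      carriers = carriers, allele_frequency = af,
      autosomal = ev$contig != "chrX",
      kept_by_occupancy_filter = ev$class == "true" && ev$codons >= 5L &&
        length(carriers) >= 3L && ev$contig != "chrX")
    list(carriers_ribo = rc)
  }

  sg_var_pos <- c(ACG = 2L, ATA = 3L, GTG = 1L, TTG = 1L)
  for (r in which(sg$id %in% sg_single)) {
    ev <- as.list(sg[r, ])
    ev$var_pos <- if (!is.na(ev$ref_triplet)) sg_var_pos[[ev$ref_triplet]]
                  else NA_integer_
    gcod <- ev$codons
    U <- 3L * gcod + 36L
    s <- U - 3L * gcod - 2L
    repeat {
      utr <- rand_clean(U)
      if (ev$class %in% c("true", "stop")) {
        substr(utr, s, s + 2L) <- ev$ref_triplet
        if (ev$class == "stop") substr(utr, s + 3L, s + 5L) <- "TAA"
        p_t <- s + ev$var_pos - 1L; alt_t <- substring("ATG", ev$var_pos, ev$var_pos)
      } else if (ev$class == "frame") {
        s_f <- s - 1L
        substr(utr, s_f, s_f + 2L) <- ev$ref_triplet
        p_t <- s_f + ev$var_pos - 1L; alt_t <- substring("ATG", ev$var_pos, ev$var_pos)
      } else { # noatg
        if (ev$id == "N2") {           # destroy a reference out-of-frame ATG
          s_f <- s - 1L
          substr(utr, s_f, s_f + 2L) <- "ATG"
          p_t <- s_f; alt_t <- "G"
        } else {
          p_t <- 10L
          ref_here <- substring(utr, p_t, p_t)
          alt_t <- setdiff(c("A", "C", "G", "T"), ref_here)[1]
        }
      }
      # validate the plant: exactly the intended windows create ATG
      mut <- utr; substr(mut, p_t, p_t) <- alt_t
      cstart <- U + 1L
      okay <- TRUE
      for (w in max(1L, p_t - 2L):p_t) {
        if (w + 2L > U) next
        refw <- substring(utr, w, w + 2L); mutw <- substring(mut, w, w + 2L)
        creates <- mutw == "ATG" && refw != "ATG"
        inframe <- (cstart - w) %% 3L == 0L
        want <- switch(ev$class,
          true = , stop = (w == s), frame = FALSE, noatg = FALSE, cds = FALSE)
        if (inframe && creates != want) okay <- FALSE
        if (ev$class == "frame" && w == s - 1L && !creates) okay <- FALSE
        if (ev$class == "noatg" && creates) okay <- FALSE
      }
      if (substring(utr, p_t, p_t) == alt_t) okay <- FALSE
      if (okay) break
    }
    n_body <- 20L
    cds <- paste0("ATG", rand_codons(n_body), "TAA")
    if (ev$id == "T2") {
      utr3 <- paste0(rand_dna(60L), rand_dna(40L))
      introns <- list(list(after = U + nchar(cds) + 60L, seq = rand_dna(70L)))
    } else if (r %% 2L == 0L) {
      utr3 <- rand_dna(25L)
      introns <- list(list(after = U + 30L, seq = rand_dna(70L)))
    } else {
      utr3 <- rand_dna(25L); introns <- list()
    }
    asm <- assemble_tx(utr, cds, utr3, introns)
    len <- nchar(asm$oseq)
    fseq <- if (ev$strand == "+") asm$oseq else revcomp(asm$oseq)
    add_spacer(ev$contig)
    h0 <- append_seq("human", ev$contig, fseq)
    for (sp in setdiff(species, "human")) append_seq(sp, ev$contig, fseq)
    to_fwd_pt <- function(o) if (ev$strand == "+") o else flip_point(o, len)
    exf <- t(apply(asm$exons_o, 1, function(se)
      if (ev$strand == "+") se else flip_interval(se, len)))
    tid <- paste0("SG_", ev$id)
    tx <- transcript_model(tid, paste0("G_", tid), ev$contig, ev$strand,
      data.frame(start = h0 - 1L + exf[, 1], end = h0 - 1L + exf[, 2]),
      cds_start_g = h0 - 1L + to_fwd_pt(asm$t2o(U + 1L)),
      cds_end_g = h0 - 1L + to_fwd_pt(asm$t2o(U + nchar(cds))))
    tx_h[[tid]] <- tx
    # aligned MAF blocks (no divergence at these loci)
    for (sp in c("chimpanzee", "gorilla", "orangutan"))
      add_maf_block(sp, ev$contig, fseq, fseq, h0,
                    gcur[[sp]][[ev$contig]] - nchar(fseq) + 1L, "+")
    plant <- plant_sg(ev, utr, p_t, alt_t, s, tx)
    # grid and anchors
    gs <- if (ev$class == "true") s else U + 1L
    grid_h[[tid]] <- data.frame(
      transcript_id = tid,
      tpos = seq.int(gs, cds_end_tpos(tx) - 2L, by = 3L))
    anchors_h[[length(anchors_h) + 1L]] <- data.frame(
      transcript_id = tid, tpos = cds_start_tpos(tx),
      fold = config$peak_fold, samples = "ALL", stringsAsFactors = FALSE)
    if (ev$class == "true")
      anchors_h[[length(anchors_h) + 1L]] <- data.frame(
        transcript_id = tid, tpos = s, fold = config$peak_fold,
        samples = paste(plant$carriers_ribo, collapse = ","),
        stringsAsFactors = FALSE)
  }

  # shared locus for the in-CDS rejection class: isoform A has a long 5'UTR,
  # isoform B's (annotation-level) CDS covers it
  {
    U <- 3L * 11L + 36L
    cds <- paste0("ATG", rand_codons(20L), "TAA")
    utr3 <- rand_dna(25L)
    evs <- sg[sg$id %in% c("C1", "C2", "C3"), ]
    repeat {
      utr <- rand_clean(U)
      ok <- TRUE
      plan <- list()
      for (k in seq_len(nrow(evs))) {
        gcod <- evs$codons[k]
        s <- U - 3L * gcod - 2L
        vp <- sg_var_pos[[evs$ref_triplet[k]]]
        substr(utr, s, s + 2L) <- evs$ref_triplet[k]
        plan[[evs$id[k]]] <- list(s = s, p_t = s + vp - 1L,
                                  alt_t = substring("ATG", vp, vp))
      }
      mut_ok <- TRUE
      for (k in names(plan)) {
        p <- plan[[k]]
        mut <- utr; substr(mut, p$p_t, p$p_t) <- p$alt_t
        for (w in max(1L, p$p_t - 2L):p$p_t) {
          if (w + 2L > U) next
          creates <- substring(mut, w, w + 2L) == "ATG" &&
            substring(utr, w, w + 2L) != "ATG"
          inframe <- ((U + 1L) - w) %% 3L == 0L
          if (inframe && creates != (w == p$s)) mut_ok <- FALSE
        }
      }
      if (mut_ok) break
    }
    asm <- assemble_tx(utr, cds, utr3)
    add_spacer("chr1")
    h0 <- append_seq("human", "chr1", asm$oseq)
    for (sp in setdiff(species, "human")) append_seq(sp, "chr1", asm$oseq)
    exf <- asm$exons_o
    txA <- transcript_model("SG_CA", "G_SG_C", "chr1", "+",
      data.frame(start = h0 - 1L + exf[, 1], end = h0 - 1L + exf[, 2]),
      cds_start_g = h0 - 1L + asm$t2o(U + 1L),
      cds_end_g = h0 - 1L + asm$t2o(U + nchar(cds)))
    # isoform B: CDS over most of A's 5'UTR (annotation-level construct)
    txB <- transcript_model("SG_CB", "G_SG_C", "chr1", "+",
      data.frame(start = h0 - 1L + exf[, 1], end = h0 - 1L + exf[, 2]),
      cds_start_g = h0 + 3L, cds_end_g = h0 - 1L + U)
    tx_h[["SG_CA"]] <- txA; tx_h[["SG_CB"]] <- txB
    for (sp in c("chimpanzee", "gorilla", "orangutan"))
      add_maf_block(sp, "chr1", asm$oseq, asm$oseq, h0,
                    gcur[[sp]][["chr1"]] - nchar(asm$oseq) + 1L, "+")
    for (k in seq_len(nrow(evs))) {
      ev <- as.list(evs[k, ]); p <- plan[[ev$id]]
      plant_sg(ev, utr, p$p_t, p$alt_t, p$s, txA)
    }
    grid_h[["SG_CA"]] <- data.frame(
      transcript_id = "SG_CA",
      tpos = seq.int(U + 1L, cds_end_tpos(txA) - 2L, by = 3L))
    anchors_h[[length(anchors_h) + 1L]] <- data.frame(
      transcript_id = "SG_CA", tpos = U + 1L, fold = config$peak_fold,
      samples = "ALL", stringsAsFactors = FALSE)
  }

  # ---------------- species-specific start-codon loci ----------------
  hss <- config$hss_events
  pi_codon <- uniform_codon_frequencies()
  for (r in seq_len(nrow(hss))) {
    ev <- as.list(hss[r, ])
    L <- ev$L_nt
    utr_up <- rand_clean(33L)
    ncod <- L %/% 3L
    sim <- simulate_codon_alignment(config$kaks_tree, config$kaks_kappa,
      c(config$kaks_omega_human, config$kaks_omega_background,
        config$kaks_omega_background), pi_codon, ncod)
    tips <- apply(sim$codons, 1, paste, collapse = "")
    body <- rand_codons(20L)
    cds_h <- paste0("ATG", tips[["human"]], "ATG", body, "TAA")
    utr3 <- rand_dna(25L)
    introns <- if (r %% 3L == 0L)
      list(list(after = 33L + nchar(cds_h) - 20L, seq = rand_dna(70L)))
      else list()
    asm <- assemble_tx(utr_up, cds_h, utr3, introns)
    len <- nchar(asm$oseq)
    # species aligned strings in transcript orientation
    aln <- stats::setNames(rep(asm$oseq, 4), species)
    hssc_o <- asm$t2o(34L)               # oriented pos of the start triplet
    ncds_o <- asm$t2o(37L)               # oriented pos of novel CDS start
    set_triplet <- function(sp, trip)
      substr(aln[[sp]], hssc_o, hssc_o + 2L) <<- trip
    set_ncds <- function(sp, seqs)
      substr(aln[[sp]], ncds_o, ncds_o + L - 1L) <<- seqs
    set_ncds("chimpanzee", tips[["chimpanzee"]])
    set_ncds("gorilla", tips[["gorilla"]])
    set_ncds("orangutan", tips[["chimpanzee"]])
    gor_trip <- orang_trip <- ev$chimp_triplet
    if (ev$class == "outgroup_shared") {
      if (ev$id == "HO1") gor_trip <- "ATG" else orang_trip <- "ATG"
    }
    set_triplet("chimpanzee", ev$chimp_triplet)
    set_triplet("gorilla", gor_trip)
    set_triplet("orangutan", orang_trip)
    if (ev$gorilla_stop && ncod >= 3L) {
      # a stop codon in the gorilla ortholog (not coding there)
      substr(aln[["gorilla"]], ncds_o + 3L, ncds_o + 5L) <- "TAA"
    }
    if (ev$gorilla_del && ncod >= 3L) {
      substr(aln[["gorilla"]], ncds_o + 3L, ncds_o + 5L) <- "---"
    }
    if (ev$class == "gap_broken") {
      # chimp loses exactly the divergent base of the start triplet
      dv <- which(strsplit(ev$chimp_triplet, "")[[1]] !=
                    strsplit("ATG", "")[[1]])[1]
      substr(aln[["chimpanzee"]], hssc_o + dv - 1L, hssc_o + dv - 1L) <- "-"
    }
    # forward-orientation aligned strings (human forward strand)
    alnf <- if (ev$strand == "+") aln else
      stats::setNames(vapply(aln, revcomp, character(1)), names(aln))
    add_spacer(ev$contig)
    h0 <- append_seq("human", ev$contig, gsub("-", "", alnf[["human"]]))
    q0 <- list()
    for (sp in setdiff(species, "human")) {
      qseq <- gsub("-", "", alnf[[sp]], fixed = TRUE)
      if (isTRUE(ev$inverted) && sp == "chimpanzee") qseq <- revcomp(qseq)
      q0[[sp]] <- append_seq(sp, ev$contig, qseq)
      add_maf_block(sp, ev$contig, alnf[["human"]], alnf[[sp]], h0, q0[[sp]],
                    if (isTRUE(ev$inverted) && sp == "chimpanzee") "-" else "+")
    }
    to_fwd_pt <- function(o) if (ev$strand == "+") o else flip_point(o, len)
    exf <- t(apply(asm$exons_o, 1, function(se)
      if (ev$strand == "+") se else flip_interval(se, len)))
    tid <- paste0("HS_", ev$id)
    tx <- transcript_model(tid, paste0("G_", tid), ev$contig, ev$strand,
      data.frame(start = h0 - 1L + exf[, 1], end = h0 - 1L + exf[, 2]),
      cds_start_g = h0 - 1L + to_fwd_pt(asm$t2o(34L)),
      cds_end_g = h0 - 1L + to_fwd_pt(asm$t2o(33L + nchar(cds_h))))
    tx_h[[tid]] <- tx
    # chimpanzee transcript model (in chimp genome coordinates)
    make_chimp_tx <- FALSE
    chimp_cds_start_t <- 34L + 3L + L   # hasc in transcript coordinates
    if (ev$class %in% c("true", "polymorphic", "outgroup_shared")) {
      make_chimp_tx <- TRUE; chimp_cds_from <- chimp_cds_start_t
    } else if (ev$id == "HU2") {
      make_chimp_tx <- TRUE; chimp_cds_from <- 34L  # CDS covers the ortholog
    }
    if (make_chimp_tx) {
      clen <- len  # chimp locus length equals human (no chimp indels here)
      c_strand <- ev$strand
      cpt <- function(o) {
        p <- if (ev$strand == "+") o else flip_point(o, clen)
        if (isTRUE(ev$inverted)) flip_point(p, clen) else p
      }
      if (isTRUE(ev$inverted)) c_strand <- if (ev$strand == "+") "-" else "+"
      cexf <- t(apply(asm$exons_o, 1, function(se) {
        fe <- if (ev$strand == "+") se else flip_interval(se, clen)
        if (isTRUE(ev$inverted)) flip_interval(fe, clen) else fe
      }))
      ctid <- paste0("C", tid)
      ctx <- transcript_model(ctid, paste0("G_", ctid), ev$contig, c_strand,
        data.frame(start = q0[["chimpanzee"]] - 1L + cexf[, 1],
                   end = q0[["chimpanzee"]] - 1L + cexf[, 2]),
        cds_start_g = q0[["chimpanzee"]] - 1L + cpt(asm$t2o(chimp_cds_from)),
        cds_end_g = q0[["chimpanzee"]] - 1L + cpt(asm$t2o(33L + nchar(cds_h))))
      tx_c[[ctid]] <- ctx
      # chimp ribo grid and anchors (only for loci with a chimp transcript)
      cosc_t <- cds_start_tpos(ctx) - (3L + L) * (chimp_cds_from != 34L)
      grid_c[[ctid]] <- data.frame(
        transcript_id = ctid,
        tpos = seq.int(max(cosc_t, 1L), cds_end_tpos(ctx) - 2L, by = 3L))
      anchors_c[[length(anchors_c) + 1L]] <- data.frame(
        transcript_id = ctid, tpos = cds_start_tpos(ctx),
        fold = config$peak_fold, samples = "ALL", stringsAsFactors = FALSE)
      if (ev$class == "true" && ev$chimp_triplet == "CTG")
        anchors_c[[length(anchors_c) + 1L]] <- data.frame(
          transcript_id = ctid, tpos = cosc_t,
          fold = config$cug_residual_fold, samples = "ALL",
          stringsAsFactors = FALSE)
    }
    # population records at the start-codon site
    dvpos <- which(strsplit(ev$chimp_triplet, "")[[1]] !=
                     strsplit("ATG", "")[[1]])
    site_g <- tx_to_genome(tx, 34L + dvpos - 1L)
    if (ev$class == "polymorphic") {
      carrier <- individuals[config$n_human_ribo + 5L]
      ref_f <- if (ev$strand == "+") substring("ATG", dvpos[1], dvpos[1])
               else complement_base(substring("ATG", dvpos[1], dvpos[1]))
      alt_f <- setdiff(c("A", "C", "G", "T"), ref_f)[1]
      add_vcf(ev$contig, site_g[1], ref_f, alt_f, genotype_row(carrier),
              paste0("POLY_", ev$id))
    } else if (isTRUE(ev$monomorphic_vcf)) {
      ref_f <- if (ev$strand == "+") substring("ATG", dvpos[1], dvpos[1])
               else complement_base(substring("ATG", dvpos[1], dvpos[1]))
      alt_f <- setdiff(c("A", "C", "G", "T"), ref_f)[1]
      add_vcf(ev$contig, site_g[1], ref_f, alt_f, genotype_row(character(0)),
              paste0("MONO_", ev$id))
    }
    truth_hss[[ev$id]] <- list(
      id = ev$id, class = ev$class, transcript_id = tid,
      chimp_transcript_id = if (make_chimp_tx) paste0("C", tid) else NA,
      expect_call = ev$class == "true",
      reject_reason = switch(ev$class, true = NA_character_,
        polymorphic = "polymorphic", outgroup_shared = "outgroup_shared",
        chimp_not_5utr = "chimp_not_5utr", gap_broken = "gap_broken"),
      novel_cds_len_nt = L, novel_cds_len_codons = L %/% 3L,
      analyzable = ev$class == "true" && L %/% 3L >= 5L,
      cug_origin = ev$class == "true" && ev$chimp_triplet == "CTG",
      chimp_triplet = ev$chimp_triplet,
      n_divergent_positions = length(dvpos),
      concat_eligible = ev$class == "true" && L > 15L,
      gorilla_del = isTRUE(ev$gorilla_del),
      gorilla_stop = isTRUE(ev$gorilla_stop),
      strand = ev$strand, contig = ev$contig)
    # human ribo grid: from the species-specific start through the stop
    grid_h[[tid]] <- data.frame(
      transcript_id = tid,
      tpos = seq.int(34L, cds_end_tpos(tx) - 2L, by = 3L))
    anchors_h[[length(anchors_h) + 1L]] <- data.frame(
      transcript_id = tid, tpos = 34L, fold = config$peak_fold,
      samples = "ALL", stringsAsFactors = FALSE)
  }

  # blacklist locus (an intergenic "rRNA" region on chr1, all species)
  add_spacer("chr1")
  bl_seq <- rand_dna(400L)
  bl_start <- append_seq("human", "chr1", bl_seq)
  for (sp in setdiff(species, "human")) append_seq(sp, "chr1", bl_seq)
  blacklist <- data.frame(contig = "chr1", start = bl_start,
                          end = bl_start + 399L, name = "ncRNA_rRNA")
  # decoy non-one-to-one alignment: one human spacer aligned to two chimp
  # copies appended at the end of chr2
  decoy_seq <- rand_dna(120L)
  d_h0 <- append_seq("human", "chr2", decoy_seq)
  for (sp in c("gorilla", "orangutan")) append_seq(sp, "chr2", decoy_seq)
  d_q1 <- append_seq("chimpanzee", "chr2", decoy_seq)
  d_q2 <- append_seq("chimpanzee", "chr2", decoy_seq)
  add_maf_block("chimpanzee", "chr2", decoy_seq, decoy_seq, d_h0, d_q1, "+")
  add_maf_block("chimpanzee", "chr2", decoy_seq, decoy_seq, d_h0, d_q2, "+")
  add_spacer("chr1"); add_spacer("chr2"); add_spacer("chrX")

  # one indel record (skipped by the VCF reader, with a count)
  add_vcf("chr1", bl_start + 10L,
          substring(bl_seq, 11L, 12L), substring(bl_seq, 11L, 11L),
          genotype_row(individuals[3]), "INDEL1")
  # ---------------- assemble genomes and write files ----------------
  genomes <- lapply(species, function(sp) {
    vapply(contigs, function(ctg)
      paste(unlist(gparts[[sp]][[ctg]]), collapse = ""), character(1))
  })
  names(genomes) <- species

  # make N3 multiallelic: append a second alternate verified to create no AUG
  n3 <- which(vapply(vcf_rows, function(v) v$id == "N3", logical(1)))
  if (length(n3)) {
    v <- vcf_rows[[n3]]
    tx3 <- tx_h[[truth_sg[["N3"]]$transcript_id]]
    seq3 <- tx_sequence(tx3, genomes$human)
    p3 <- truth_sg[["N3"]]$variant_pos_t
    for (third in setdiff(c("A", "C", "G", "T"), c(v$ref, v$alt))) {
      third_t <- if (tx3$strand == "+") third else complement_base(third)
      mut <- seq3; substr(mut, p3, p3) <- third_t
      wins <- max(1L, p3 - 2L):p3
      creates <- any(substring(mut, wins, wins + 2L) == "ATG" &
                       substring(seq3, wins, wins + 2L) != "ATG")
      if (!creates) {
        vcf_rows[[n3]]$alt <- paste0(v$alt, ",", third)
        break
      }
    }
  }
  paths <- list(out_dir = out_dir)
  for (sp in species) {
    paths[[paste0("fasta_", sp)]] <- file.path(out_dir, paste0(sp, ".fa"))
    write_fasta(genomes[[sp]], paths[[paste0("fasta_", sp)]])
  }
  paths$gff_human <- file.path(out_dir, "human.gff3")
  write_gff3(tx_h, paths$gff_human)
  paths$gff_chimp <- file.path(out_dir, "chimpanzee.gff3")
  write_gff3(tx_c, paths$gff_chimp)
  # MAF files
  src_sizes <- unlist(lapply(species, function(sp)
    stats::setNames(nchar(genomes[[sp]]), paste0(sp, ".", contigs))))
  for (sp in c("chimpanzee", "gorilla", "orangutan")) {
    p <- file.path(out_dir, paste0("human_", sp, ".maf"))
    paths[[paste0("maf_", sp)]] <- p
    write_maf(maf[[sp]], p, src_sizes)
  }
  # VCF
  paths$vcf <- file.path(out_dir, "population.vcf")
  write_vcf_rows(vcf_rows, individuals, paths$vcf)
  # blacklist BED
  paths$blacklist <- file.path(out_dir, "blacklist.bed")
  write_bed(blacklist, paths$blacklist)

  # ---------------- ribosome footprints ----------------
  ribo <- list(
    human = list(transcripts = tx_h, grid = do.call(rbind, grid_h),
                 anchors = do.call(rbind, anchors_h), samples = ribo_h,
                 genome = genomes$human),
    chimpanzee = list(transcripts = tx_c, grid = do.call(rbind, grid_c),
                      anchors = do.call(rbind, anchors_c), samples = ribo_c,
                      genome = genomes$chimpanzee),
    config = config, blacklist = blacklist)
  dir.create(file.path(out_dir, "ribo"), showWarnings = FALSE)
  paths$sam <- list()
  for (smp in ribo_h) {
    rd <- simulate_footprint_reads(ribo$human, smp, config)
    rd <- rbind(rd, distractor_reads(genomes$human, blacklist, config, smp))
    p <- file.path(out_dir, "ribo", paste0(smp, ".sam"))
    write_sam(rd, genomes$human, p)
    paths$sam[[smp]] <- p
  }
  for (smp in ribo_c) {
    rd <- simulate_footprint_reads(ribo$chimpanzee, smp, config)
    rd <- rbind(rd, distractor_reads(genomes$chimpanzee, NULL, config, smp))
    p <- file.path(out_dir, "ribo", paste0(smp, ".sam"))
    write_sam(rd, genomes$chimpanzee, p)
    paths$sam[[smp]] <- p
  }

  truth <- list(
    seed = config$seed,
    individuals = individuals, ribo_human_samples = ribo_h,
    ribo_chimp_samples = ribo_c,
    startgain = truth_sg, species = truth_hss,
    n_true_startgain = sum(vapply(truth_sg, function(x)
      isTRUE(x$expect_call), logical(1))),
    n_kept_occupancy = sum(vapply(truth_sg, function(x)
      isTRUE(x$kept_by_occupancy_filter), logical(1))),
    n_true_hss = sum(vapply(truth_hss, function(x)
      isTRUE(x$expect_call), logical(1))),
    n_analyzable_hss = sum(vapply(truth_hss, function(x)
      isTRUE(x$analyzable), logical(1))),
    n_cug_origin = sum(vapply(truth_hss, function(x)
      isTRUE(x$cug_origin), logical(1))),
    n_concat_eligible = sum(vapply(truth_hss, function(x)
      isTRUE(x$concat_eligible), logical(1))),
    peak_fold = config$peak_fold,
    kaks = list(tree = as.list(config$kaks_tree),
                kappa = config$kaks_kappa,
                omega_human = config$kaks_omega_human,
                omega_background = config$kaks_omega_background))
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(paths = paths, truth = truth, genomes = genomes,
                 transcripts_human = tx_h, transcripts_chimp = tx_c,
                 ribo = ribo, blacklist = blacklist, config = config))
}

# plain-text VCF writer for the fixture
write_vcf_rows <- function(rows, individuals, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individuals), collapse = "\t"))
  ord <- order(vapply(rows, `[[`, "", "contig"),
               vapply(rows, function(r) r$pos, 0))
  body <- vapply(rows[ord], function(r)
    paste(c(r$contig, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT",
            r$gt), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate ribosome footprints for one sample
#'
#' P-site positions are drawn from a background-plus-peaks intensity: unit
#' weight on every codon of each transcript's coding grid (novel CDS
#' included), multiplied by the anchor fold at active start codons for the
#' samples that carry them. Within a codon, the P-site lands on the first
#' nucleotide with probability `periodicity` and on the preceding or second
#' nucleotide with the remaining mass split evenly (cleavage slop), which
#' plants the 3-nt periodicity. Read lengths are uniform over 26-32 nt and
#' the leftmost position is back-computed from the sampled P-site by the
#' inverse offset rule, so every length and both strands exercise the
#' P-site rule.
#'
#' @param spec one species entry of the `ribo` element returned by
#'   [make_fixture()] (`transcripts`, `grid`, `anchors`, `samples`).
#' @param sample_id which sample to simulate.
#' @param config the `fixture_config`.
#' @param n_reads override for the number of signal reads.
#' @return data.frame of reads suitable for [write_sam()].
#' @export
simulate_footprint_reads <- function(spec, sample_id, config,
                                     n_reads = config$reads_per_sample) {
  grid <- spec$grid
  w <- rep(1, nrow(grid))
  anc <- spec$anchors
  for (k in seq_len(nrow(anc))) {
    applies <- anc$samples[k] == "ALL" ||
      sample_id %in% strsplit(anc$samples[k], ",", fixed = TRUE)[[1]]
    if (!applies) next
    i <- which(grid$transcript_id == anc$transcript_id[k] &
                 grid$tpos == anc$tpos[k])
    w[i] <- w[i] * anc$fold[k]
  }
  if (n_reads == 0L)
    return(data.frame(sample_id = character(), contig = character(),
                      pos = integer(), len = integer(), strand = character(),
                      unique = logical(), blacklisted = logical()))
  idx <- sample.int(nrow(grid), n_reads, replace = TRUE, prob = w)
  slop <- (1 - config$periodicity) / 2
  delta <- sample(c(-1L, 0L, 1L), n_reads, replace = TRUE,
                  prob = c(slop, config$periodicity, slop))
  tp <- grid$tpos[idx] + delta
  tid <- grid$transcript_id[idx]
  gpos <- integer(n_reads); strand <- character(n_reads)
  contig <- character(n_reads)
  for (id in unique(tid)) {
    tx <- spec$transcripts[[id]]
    sel <- tid == id
    gpos[sel] <- tx_to_genome(tx, tp[sel])
    strand[sel] <- tx$strand
    contig[sel] <- tx$contig
  }
  len <- sample(config$read_lengths, n_reads, replace = TRUE)
  off <- ifelse(len <= 29L, 11L, 12L)
  pos <- ifelse(strand == "+", gpos - off, gpos + off - len + 1L)
  data.frame(sample_id = sample_id, contig = contig, pos = as.integer(pos),
             len = as.integer(len), strand = strand, unique = TRUE,
             blacklisted = FALSE, stringsAsFactors = FALSE)
}

# reads that every filtering rule must remove: multimappers, out-of-range
# lengths, and (for the human samples) blacklist overlaps
distractor_reads <- function(genome, blacklist, config, sample_id) {
  n <- config$distractor_reads
  ctg <- names(genome)[1]
  glen <- nchar(genome[[ctg]])
  mk <- function(count, len, unique, at_blacklist = FALSE) {
    if (count == 0L) return(NULL)
    if (at_blacklist && !is.null(blacklist)) {
      pos <- sample(seq.int(blacklist$start[1], blacklist$end[1] - len),
                    count, replace = TRUE)
      c2 <- blacklist$contig[1]
    } else {
      pos <- sample.int(glen - 100L, count, replace = TRUE) + 40L
      c2 <- ctg
    }
    data.frame(sample_id = sample_id, contig = c2, pos = as.integer(pos),
               len = len, strand = sample(c("+", "-"), count, TRUE),
               unique = unique, blacklisted = FALSE, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(n[["multi"]], 28L, FALSE),
               mk(n[["short"]], 25L, TRUE),
               mk(n[["long"]], 33L, TRUE),
               if (!is.null(blacklist)) mk(n[["blacklist"]], 28L, TRUE, TRUE))
  out
}
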