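# toy transcript used by the rule-application examples: a 45-nt 5'UTR with
# the canonical start at transcript position 46
toy_startgain_tx <- function(utr) {
  cds <- paste0("ATG", "AAACCCGGG", "TAA")
  seq <- paste0(utr, cds, "GGGTTTT")
  genome <- c(c1 = seq)
  tx <- transcript_model("toy", "g", "c1", "+",
                         data.frame(start = 1L, end = nchar(seq)),
                         cds_start_g = nchar(utr) + 1L,
                         cds_end_g = nchar(utr) + 15L)
  list(tx = tx, genome = genome, cstart = nchar(utr) + 1L)
}

test_that("classify_snv applies the four calling rules", {
  # 45-nt UTR, clean of AUG/stop triplets; plant ACG 15 nt (5 codons)
  # upstream of the canonical start: C->T creates an in-frame AUG with a
  # 12-nt (4-codon) novel CDS
  base <- "CCTCCTCCTCCTCCTCCTCCTCCTCCTCCTCCTCCTCCTCCTCCT"
  utr <- base
  substr(utr, 31, 33) <- "ACG"
  w <- toy_startgain_tx(utr)
  snv <- list(contig = "c1", pos = 32L, ref = "C", alt = "T")
  cl <- classify_snv(snv, w$tx, w$genome, data.frame())
  expect_false(is.null(cl))
  expect_equal(cl$novel_start_tpos, 31L)
  expect_equal(cl$novel_cds_len_nt, 12L)
  expect_equal(cl$novel_cds_len_codons, 4L)
  # frame shift: same creation one base later is out of frame -> null
  utr2 <- base
  substr(utr2, 32, 34) <- "ACG"
  w2 <- toy_startgain_tx(utr2)
  expect_null(classify_snv(list(contig = "c1", pos = 33L, ref = "C",
                                alt = "T"), w2$tx, w2$genome, data.frame()))
  # an in-frame TGA between the novel AUG and the canonical start -> null
  utr3 <- utr
  substr(utr3, 37, 39) <- "TGA"
  w3 <- toy_startgain_tx(utr3)
  expect_null(classify_snv(snv, w3$tx, w3$genome, data.frame()))
  # the same call is rejected when the position lies in an annotated CDS
  cds_union <- data.frame(contig = "c1", start = 30L, end = 40L)
  expect_null(classify_snv(snv, w$tx, w$genome, cds_union))
  # ref allele inconsistent with the genome is a data error
  expect_error(classify_snv(list(contig = "c1", pos = 32L, ref = "A",
                                 alt = "T"), w$tx, w$genome, data.frame()),
               "inconsistent")
})

test_that("classify_snv agrees with the exhaustive substitution oracle", {
  fx <- default_fixture()
  inp <- default_inputs()
  txs <- inp$tx_h
  genome <- inp$genome_h
  cds_union <- cds_genomic_intervals(txs)
  bases <- c("A", "C", "G", "T")
  # every 5'UTR position x alternate allele of every start-gain locus
  # transcript, including the minus-strand and shared-locus ones
  picked <- grep("^SG_", names(txs), value = TRUE)
  n_checked <- 0L
  for (tid in picked) {
    tx <- txs[[tid]]
    seq <- walk_tx_seq(tx, genome)
    map <- walk_tx_map(tx)
    cstart <- cds_start_tpos(tx)
    for (tpos in seq_len(cstart - 1L)) {
      ref_t <- substr(seq, tpos, tpos)
      ref_f <- if (tx$strand == "+") ref_t else
        c(A = "T", C = "G", G = "C", T = "A")[[ref_t]]
      for (alt_t in setdiff(bases, ref_t)) {
        alt_f <- if (tx$strand == "+") alt_t else
          c(A = "T", C = "G", G = "C", T = "A")[[alt_t]]
        got <- classify_snv(list(contig = tx$contig, pos = map[tpos],
                                 ref = ref_f, alt = alt_f),
                            tx, genome, cds_union)
        want <- oracle_startgain(tx, genome, txs, tpos, alt_t)
        if (is.na(want)) {
          expect_null(got, info = paste(tid, tpos, alt_t))
        } else {
          expect_false(is.null(got), info = paste(tid, tpos, alt_t))
          if (!is.null(got))
            expect_equal(got$novel_start_tpos, want,
                         info = paste(tid, tpos, alt_t))
        }
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 1000L)
})

test_that("the caller recovers exactly the planted start-gain SNVs", {
  fx <- default_fixture()
  inp <- default_inputs()
  calls <- call_start_gains(inp$snvs, inp$tx_h, inp$genome_h)
  truth <- fx$truth$startgain
  true_ids <- names(Filter(function(x) isTRUE(x$expect_call), truth))
  expect_setequal(unique(calls$variant_id), true_ids)   # precision = recall = 1
  for (id in true_ids) {
    tr <- truth[[id]]
    row <- calls[calls$variant_id == id, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$transcript_id, tr$transcript_id)
    expect_equal(row$novel_start_tpos, tr$novel_start_tpos)
    expect_equal(row$novel_cds_len_codons, tr$novel_cds_len_codons)
    expect_equal(row$n_carriers, tr$n_carriers)
    expect_equal(row$allele_frequency, tr$allele_frequency)
    expect_equal(row$autosomal, tr$autosomal)
    # structural invariants of every emitted call
    gap <- row$canonical_start_tpos - row$novel_start_tpos
    expect_equal(gap %% 3L, 0L)
    expect_equal(row$novel_cds_len_nt, gap - 3L)
    expect_gte(row$novel_cds_len_nt, 0L)
  }
})

test_that("population summary counts carriers, AFs and burden", {
  # 1 call, 4 individuals with GT 0|0, 0|1, 1|1, 0|0
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2\ti3\ti4",
    "c1\t32\tv\tC\tT\t.\t.\t.\tGT\t0|0\t0|1\t1|1\t0|0"), f)
  snvs <- read_vcf(f)
  expect_equal(snv_allele_frequency(snvs, 1), 3 / 8)
  expect_setequal(snv_carriers(snvs, 1), c("i2", "i3"))
  calls <- data.frame(variant_id = "v", transcript_id = "t",
                      novel_cds_len_nt = 12L, allele_frequency = 3 / 8)
  s <- population_summary(calls, snvs)
  expect_equal(s$per_individual$n_carried, c(0L, 1L, 1L, 0L))
  expect_equal(s$per_call$allele_frequency, 3 / 8)
  # empty call set gives an empty table, not an error
  s0 <- population_summary(calls[0, ], snvs)
  expect_equal(sum(s0$per_individual$n_carried), 0L)
})

test_that("fixture allele frequencies match an independent haplotype tally", {
  fx <- default_fixture()
  inp <- default_inputs()
  raw <- readLines(file.path(fx$paths$out_dir, "population.vcf"))
  body <- raw[!startsWith(raw, "#")]
  for (i in seq_len(nrow(inp$snvs$sites))) {
    site <- inp$snvs$sites[i, ]
    ln <- body[grepl(paste0("^", site$contig, "\t", site$pos, "\t"), body)]
    f <- strsplit(ln, "\t")[[1]]
    alts <- strsplit(f[5], ",")[[1]]
    k <- which(alts == site$alt)
    gts <- unlist(strsplit(sub(":.*", "", f[-(1:9)]), "[|/]"))
    af <- sum(gts == as.character(k)) / sum(gts != ".")
    expect_equal(snv_allele_frequency(inp$snvs, i), af, info = site$variant_id)
  }
})

test_that("median planted novel-CDS length is recovered", {
  fx <- default_fixture()
  inp <- default_inputs()
  calls <- call_start_gains(inp$snvs, inp$tx_h, inp$genome_h)
  truth <- Filter(function(x) isTRUE(x$expect_call), fx$truth$startgain)
  planted <- vapply(truth, function(x) x$novel_cds_len_nt, 0L)
  expect_equal(stats::median(calls$novel_cds_len_nt),
               stats::median(planted))
})

test_that("occupancy filter keeps codons >= 5, carriers >= 3, autosomes", {
  calls <- data.frame(
    variant_id = c("a", "b", "c"),
    novel_cds_len_codons = c(4L, 5L, 10L),
    n_carriers = c(5L, 3L, 10L),
    autosomal = c(TRUE, TRUE, FALSE))
  kept <- filter_for_occupancy(calls)
  expect_equal(kept$variant_id, "b")   # 4 codons dropped, chrX dropped
})

test_that("NMD classification applies the strict 50-nt junction rule", {
  mk <- function(utr3a, utr3b) {
    # stop ends at tpos 75; junction depends on the 3'UTR exon split
    cds <- paste0("ATG", strrep("GCT", 19L), "TAA")
    tx_seq_len <- 15L + nchar(cds) + utr3a + utr3b
    exon1_end <- 15L + nchar(cds) + utr3a
    transcript_model("t", "g", "c1", "+",
      data.frame(start = c(1L, exon1_end + 101L),
                 end = c(exon1_end, exon1_end + 100L + utr3b)),
      cds_start_g = 16L, cds_end_g = 15L + nchar(cds))
  }
  # junction 60 nt after the stop -> predicted NMD target
  n1 <- nmd_classify(mk(60L, 40L))
  expect_equal(n1$distance_nt, 60L)
  expect_true(n1$nmd_predicted)
  # exactly 50 nt: the rule is strictly "more than 50"
  n2 <- nmd_classify(mk(50L, 40L))
  expect_equal(n2$distance_nt, 50L)
  expect_false(n2$nmd_predicted)
  # single-exon transcript: no junction, never NMD
  tx1 <- transcript_model("t", "g", "c1", "+",
                          data.frame(start = 1L, end = 90L),
                          cds_start_g = 16L, cds_end_g = 75L)
  n3 <- nmd_classify(tx1)
  expect_false(n3$nmd_predicted)
  expect_true(is.na(n3$distance_nt))
})

test_that("the planted NMD-positive transcript is the only one detected", {
  fx <- default_fixture()
  inp <- default_inputs()
  calls <- call_start_gains(inp$snvs, inp$tx_h, inp$genome_h)
  nmd <- lapply(unique(calls$transcript_id), function(tid)
    nmd_classify(inp$tx_h[[tid]]))
  pos <- Filter(function(x) x$nmd_predicted, nmd)
  expect_equal(vapply(pos, `[[`, "", "transcript_id"), "SG_T2")
})
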