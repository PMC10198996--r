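mk_block <- function(id, t_start, t_len, q_start, q_len = t_len,
                     t_contig = "c1", q_contig = "c1") {
  list(target = list(species = "human", contig = t_contig, start = t_start,
                     end = t_start + t_len - 1L, strand = "+",
                     size = t_len, aln = strrep("A", t_len)),
       query = list(species = "chimpanzee", contig = q_contig,
                    start = q_start, end = q_start + q_len - 1L,
                    strand = "+", size = q_len, aln = strrep("A", q_len)),
       block_id = id)
}

test_that("one-to-one filter drops multi-hit blocks on either side", {
  # two blocks overlapping on the human side: both dropped
  b <- list(mk_block("a", 1L, 100L, 1L), mk_block("b", 50L, 100L, 500L))
  expect_equal(length(filter_one_to_one(b)), 0L)
  # disjoint on both sides: all kept
  b2 <- list(mk_block("a", 1L, 100L, 1L), mk_block("b", 201L, 100L, 501L))
  expect_equal(length(filter_one_to_one(b2)), 2L)
  # overlap on the query side only: both dropped
  b3 <- list(mk_block("a", 1L, 100L, 1L), mk_block("b", 201L, 100L, 50L))
  expect_equal(length(filter_one_to_one(b3)), 0L)
})

test_that("one-to-one filter equals the per-base coverage oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    blocks <- lapply(seq_len(n), function(i) {
      len <- sample(20:80, 1)
      mk_block(paste0("b", i), sample(1:400, 1), len, sample(1:400, 1), len)
    })
    kept <- filter_one_to_one(blocks)
    # oracle: tabulate coverage of every base on both genomes
    tcov <- integer(1000); qcov <- integer(1000)
    for (b in blocks) {
      tcov[b$target$start:b$target$end] <- tcov[b$target$start:b$target$end] + 1L
      qcov[b$query$start:b$query$end] <- qcov[b$query$start:b$query$end] + 1L
    }
    want <- Filter(function(b)
      all(tcov[b$target$start:b$target$end] == 1L) &&
        all(qcov[b$query$start:b$query$end] == 1L), blocks)
    expect_setequal(vapply(kept, `[[`, "", "block_id"),
                    vapply(want, `[[`, "", "block_id"))
  }
})

test_that("divergent sites are exactly the planted substitutions", {
  inp <- default_inputs()
  blocks <- filter_one_to_one(inp$maf_c)
  sites <- find_divergent_sites(blocks, inp$genome_h, inp$genome_c)
  # every emitted site disagrees between the genomes at the stated positions
  for (i in seq_len(nrow(sites))) {
    h <- substring(as.character(inp$genome_h[[sites$contig[i]]]),
                   sites$pos[i], sites$pos[i])
    expect_equal(h, sites$target_allele[i])
  }
  # oracle: walk the columns of every block and recount mismatches
  n_oracle <- 0L
  for (b in blocks) {
    tch <- strsplit(b$target$aln, "")[[1]]
    qch <- strsplit(b$query$aln, "")[[1]]
    n_oracle <- n_oracle +
      sum(tch != "-" & qch != "-" & tch != qch & tch != "N" & qch != "N")
  }
  expect_equal(nrow(sites), n_oracle)
  # a gap column never yields a site: the gap-broken distractors have no
  # divergent site inside their start codon triplet
  fx <- default_fixture()
  for (id in c("HG1", "HG2")) {
    tx <- inp$tx_h[[fx$truth$species[[id]]$transcript_id]]
    trip_g <- tx_to_genome(tx, cds_start_tpos(tx) + 0:2)
    expect_equal(sum(sites$contig == tx$contig & sites$pos %in% trip_g), 0L,
                 info = id)
  }
})

test_that("block sequences disagreeing with the genome are a data error", {
  inp <- default_inputs()
  blocks <- filter_one_to_one(inp$maf_c)
  b <- blocks[[1]]
  bad <- b
  substr(bad$target$aln, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                          substr(b$target$aln, 3, 3))[1]
  expect_error(find_divergent_sites(list(bad), inp$genome_h, inp$genome_c),
               "disagrees")
})

test_that("species caller recovers the planted fixed start codons exactly", {
  fx <- default_fixture()
  sp <- species_calls()
  truth <- fx$truth$species
  true_ids <- names(Filter(function(x) isTRUE(x$expect_call), truth))
  got_ids <- sub("^HS_", "", vapply(sp$calls, `[[`, "", "transcript_id"))
  expect_setequal(got_ids, true_ids)             # precision = recall = 1
  tb <- hss_calls_table(sp$calls)
  for (id in true_ids) {
    tr <- truth[[id]]
    row <- tb[tb$transcript_id == paste0("HS_", id), ]
    expect_equal(row$novel_cds_len_nt, tr$novel_cds_len_nt, info = id)
    expect_equal(row$cug_origin, tr$cug_origin, info = id)
    expect_equal(row$chimp_triplet, tr$chimp_triplet, info = id)
    expect_true(row$in_frame, info = id)
    expect_equal(length(strsplit(row$divergent_positions, ",")[[1]]),
                 tr$n_divergent_positions, info = id)
  }
})

test_that("every rejection class is rejected for the stated reason", {
  fx <- default_fixture()
  sp <- species_calls()
  truth <- fx$truth$species
  rejected_ids <- names(Filter(function(x)
    !isTRUE(x$expect_call) && x$class != "gap_broken", truth))
  for (id in rejected_ids) {
    tr <- truth[[id]]
    row <- sp$rejected[sp$rejected$transcript_id == tr$transcript_id, ]
    expect_equal(nrow(row), 1L, info = id)
    expect_equal(row$reason, tr$reject_reason, info = id)
  }
  # gap-broken candidates never reach evaluation: absent from both lists
  for (id in c("HG1", "HG2")) {
    tid <- truth[[id]]$transcript_id
    expect_false(tid %in% sp$rejected$transcript_id, info = id)
    expect_false(tid %in% vapply(sp$calls, `[[`, "", "transcript_id"),
                 info = id)
  }
})

test_that("a partially aligned chimp triplet gives an unknown CUG flag", {
  sp <- species_calls()
  inp <- default_inputs()
  call <- sp$calls[[1]]
  tx <- inp$tx_h[[call$transcript_id]]
  # deprive the lookup of one triplet base by using an empty lookup
  empty <- new.env(parent = emptyenv())
  flagged <- flag_cug_origin(call, inp$tx_h, empty)
  expect_true(is.na(flagged$cug_origin))
  expect_true(is.na(flagged$chimp_triplet))
})

test_that("anchor panel lifts all four anchor classes through the MAF", {
  fx <- default_fixture()
  sp <- species_calls()
  inp <- default_inputs()
  panel <- sp$panel
  expect_equal(nrow(panel), 4L * length(sp$calls))
  expect_equal(sum(panel$analyzable[panel$anchor_class == "hSSC"]),
               fx$truth$n_analyzable_hss)
  # brute-force column walk of the MAF blocks for a plus- and the inverted
  # minus-strand call: cOSC must be the chimp base aligned to the hSSC
  for (id in c("H02", "H05")) {
    tid <- paste0("HS_", id)
    call <- sp$calls[[which(vapply(sp$calls, `[[`, "", "transcript_id") == tid)]]
    tx <- inp$tx_h[[tid]]
    blk <- Filter(function(b) b$target$contig == tx$contig &&
                    b$target$start <= call$hssc_g &&
                    b$target$end >= call$hssc_g, sp$blocks_c)[[1]]
    tch <- strsplit(blk$target$aln, "")[[1]]
    qch <- strsplit(blk$query$aln, "")[[1]]
    tpos_walk <- cumsum(tch != "-")
    col <- which(tch != "-" & (blk$target$start + tpos_walk - 1L) == call$hssc_g)
    stopifnot(length(col) == 1)
    qnon <- cumsum(qch != "-")
    q_fwd <- if (blk$query$strand == "+") blk$query$start + qnon[col] - 1L
             else blk$query$end - qnon[col] + 1L
    ctx <- inp$tx_c[[call$chimp_transcript_id]]
    cosc <- panel[panel$call_id == tid & panel$anchor_class == "cOSC", ]
    expect_equal(cosc$tpos, genome_to_tx(ctx, q_fwd), info = id)
    # and the chimp start codon anchor is the annotated chimp start
    csc <- panel[panel$call_id == tid & panel$anchor_class == "cSC", ]
    expect_equal(csc$tpos, cds_start_tpos(ctx), info = id)
  }
})

test_that("minus-strand and inverted-locus calls behave like plus-strand", {
  fx <- default_fixture()
  sp <- species_calls()
  tb <- hss_calls_table(sp$calls)
  minus <- tb[tb$strand == "-", ]
  expect_gt(nrow(minus), 0L)
  # identical invariants hold regardless of strand or query inversion
  for (i in seq_len(nrow(tb))) {
    expect_equal((tb$hasc_tpos[i] - tb$hssc_tpos[i]) %% 3L, 0L)
    expect_equal(tb$novel_cds_len_nt[i],
                 tb$hasc_tpos[i] - tb$hssc_tpos[i] - 3L)
  }
  # the inverted-locus event (H05) is called with the correct triplet
  expect_true("HS_H05" %in% tb$transcript_id)
})
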