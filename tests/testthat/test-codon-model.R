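test_that("rate matrix has the Goldman-Yang structure", {
  tab <- codon_tables()
  pi_u <- as.numeric(uniform_codon_frequencies())
  Q <- build_rate_matrix(1, 1, pi_u)
  # kappa = omega = 1 with uniform frequencies: symmetric
  expect_equal(Q, t(Q), tolerance = 1e-12)
  # codon pairs differing at > 1 position have rate zero
  expect_equal(Q["TTT", "TCC"], 0)
  expect_equal(Q["ATG", "TAC"], 0)
  kappa <- 2.5; omega <- 0.4
  Q2 <- build_rate_matrix(kappa, omega, pi_u)
  # synonymous transition TTT->TTC vs nonsynonymous transversion TTT->TTA
  expect_equal(Q2["TTT", "TTC"] / Q2["TTT", "TTA"], kappa / omega)
  # rows sum to zero, expected rate is one substitution per codon
  expect_lt(max(abs(rowSums(Q2))), 1e-12)
  expect_equal(-sum(pi_u * diag(Q2)), 1)
})

test_that("detailed balance and unit scaling hold for random parameters", {
  set.seed(11)
  for (rep in 1:5) {
    kappa <- stats::runif(1, 0.5, 5)
    omega <- stats::runif(1, 0.05, 3)
    pi <- random_pi()
    Q <- build_rate_matrix(kappa, omega, pi)
    flux <- pi * Q                       # pi_i q_ij
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    # transition matrices are stochastic and agree with the matrix
    # exponential of the R-side generator
    t <- stats::runif(1, 0.05, 1)
    P <- codon_pmatrix(kappa, omega, pi, t)
    expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-9)
    Pe <- as.matrix(Matrix::expm(Q * t))
    expect_lt(max(abs(P - unname(Pe))), 1e-8)
  }
})

test_that("zero-frequency codons are restricted out of the support", {
  pi <- as.numeric(uniform_codon_frequencies())
  pi[5] <- 0
  pi <- pi / sum(pi)
  Q <- build_rate_matrix(2, 0.5, pi)
  expect_true(all(Q[5, ] == 0))
  expect_true(all(Q[, 5][-5] == 0))
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
})

test_that("pruning equals brute-force root-state enumeration", {
  tab <- codon_tables()
  set.seed(12)
  for (rep in 1:4) {
    kappa <- stats::runif(1, 1, 4)
    om <- stats::runif(3, 0.1, 2.5)
    tv <- stats::runif(3, 0.02, 0.6)
    pi <- if (rep %% 2) as.numeric(uniform_codon_frequencies()) else random_pi()
    ncol <- sample(2:3, 1)
    m <- matrix(sample(tab$codons, 3 * ncol, replace = TRUE), nrow = 3,
                dimnames = list(c("human", "chimpanzee", "gorilla"), NULL))
    aln <- codon_alignment(m)
    got <- codon_log_likelihood(aln, kappa, om, tv, pi)
    # oracle: explicit sum over all 61 root states, term by term, using
    # R-built rate matrices and Matrix::expm
    Ps <- lapply(seq_len(3), function(b) {
      Q <- build_rate_matrix(kappa, om[b], pi)
      as.matrix(Matrix::expm(Q * tv[b]))
    })
    idx <- matrix(match(aln$codons, tab$codons), nrow = 3)
    want <- 0
    for (col in seq_len(aln$n_codons)) {
      s <- 0
      for (r in 1:61) {
        term <- pi[r]
        for (b in 1:3) term <- term * Ps[[b]][r, idx[b, col]]
        s <- s + term
      }
      want <- want + log(s)
    }
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("zero branch lengths reduce the likelihood to log root frequency", {
  tab <- codon_tables()
  pi <- as.numeric(uniform_codon_frequencies())
  m <- matrix("ATG", nrow = 3, ncol = 1,
              dimnames = list(c("human", "chimpanzee", "gorilla"), NULL))
  aln <- codon_alignment(m)
  ll <- codon_log_likelihood(aln, 2, c(1, 1, 1), c(0, 0, 0), pi)
  expect_equal(ll, log(pi[match("ATG", tab$codons)]), tolerance = 1e-9)
})

test_that("star-tree likelihood is symmetric in the background branches", {
  set.seed(13)
  pi <- as.numeric(uniform_codon_frequencies())
  aln <- simulate_codon_alignment(
    c(human = 0.2, chimpanzee = 0.3, gorilla = 0.1), 2, c(0.5, 1.2, 1.2),
    pi, 40)
  # swapping the two background branches (lengths and tip labels together)
  # leaves the likelihood unchanged
  l1 <- codon_log_likelihood(aln, 2, c(0.5, 1.2, 1.2), c(0.2, 0.3, 0.1), pi)
  aln2 <- aln
  aln2$codons <- aln$codons[c(1, 3, 2), ]
  rownames(aln2$codons) <- aln$taxa
  l2 <- codon_log_likelihood(aln2, 2, c(0.5, 1.2, 1.2), c(0.2, 0.1, 0.3), pi)
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("likelihood is invariant to codon-column permutation", {
  set.seed(14)
  pi <- as.numeric(uniform_codon_frequencies())
  aln <- simulate_codon_alignment(
    c(human = 0.2, chimpanzee = 0.2, gorilla = 0.2), 2, c(1, 1, 1), pi, 60)
  perm <- aln
  perm$codons <- perm$codons[, sample(ncol(perm$codons))]
  f1 <- fit_codon_model(aln, "human", pi_method = "uniform", n_starts = 2)
  f2 <- fit_codon_model(perm, "human", pi_method = "uniform", n_starts = 2)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-6)
})

test_that("alternative fits never fall below the nested null", {
  set.seed(15)
  pi <- as.numeric(uniform_codon_frequencies())
  for (rep in 1:3) {
    aln <- simulate_codon_alignment(
      c(human = 0.25, chimpanzee = 0.25, gorilla = 0.25), 2,
      rep(stats::runif(1, 0.3, 2), 3), pi, 120)
    f0 <- fit_codon_model(aln, "none", pi_method = "uniform")
    f1 <- fit_codon_model(aln, "human", pi_method = "uniform")
    expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-4)
    lrt <- codon_lrt(f0, f1)
    expect_gte(lrt$statistic, 0)
    expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  }
})

test_that("LRT maps the statistic through the chi-squared tail", {
  f0 <- structure(list(log_likelihood = -100, n_params = 5L), class = "kaks_fit")
  f1 <- structure(list(log_likelihood = -100, n_params = 6L), class = "kaks_fit")
  expect_equal(codon_lrt(f0, f1)$p_value, 1)
  f2 <- structure(list(log_likelihood = -100 + 3.84 / 2, n_params = 6L),
                  class = "kaks_fit")
  expect_equal(codon_lrt(f0, f2)$p_value, 0.05, tolerance = 0.01)
  f3 <- structure(list(log_likelihood = -101, n_params = 6L), class = "kaks_fit")
  expect_error(codon_lrt(f0, f3), "optimiser failure")
})

test_that("concatenation keeps alignments strictly above the length bound", {
  mk <- function(n, tag) {
    m <- matrix("ATG", nrow = 3, ncol = n,
                dimnames = list(c("human", "chimpanzee", "gorilla"), NULL))
    codon_alignment(m, source_cds_ids = tag)
  }
  # 4, 5, 6 codons = 12, 15, 18 nt: only the 18-nt alignment survives "> 15"
  cc <- concatenate_alignments(list(mk(4, "a"), mk(5, "b"), mk(6, "c")), 15)
  expect_equal(cc$n_codons, 6L)
  expect_equal(cc$source_cds_ids, "c")
  cc2 <- concatenate_alignments(list(mk(6, "a"), mk(10, "b")), 15)
  expect_equal(cc2$n_codons, 16L)
  expect_error(concatenate_alignments(list(mk(4, "a")), 15), "longer than")
})

test_that("concatenated likelihood is the sum of per-alignment likelihoods", {
  set.seed(16)
  pi <- as.numeric(uniform_codon_frequencies())
  tv <- c(human = 0.2, chimpanzee = 0.2, gorilla = 0.3)
  a1 <- simulate_codon_alignment(tv, 2, c(0.5, 1, 1), pi, 20)
  a2 <- simulate_codon_alignment(tv, 2, c(0.5, 1, 1), pi, 30)
  cc <- concatenate_alignments(list(a1, a2), 15)
  l1 <- codon_log_likelihood(a1, 2, c(0.5, 1, 1), tv, pi)
  l2 <- codon_log_likelihood(a2, 2, c(0.5, 1, 1), tv, pi)
  lc <- codon_log_likelihood(cc, 2, c(0.5, 1, 1), tv, pi)
  expect_equal(lc, l1 + l2, tolerance = 1e-9)
})

test_that("novel-CDS extraction matches the genome slice and drops columns", {
  fx <- default_fixture()
  inp <- default_inputs()
  sp <- species_calls()
  truth <- fx$truth$species
  calls <- sp$calls
  by_tid <- stats::setNames(calls, vapply(calls, `[[`, "", "transcript_id"))
  # a clean call: the human row equals the brute-force transcript slice
  cl <- by_tid[["HS_H02"]]
  tx <- inp$tx_h[["HS_H02"]]
  aln <- extract_novel_cds_alignment(cl, tx, inp$genome_h, sp$lk_c, sp$lk_g)
  seq <- walk_tx_seq(tx, inp$genome_h)
  want <- substr(seq, cl$hssc_tpos + 3L, cl$hasc_tpos - 1L)
  expect_equal(paste(aln$codons["human", ], collapse = ""), want)
  expect_equal(aln$n_codons, truth$H02$novel_cds_len_codons)
  # the planted gorilla one-codon deletion drops exactly one column
  del_id <- truth[[which(vapply(truth, function(x)
    isTRUE(x$gorilla_del), logical(1)))]]$id
  cl_d <- by_tid[[paste0("HS_", del_id)]]
  aln_d <- extract_novel_cds_alignment(cl_d, inp$tx_h[[cl_d$transcript_id]],
                                       inp$genome_h, sp$lk_c, sp$lk_g)
  expect_equal(aln_d$n_codons, truth[[del_id]]$novel_cds_len_codons - 1L)
  expect_equal(aln_d$n_dropped_columns, 1L)
  # the planted gorilla stop codon is dropped, not an error
  stop_id <- truth[[which(vapply(truth, function(x)
    isTRUE(x$gorilla_stop), logical(1)))]]$id
  cl_s <- by_tid[[paste0("HS_", stop_id)]]
  aln_s <- extract_novel_cds_alignment(cl_s, inp$tx_h[[cl_s$transcript_id]],
                                       inp$genome_h, sp$lk_c, sp$lk_g)
  expect_equal(aln_s$n_codons, truth[[stop_id]]$novel_cds_len_codons - 1L)
})

test_that("codon simulation respects degenerate parameters", {
  pi <- as.numeric(uniform_codon_frequencies())
  set.seed(17)
  # zero branch lengths: all taxa identical to the root draw
  a0 <- simulate_codon_alignment(
    c(human = 0, chimpanzee = 0, gorilla = 0), 2, c(1, 1, 1), pi, 50)
  expect_true(all(a0$codons["human", ] == a0$codons["chimpanzee", ]))
  expect_true(all(a0$codons["human", ] == a0$codons["gorilla", ]))
  # omega = 0 on a branch: that branch never changes the amino acid; a
  # zero-length twin branch exposes the root state directly
  tab <- codon_tables()
  aa <- function(cod) tab$aa[match(cod, tab$codons)]
  a2 <- simulate_codon_alignment(
    c(human = 0.8, root = 0), 2, c(0, 1), pi, 400)
  expect_true(all(aa(a2$codons["human", ]) == aa(a2$codons["root", ])))
  # simulated codon frequencies approach pi (law of large numbers)
  a3 <- simulate_codon_alignment(c(human = 0.1, chimpanzee = 0.1), 2,
                                 c(1, 1), pi, 15000)
  freq <- table(factor(a3$codons, levels = tab$codons)) / (2 * 15000)
  expect_lt(max(abs(as.numeric(freq) - pi)), 0.005)
})
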