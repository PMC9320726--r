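test_that("window extraction follows TSS-relative offsets, strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chr = random_dna(400)))
  s <- as.character(genome[[1]])
  tss <- data.frame(replicon = "chr", position = 100L, strand = "+")
  w <- extract_window_sets(tss, genome, motif_window_spec("minus10"))
  expect_equal(unname(w$positive), substr(s, 80, 99))
  expect_equal(unname(w$negative), substr(s, 200, 219))
  tss_m <- data.frame(replicon = "chr", position = 100L, strand = "-")
  w_m <- extract_window_sets(tss_m, genome, motif_window_spec("minus10"))
  expect_equal(unname(w_m$positive), revcomp(substr(s, 101, 120)))
  # minus35 window geometry
  w35 <- extract_window_sets(tss, genome, motif_window_spec("minus35"))
  expect_equal(unname(w35$positive), substr(s, 65, 84))
  # off-edge TSSs are skipped and counted
  tss_edge <- data.frame(replicon = "chr", position = c(10L, 100L), strand = "+")
  w_e <- extract_window_sets(tss_edge, genome, motif_window_spec("minus35"))
  expect_equal(length(w_e$positive), 1)
  expect_gte(w_e$n_skipped, 1)
  expect_error(extract_window_sets(tss[0, ], genome), "empty")
})

test_that("window extraction is invariant under reverse-complementing the genome", {
  L <- 400L
  s <- random_dna(L)
  genome <- Biostrings::DNAStringSet(c(chr = s))
  genome_rc <- Biostrings::DNAStringSet(c(chr = revcomp(s)))
  tss <- data.frame(replicon = "chr", position = 200L, strand = "+")
  tss_rc <- data.frame(replicon = "chr", position = L + 1L - 200L, strand = "-")
  for (which in c("minus10", "minus35")) {
    a <- extract_window_sets(tss, genome, motif_window_spec(which))
    b <- extract_window_sets(tss_rc, genome_rc, motif_window_spec(which))
    expect_equal(unname(a$positive), unname(b$positive))
    expect_equal(unname(a$negative), unname(b$negative))
  }
})

test_that("EM recovers a planted word exactly from identical sequences", {
  seqs <- rep(paste0("GCGCGC", "TATAAT", "GCGCGCGC"), 30)
  fit <- oops_em(seqs, width = 6)
  expect_equal(fit$consensus, "TATAAT")
  expect_true(all(abs(colSums(fit$theta) - 1) < 1e-9))
  expect_true(all(fit$ic >= 0 & fit$ic <= 2 + 1e-9))
})

test_that("EM recovers a corrupted -10-like motif on GC-rich background", {
  set.seed(61)
  word <- strsplit("TATAAT", "")[[1]]
  seqs <- vapply(1:200, function(i) {
    bg <- strsplit(random_dna(20), "")[[1]]
    at <- sample(1:15, 1)
    ins <- ifelse(runif(6) < 0.15,
                  sample(c("A", "C", "G", "T"), 6, replace = TRUE), word)
    bg[at:(at + 5)] <- ins
    paste(bg, collapse = "")
  }, "")
  neg <- vapply(1:200, function(i) random_dna(20), "")
  fit <- oops_em(seqs, width = 6, negative = neg, seed = 1)
  match <- sum(strsplit(fit$consensus, "")[[1]] == word)
  expect_gte(match, 5)
  # the EM objective never decreases
  expect_true(all(diff(fit$log_likelihood) >= -1e-8))
  # and the motif scores as significantly enriched vs the negative set
  enr <- score_enrichment(fit, seqs, neg, n_perm = 1000, seed = 2)
  expect_gt(enr$statistic, 0)
  expect_lte(enr$p_value, 0.01)
})

test_that("EM input validation catches short and ragged sequences", {
  expect_error(oops_em(c("ACGTT", "ACG"), width = 4), "shorter|equal length")
  expect_error(oops_em(rep("ACGTACGT", 5), width = 3), "at least 4")
})

test_that("enrichment scoring is null-calibrated and reduces to score differences", {
  set.seed(77)
  seqs <- vapply(1:60, function(i) random_dna(20), "")
  fit <- oops_em(seqs, width = 6, seed = 1)
  null <- score_enrichment(fit, seqs, seqs, n_perm = 200, seed = 3)
  expect_equal(null$statistic, 0, tolerance = 1e-12)
  expect_gt(null$p_value, 0.05)
  one <- score_enrichment(fit, seqs[1], seqs[2], n_perm = 50, seed = 4)
  sc <- one$mean_positive - one$mean_negative
  expect_equal(one$statistic, sc)
})

test_that("fits are reproducible and expose a logLik", {
  seqs <- rep(c("GGGGTATAATGGGGGGGGGG", "CCCCTATAATCCCCCCCCCC"), 15)
  f1 <- oops_em(seqs, width = 6, seed = 9)
  f2 <- oops_em(seqs, width = 6, seed = 9)
  expect_identical(f1$theta, f2$theta)
  expect_s3_class(logLik(f1), "logLik")
  rep_tab <- consensus_report(f1)
  expect_equal(nrow(rep_tab), 6)
})
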