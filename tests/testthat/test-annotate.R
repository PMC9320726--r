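one_gene <- feature_table("chr", 1000L, 2000L, "+", "gene", "gA")

test_that("the four positional classes follow the interval rules", {
  cls <- function(pos, strand, feats = one_gene)
    classify_tss(data.frame(replicon = "chr", position = pos, strand = strand),
                 feats)
  a <- cls(900L, "+")
  expect_equal(a$classes, "P")
  expect_equal(a$utr_length, 100L)
  expect_equal(a$linked_gene, "gA")
  expect_equal(cls(1500L, "+")$classes, "I")
  expect_equal(cls(1500L, "-")$classes, "Ai")
  expect_equal(cls(2020L, "-")$classes, "Ad")
  expect_equal(cls(600L, "+")$classes, "O")   # 400 nt > 250 window
  # offset 0: leaderless primary TSS, also internal to the gene it starts
  z <- cls(1000L, "+")
  expect_true(grepl("P", z$classes))
  expect_equal(z$class_exclusive, "P")
  expect_equal(z$utr_length, 0L)
  expect_true(z$leaderless)
  # labels accumulate: internal to gA and primary for the downstream gene
  two <- feature_table(c("chr", "chr"), c(1000L, 2100L), c(2000L, 2900L),
                       c("+", "+"), c("gene", "gene"), c("gA", "gB"))
  m <- cls(1900L, "+", two)
  expect_setequal(strsplit(m$classes, ",")[[1]], c("P", "I"))
  expect_equal(m$linked_gene, "gB")  # the primary link wins
  expect_equal(m$utr_length, 200L)
})

test_that("5'UTR arithmetic is strand-mirrored and flags leaderless starts", {
  expect_equal(compute_utr(936L, 1000L, 2000L, "+"), 64L)
  expect_equal(compute_utr(1000L, 1000L, 2000L, "+"), 0L)
  expect_equal(compute_utr(2084L, 1500L, 2000L, "-"), 84L)
  expect_error(compute_utr(1100L, 1000L, 2000L, "+"), "negative")
})

test_that("classification agrees exactly with the exhaustive literal scan", {
  set.seed(71)
  n_bad <- 0
  for (rep in 1:25) {
    feats <- random_features(n_genes = sample(5:20, 1), genome_len = 10000L,
                             seed = 700 + rep)
    pos <- sample.int(10000L, 40L)
    strand <- sample(c("+", "-"), 40L, replace = TRUE)
    ann <- classify_tss(data.frame(replicon = "chr", position = pos,
                                   strand = strand), feats)
    for (i in 1:40) {
      want <- oracle_classify("chr", pos[i], strand[i], feats)
      got <- sort(strsplit(ann$classes[i], ",")[[1]])
      if (!identical(got, want)) n_bad <- n_bad + 1
    }
  }
  expect_equal(n_bad, 0)
})

test_that("labels are invariant under the strand-mirror transformation", {
  L <- 10000L
  feats <- random_features(12, L, seed = 88)
  mirror_feats <- feature_table(feats$replicon, L + 1L - feats$end,
                                L + 1L - feats$start,
                                ifelse(feats$strand == "+", "-", "+"),
                                feats$type, feats$locus_tag)
  set.seed(89)
  pos <- sample.int(L, 60L)
  strand <- sample(c("+", "-"), 60L, replace = TRUE)
  a <- classify_tss(data.frame(replicon = "chr", position = pos,
                               strand = strand), feats)
  b <- classify_tss(data.frame(replicon = "chr", position = L + 1L - pos,
                               strand = ifelse(strand == "+", "-", "+")),
                    mirror_feats)
  expect_identical(a$classes, b$classes)
  expect_identical(a$utr_length, b$utr_length)
})

test_that("every TSS gets a label and orphans stay exclusive", {
  feats <- random_features(10, 8000L, seed = 90)
  ann <- classify_tss(data.frame(replicon = "chr",
                                 position = seq(10L, 7990L, by = 97L),
                                 strand = "+"), feats)
  expect_true(all(nchar(ann$classes) > 0))
  orphan <- grepl("O", ann$classes)
  expect_true(all(ann$classes[orphan] == "O"))
})

test_that("summaries tally classes, replicons and 5'UTRs deterministically", {
  empty <- summarize_tss(classify_tss(
    data.frame(replicon = character(), position = integer(),
               strand = character()), one_gene))
  expect_equal(sum(empty$per_class$count), 0)
  calls <- data.frame(replicon = "chr",
                      position = c(900L, 995L, 1500L, 600L),
                      strand = c("+", "+", "+", "+"))
  s <- summarize_tss(classify_tss(calls, one_gene))
  expect_equal(s$per_class$count[s$per_class$class == "P"], 2)
  expect_equal(s$per_class$count[s$per_class$class == "I"], 1)
  expect_equal(s$per_class$count[s$per_class$class == "O"], 1)
  expect_equal(s$utr$n, 2)
  expect_equal(s$utr$mean, mean(c(100, 5)))
  expect_equal(s$utr$leaderless_fraction, 0.5)
})
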