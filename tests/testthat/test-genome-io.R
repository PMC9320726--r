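test_that("FASTA and GFF3 round-trip the simulated genome losslessly", {
  cfg <- simulation_config(genome_length = c(chrA = 2e4, chrB = 8e3), seed = 31)
  g <- simulate_genome(cfg)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_fasta(g$genome, fa)
  back <- read_fasta(fa)
  expect_identical(as.character(back), as.character(g$genome))
  write_gff3(g$features, gff)
  feats <- read_gff3(gff, back)
  expect_identical(as.data.frame(feats), as.data.frame(g$features))
})

test_that("malformed GFF3 rows are rejected with their line number", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t500\t100\t.\t+\t.\tID=g1"), bad)
  expect_error(read_gff3(bad), "line 2.*end < start")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t100\t500\t.\t?\t.\tID=g1"), bad)
  expect_error(read_gff3(bad), "line 2.*strand")
})

test_that("bedGraph conversion follows the 0-based half-open convention", {
  prof <- make_profile(c(100L, 200L), c(7L, 3L))
  fwd <- tempfile(fileext = ".bedgraph"); rev <- tempfile(fileext = ".bedgraph")
  write_bedgraph_pair(prof, fwd, rev)
  expect_identical(readLines(fwd), c("chr\t99\t100\t7", "chr\t199\t200\t3"))
  back <- read_bedgraph_pair(fwd, rev)
  expect_identical(as.data.frame(back), as.data.frame(prof))
  expect_equal(total_count(back), total_count(prof))
})

test_that("bedGraph reading validates counts and interval disjointness", {
  f <- tempfile(fileext = ".bedgraph"); empty <- tempfile(fileext = ".bedgraph")
  writeLines(character(0), empty)
  writeLines("chr\t10\t11\t-3", f)
  expect_error(read_bedgraph_pair(f, empty), "negative count")
  writeLines(c("chr\t10\t15\t2", "chr\t12\t20\t1"), f)
  expect_error(read_bedgraph_pair(f, empty), "overlapping")
  # multi-base intervals expand to per-position counts
  writeLines("chr\t10\t13\t4", f)
  prof <- read_bedgraph_pair(f, empty)
  expect_identical(prof$pos, 11:13)
  expect_identical(prof$count, rep(4L, 3))
})

test_that("5' ends are extracted from alignments strand-correctly", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr\tLN:1000",
    "r1\t0\tchr\t100\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t16\tchr\t100\t60\t50M\t*\t0\t0\t*\t*",
    "r3\t0\tchr\t100\t60\t50M\t*\t0\t0\t*\t*",
    "r4\t256\tchr\t300\t60\t50M\t*\t0\t0\t*\t*"), sam)
  prof <- alignments_to_end_profile(sam, "plus_lib")
  df <- as.data.frame(prof)
  expect_equal(nrow(df), 2)
  expect_equal(df$count[df$pos == 100 & df$strand == "+"], 2)  # forward 5' = leftmost
  expect_equal(df$count[df$pos == 149 & df$strand == "-"], 1)  # reverse 5' = rightmost
  expect_false(300 %in% df$pos)                                 # secondary ignored
  # unmapped-only file gives an empty profile
  sam2 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr\tLN:1000",
               "u1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam2)
  expect_equal(nrow(alignments_to_end_profile(sam2, "plus_lib")), 0)
})

test_that("TSS outputs keep a stable column order and round-trip", {
  calls <- make_calls(c(150L, 900L), c(40L, 25L))
  ann <- classify_tss(calls, feature_table("chr", 200, 800, "+", "gene", "g1"))
  tsv <- tempfile(fileext = ".tsv"); gff <- tempfile(fileext = ".gff3")
  out <- write_tss_outputs(ann, tsv, gff)
  expect_identical(names(out)[1:4], c("replicon", "position", "strand", "classes"))
  back <- read_tss_table(tsv)
  expect_equal(back$position, c(150L, 900L))
  expect_equal(back$classes, out$classes)
  gl <- readLines(gff)
  expect_identical(gl[1], "##gff-version 3")
  expect_equal(length(gl), 3)
})
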