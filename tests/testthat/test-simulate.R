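test_that("simulated genome hits configured GC and gene density", {
  cfg <- simulation_config(genome_length = 1e5, seed = 11)
  g <- simulate_genome(cfg)
  s <- strsplit(as.character(g$genome[[1]]), "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  # binomial oracle on the emitted sequence
  expect_lt(abs(gc - 0.68), 3 * sqrt(0.68 * 0.32 / 1e5))
  gene_nt <- sum(g$features$end - g$features$start + 1)
  expect_lt(abs(gene_nt / 1e5 - 0.833), 0.05)
  expect_gt(sum(g$features$type == "tRNA"), 0)
})

test_that("degenerate configs behave: no genes, unreachable density", {
  cfg0 <- simulation_config(genome_length = 2e4, gene_density = 0, seed = 1)
  expect_equal(nrow(simulate_genome(cfg0)$features), 0)
  cfg_bad <- simulation_config(genome_length = 2e4, gene_density = 0.99,
                               mean_gene_length = 500, mean_intergenic = 500,
                               seed = 1)
  expect_error(simulate_genome(cfg_bad), "unreachable")
})

test_that("generation is deterministic given the seed", {
  cfg <- simulation_config(genome_length = 3e4, n_tss = 30, n_processed = 10,
                           seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  expect_identical(a$profiles[[1]][[1]]$plus, b$profiles[[1]][[1]]$plus)
  expect_identical(a$profiles[[2]][[2]]$minus, b$profiles[[2]][[2]]$minus)
})

test_that("planted classes obey their positional rules", {
  cfg <- simulation_config(genome_length = 1e5, n_tss = 120, seed = 21)
  g <- simulate_genome(cfg)
  truth <- plant_tss(g$features, cfg)
  expect_equal(nrow(truth), 120)
  # self-consistency: the classifier reproduces every planted class
  ann <- classify_tss(truth[c("replicon", "position", "strand")], g$features)
  expect_identical(ann$class_exclusive, truth$planted_class)
  # utr bookkeeping
  is_p <- truth$planted_class == "P"
  expect_true(all(!is.na(truth$utr_length[is_p])))
  expect_true(all(is.na(truth$utr_length[!is_p])))
  expect_identical(truth$is_leaderless[is_p], truth$utr_length[is_p] <= 9)
  # same-strand spacing >= 25 nt
  for (key in split(truth, paste(truth$replicon, truth$strand))) {
    if (nrow(key) > 1) expect_true(all(diff(sort(key$position)) >= 25))
  }
})

test_that("all-leaderless and orphan-only mixes honour their constraints", {
  cfg <- simulation_config(genome_length = 5e4,
                           class_mix = c(P = 1, I = 0, A = 0, O = 0),
                           leaderless_fraction = 1, n_tss = 40, seed = 3)
  g <- simulate_genome(cfg)
  truth <- plant_tss(g$features, cfg)
  expect_true(all(truth$utr_length == 0))
  cfg_o <- simulation_config(genome_length = 5e4,
                             class_mix = c(P = 0, I = 0, A = 0, O = 1),
                             n_tss = 30, seed = 4)
  g2 <- simulate_genome(cfg_o)
  truth_o <- plant_tss(g2$features, cfg_o)
  gstart <- ifelse(g2$features$strand == "+", g2$features$start, g2$features$end)
  for (i in seq_len(nrow(truth_o))) {
    same <- g2$features$strand == truth_o$strand[i]
    off <- ifelse(truth_o$strand[i] == "+",
                  gstart[same] - truth_o$position[i],
                  truth_o$position[i] - gstart[same])
    down <- off[off >= 0]
    if (length(down)) expect_gt(min(down), 250)
  }
})

test_that("planted 5'UTR lengths and leaderless fraction match the design", {
  cfg <- simulation_config(genome_length = 4e5,
                           class_mix = c(P = 1, I = 0, A = 0, O = 0),
                           n_tss = 500, seed = 8)
  g <- simulate_genome(cfg)
  truth <- plant_tss(g$features, cfg)
  expect_lt(abs(mean(truth$utr_length) - 84), 10)
  cfg2 <- simulation_config(genome_length = 6e5,
                            class_mix = c(P = 1, I = 0, A = 0, O = 0),
                            n_tss = 1000, seed = 9)
  g2 <- simulate_genome(cfg2)
  truth2 <- plant_tss(g2$features, cfg2)
  expect_lt(abs(mean(truth2$is_leaderless) - 0.07),
            3 * sqrt(0.07 * 0.93 / 1000))
})

test_that("library counts follow the configured Poisson model", {
  # one planted TSS, many replicate library draws
  cfg <- simulation_config(genome_length = 5e3, n_tss = 1, n_processed = 1,
                           depth = 50, enrichment = 10, background_rate = 0,
                           class_mix = c(P = 1, I = 0, A = 0, O = 0),
                           n_conditions = 1, n_replicates = 400, seed = 13)
  g <- simulate_genome(cfg)
  truth <- plant_tss(g$features, cfg)
  prof <- simulate_libraries(truth, g$features, cfg)
  proc <- attr(prof, "processed")
  at <- function(p, df) {
    hit <- p$replicon == df$replicon[1] & p$strand == df$strand[1] &
      p$pos == df$position[1]
    if (any(hit)) p$count[hit] else 0L
  }
  kp <- vapply(prof[[1]], function(r) at(r$plus, truth), 0L)
  km <- vapply(prof[[1]], function(r) at(r$minus, truth), 0L)
  expect_lt(abs(mean(kp) - 500), 3 * sqrt(500 / 400))
  expect_lt(abs(mean(km) - 50), 3 * sqrt(50 / 400))
  # processed sites are balanced between the banks
  proc_df <- data.frame(replicon = proc$replicon[1], position = proc$position[1],
                        strand = proc$strand[1])
  pp <- vapply(prof[[1]], function(r) at(r$plus, proc_df), 0L)
  pm <- vapply(prof[[1]], function(r) at(r$minus, proc_df), 0L)
  se <- sqrt(2 * 50 / 400)
  expect_lt(abs(mean(pp) - mean(pm)), 3 * se)
})

test_that("zero-rate configuration yields empty profiles", {
  cfg <- simulation_config(genome_length = 2e4, depth = 0, enrichment = 10,
                           background_rate = 0, processed_site_rate = 0,
                           n_tss = 5, n_processed = 2, n_conditions = 1,
                           n_replicates = 1, seed = 2)
  g <- simulate_genome(cfg)
  truth <- plant_tss(g$features, cfg)
  prof <- simulate_libraries(truth, g$features, cfg)
  expect_equal(nrow(prof[[1]][[1]]$plus) + nrow(prof[[1]][[1]]$minus), 0)
})
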