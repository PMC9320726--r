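# Independent oracles and tiny fixture builders shared across test files.

# Skellam upper tail by direct convolution of two truncated Poisson mass
# functions: P(N1 - N2 >= d) = sum_j P(N2 = j) P(N1 >= d + j).
conv_skellam_sf <- function(d, lambda1, lambda2) {
  if (lambda2 == 0) {
    return(if (d <= 0) 1 else stats::ppois(d - 1, lambda1, lower.tail = FALSE))
  }
  J <- max(20L, suppressWarnings(stats::qpois(1 - 1e-15, lambda2)) + 20L)
  j <- 0:J
  sum(stats::dpois(j, lambda2) *
        ifelse(d + j <= 0, 1, stats::ppois(d + j - 1, lambda1, lower.tail = FALSE)))
}

# Literal exhaustive-scan classifier: for one TSS, loop over every feature
# and apply the interval rules directly. Independent of classify_tss's
# vectorised/short-circuited implementation.
oracle_classify <- function(replicon, position, strand, features,
                            primary_window = 250, antisense_margin = 30) {
  labels <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$replicon != replicon) next
    if (f$strand == strand) {
      gstart <- if (f$strand == "+") f$start else f$end
      off <- if (strand == "+") gstart - position else position - gstart
      if (off >= 0 && off <= primary_window) labels <- c(labels, "P")
      if (position >= f$start && position <= f$end) labels <- c(labels, "I")
    } else {
      if (position >= f$start && position <= f$end) {
        labels <- c(labels, "Ai")
      } else {
        dist <- max(f$start - position, position - f$end)
        if (dist >= 1 && dist <= antisense_margin) labels <- c(labels, "Ad")
      }
    }
  }
  labels <- unique(labels)
  # internal antisense shadows the margin label for the same TSS
  if ("Ai" %in% labels) labels <- setdiff(labels, "Ad")
  if (length(labels) == 0) labels <- "O"
  sort(labels)
}

# random feature table on one replicon for property tests
random_features <- function(n_genes, genome_len, seed) {
  set.seed(seed)
  start <- sort(sample.int(genome_len - 200L, n_genes))
  len <- sample(80:400, n_genes, replace = TRUE)
  end <- pmin(start + len, genome_len)
  feature_table(rep("chr", n_genes), start, end,
                sample(c("+", "-"), n_genes, replace = TRUE),
                rep("gene", n_genes), sprintf("G%04d", seq_len(n_genes)))
}

make_profile <- function(pos, count, strand = "+", replicon = "chr",
                         kind = "plus_lib", condition = 1L, replicate = 1L) {
  end_profile(rep(replicon, length(pos)), rep(strand, length(pos)),
              pos, count, library_kind = kind,
              condition = condition, replicate = replicate)
}

make_calls <- function(position, k_plus, strand = "+", replicon = "chr",
                       k_minus = 0L, condition = 1L) {
  n <- length(position)
  df <- data.frame(replicon = rep(replicon, n), position = as.integer(position),
                   strand = rep(strand, n), k_plus = as.integer(k_plus),
                   k_minus = rep(as.integer(k_minus), length.out = n),
                   diff = as.integer(k_plus - rep(k_minus, length.out = n)),
                   p_value = rep(1e-6, n), condition = rep(condition, n),
                   support = rep(1L, n), stringsAsFactors = FALSE)
  class(df) <- c("tss_calls", "data.frame")
  df
}

random_dna <- function(n, gc = 0.68) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
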