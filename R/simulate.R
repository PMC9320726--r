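#' Configuration for the synthetic dRNA-seq generator
#'
#' Bundles every knob of the synthetic genome / TSS / library generator. The
#' defaults emulate a GC-rich multi-replicon methylotroph genome: 68% GC,
#' 83.3% gene density, mean CDS length 887 nt with 183-nt intergenic gaps,
#' mean 5'UTR 84 nt with a 7% leaderless (UTR 0-9 nt) fraction, a 250-nt cap
#' on 5'UTR length, and a class mix of roughly one third primary TSSs, 31%
#' antisense and 17% orphans.
#'
#' @param genome_length integer vector of replicon lengths in nt (named or
#'   not; unnamed replicons are called `replicon1`, ...).
#' @param gc_content fraction of G+C in simulated sequence.
#' @param gene_density target fraction of the genome covered by genes.
#' @param mean_gene_length,mean_intergenic geometric means (nt) of gene and
#'   intergenic lengths.
#' @param class_mix named fractions over the planted classes `P` (primary),
#'   `I` (internal), `A` (antisense), `O` (orphan); must sum to 1.
#' @param utr_mean,utr_max mean and maximum planted 5'UTR length (nt).
#' @param leaderless_fraction fraction of primary TSSs planted with UTR 0.
#' @param depth expected "-"-library read count at a true TSS.
#' @param enrichment ratio of "+" to "-" expected count at a true TSS (> 1).
#' @param background_rate expected count per transcribed non-TSS position
#'   (both libraries).
#' @param processed_site_rate expected count at planted processed 5' ends
#'   (both libraries equally — the signature of a cleavage product).
#' @param n_tss,n_processed number of planted TSSs and processed sites.
#' @param n_conditions,n_replicates library layout.
#' @param condition_specificity probability that a planted TSS is silent in
#'   any given condition (0 = all TSSs shared by all conditions).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 1e5, gc_content = 0.68,
                              gene_density = 0.833, mean_gene_length = 887,
                              mean_intergenic = 183,
                              class_mix = c(P = 0.33, I = 0.19, A = 0.31, O = 0.17),
                              utr_mean = 84, leaderless_fraction = 0.07,
                              utr_max = 250, depth = 50, enrichment = 10,
                              background_rate = 0.02, processed_site_rate = 50,
                              n_tss = 200, n_processed = 100,
                              n_conditions = 2, n_replicates = 2,
                              condition_specificity = 0, seed = 1L) {
  if (is.null(names(genome_length))) {
    names(genome_length) <- paste0("replicon", seq_along(genome_length))
  }
  frac <- c(gc_content = gc_content, gene_density = gene_density,
            leaderless_fraction = leaderless_fraction,
            condition_specificity = condition_specificity)
  if (any(frac < 0 | frac > 1)) {
    stop("fractions must lie in [0,1]: ",
         paste(names(frac)[frac < 0 | frac > 1], collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(class_mix), c("P", "I", "A", "O"))) {
    stop("class_mix must be named over {P, I, A, O}", call. = FALSE)
  }
  class_mix <- class_mix[c("P", "I", "A", "O")]
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (enrichment <= 1) stop("enrichment must exceed 1", call. = FALSE)
  if (!(utr_max >= utr_mean && utr_mean >= 0)) {
    stop("need utr_max >= utr_mean >= 0", call. = FALSE)
  }
  structure(list(genome_length = genome_length, gc_content = gc_content,
                 gene_density = gene_density, mean_gene_length = mean_gene_length,
                 mean_intergenic = mean_intergenic, class_mix = class_mix,
                 utr_mean = utr_mean, leaderless_fraction = leaderless_fraction,
                 utr_max = utr_max, depth = depth, enrichment = enrichment,
                 background_rate = background_rate,
                 processed_site_rate = processed_site_rate,
                 n_tss = as.integer(n_tss), n_processed = as.integer(n_processed),
                 n_conditions = as.integer(n_conditions),
                 n_replicates = as.integer(n_replicates),
                 condition_specificity = condition_specificity,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-replicon genome with gene annotation
#'
#' Sequence is drawn i.i.d. with `P(G) = P(C) = gc_content/2`. Genes are laid
#' down left to right, alternating geometric intergenic gaps and geometric
#' gene lengths around the configured means, on random strands, until the
#' target gene density is reached or the replicon ends; about 2% of features
#' are typed tRNA (70-90 nt). Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (`DNAStringSet`) and `features`
#'   ([feature_table()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$genome_length < 2 * config$mean_gene_length)) {
    stop("each replicon must be at least twice the mean gene length", call. = FALSE)
  }
  achievable <- config$mean_gene_length /
    (config$mean_gene_length + config$mean_intergenic)
  if (config$gene_density > achievable + 0.05) {
    stop(sprintf(paste0("gene density %.3f unreachable with mean gene %d nt and ",
                        "mean intergenic %d nt (attainable ~%.3f)"),
                 config$gene_density, config$mean_gene_length,
                 config$mean_intergenic, achievable), call. = FALSE)
  }
  set.seed(config$seed)
  base_prob <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
                 G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seqs <- character(0)
  feats <- list()
  gi <- 0L
  for (rn in names(config$genome_length)) {
    L <- as.integer(config$genome_length[[rn]])
    seqs[[rn]] <- paste(sample(names(base_prob), L, replace = TRUE, prob = base_prob),
                        collapse = "")
    target <- config$gene_density * L
    pos <- 1L
    placed <- 0
    while (config$gene_density > 0 && placed < target) {
      gap <- stats::rgeom(1L, 1 / (config$mean_intergenic + 1))
      start <- pos + gap
      is_trna <- stats::runif(1L) < 0.02
      len <- if (is_trna) sample(70:90, 1L) else
        max(60L, stats::rgeom(1L, 1 / config$mean_gene_length) + 1L)
      end <- start + len - 1L
      if (end > L) break
      gi <- gi + 1L
      feats[[gi]] <- data.frame(
        replicon = rn, start = start, end = end,
        strand = sample(c("+", "-"), 1L),
        type = if (is_trna) "tRNA" else "gene",
        locus_tag = sprintf("SYN_%05d", gi), stringsAsFactors = FALSE)
      placed <- placed + len
      pos <- end + 1L
    }
  }
  features <- if (length(feats)) {
    df <- do.call(rbind, feats)
    feature_table(df$replicon, df$start, df$end, df$strand, df$type, df$locus_tag)
  } else feature_table()
  list(genome = Biostrings::DNAStringSet(unlist(seqs)), features = features)
}

# Discretized gamma sampler for non-leaderless 5'UTR lengths, truncated to
# [10, utr_max] (leaderless transcripts, UTR 0-9 nt, are drawn separately).
# Both gamma parameters are solved numerically so that the leaderless/
# non-leaderless mixture reproduces the two summary statistics the
# distribution is designed around: mixture mean = utr_mean and mixture
# median ~ (64/84) x utr_mean, the right-skew seen in bacterial 5'UTR
# length distributions.
utr_sampler <- function(utr_mean, utr_max, leaderless_fraction) {
  support <- 10:utr_max
  lf <- min(leaderless_fraction, 1 - 1e-9)
  mix_target <- utr_mean / (1 - lf)
  probs_for <- function(shape) {
    tr_mean <- function(scale) {
      p <- stats::pgamma(support + 1, shape, scale = scale) -
        stats::pgamma(support, shape, scale = scale)
      sum(support * p) / sum(p)
    }
    scale <- stats::uniroot(function(s) tr_mean(s) - mix_target,
                            lower = 0.5, upper = 40 * utr_max)$root
    p <- stats::pgamma(support + 1, shape, scale = scale) -
      stats::pgamma(support, shape, scale = scale)
    p / sum(p)
  }
  med_target <- round(64 / 84 * utr_mean)
  med_gap <- function(shape) {
    # infeasible shapes (trunc mean cannot reach the target) return NA
    p <- tryCatch(probs_for(shape), error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    lf + (1 - lf) * sum(p[support <= med_target]) - 0.5
  }
  # the mixture CDF at the median target decreases in shape; scan a shape
  # grid and take the best feasible skew (NAs mark infeasible shapes)
  grid <- seq(0.3, 3, by = 0.02)
  gaps <- vapply(grid, med_gap, 0)
  shape <- if (all(is.na(gaps))) 1 else grid[which.min(abs(gaps))]
  p <- probs_for(shape)
  function(n) sample(support, n, replace = TRUE, prob = p)
}

#' Plant ground-truth TSSs of each positional class
#'
#' Samples TSS positions satisfying the positional class rules: `P` upstream
#' of a gene start at a 5'UTR distance drawn from the configured distribution
#' (forced to 0 for the leaderless fraction), `I` inside a sense gene, `Ai`
#' inside an antisense gene, `Ad` within 30 nt beyond an antisense gene end,
#' and `O` away from all genes. Each planted position is verified with the
#' package's own classifier so that its exclusive class label is exactly the
#' planted one, and no two truth records lie within 25 nt on the same strand
#' (keeping downstream merge/curation behaviour unambiguous on truth sites).
#'
#' @param features a [feature_table()] (non-tRNA genes are used for planting).
#' @param config a [simulation_config()].
#' @param class_params [class_params()] used for the self-consistency check.
#' @return a data frame of class `truth_table` with columns replicon,
#'   position, strand, planted_class, linked_gene, utr_length, is_leaderless,
#'   expected_plus_rate, expected_minus_rate.
#' @export
plant_tss <- function(features, config, class_params = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(class_params)) class_params <- class_params()
  mix <- config$class_mix
  if (nrow(features) == 0L && any(mix[c("P", "I", "A")] > 0)) {
    stop("cannot plant gene-linked TSSs on an empty feature table", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- config$n_tss
  counts <- round(mix * n)
  counts["P"] <- counts["P"] + (n - sum(counts))   # rounding residue
  # split antisense between internal (Ai) and downstream-margin (Ad)
  n_ad <- round(0.2 * counts[["A"]])
  plan <- c(rep("P", counts[["P"]]), rep("I", counts[["I"]]),
            rep("Ai", counts[["A"]] - n_ad), rep("Ad", n_ad),
            rep("O", counts[["O"]]))
  lens <- config$genome_length
  genes <- features[features$type == "gene", , drop = FALSE]
  draw_utr <- if (counts[["P"]] > 0 && config$leaderless_fraction < 1) {
    utr_sampler(config$utr_mean, config$utr_max, config$leaderless_fraction)
  } else function(n) rep(0L, n)
  placed <- data.frame(replicon = character(), position = integer(),
                       strand = character(), planted_class = character(),
                       linked_gene = character(), utr_length = integer(),
                       is_leaderless = logical(), stringsAsFactors = FALSE)
  too_close <- function(rn, pos, strand) {
    same <- placed$replicon == rn & placed$strand == strand
    any(abs(placed$position[same] - pos) < 25L)
  }
  for (cls in plan) {
    ok <- FALSE
    # the 5'UTR (and leaderless state) belongs to the record, not to the
    # placement attempt: drawing it once keeps the configured length
    # distribution unbiased by placement rejections under crowding
    if (cls == "P") {
      ll_rec <- stats::runif(1L) < config$leaderless_fraction
      utr_rec <- if (ll_rec) 0L else draw_utr(1L)
    }
    for (attempt in 1:2000) {
      if (cls == "O") {
        rn <- sample(names(lens), 1L, prob = lens)
        pos <- sample.int(lens[[rn]], 1L)
        strand <- sample(c("+", "-"), 1L)
        gene <- NA_character_; utr <- NA_integer_; ll <- NA
      } else {
        g <- genes[sample.int(nrow(genes), 1L), ]
        rn <- g$replicon
        if (cls == "P") {
          ll <- ll_rec
          utr <- utr_rec
          pos <- if (g$strand == "+") g$start - utr else g$end + utr
          strand <- g$strand
        } else if (cls == "I") {
          pos <- sample(g$start:g$end, 1L); strand <- g$strand
          utr <- NA_integer_; ll <- NA
        } else if (cls == "Ai") {
          pos <- sample(g$start:g$end, 1L)
          strand <- if (g$strand == "+") "-" else "+"
          utr <- NA_integer_; ll <- NA
        } else { # Ad: within the antisense margin beyond an end of the gene
          off <- sample.int(class_params$antisense_margin, 1L)
          pos <- if (stats::runif(1L) < 0.5) g$end + off else g$start - off
          strand <- if (g$strand == "+") "-" else "+"
          utr <- NA_integer_; ll <- NA
        }
        gene <- g$locus_tag
      }
      if (pos < 1L || pos > lens[[rn]]) next
      if (too_close(rn, pos, strand)) next
      got <- classify_position(rn, pos, strand, features, class_params)
      if (got$exclusive != cls) next
      if (cls %in% c("P", "I", "Ai")) gene <- got$linked_gene
      placed <- rbind(placed, data.frame(
        replicon = rn, position = as.integer(pos), strand = strand,
        planted_class = cls, linked_gene = gene,
        utr_length = if (cls == "P") as.integer(utr) else NA_integer_,
        is_leaderless = if (cls == "P") !is.na(utr) && utr <= 9L else NA,
        stringsAsFactors = FALSE))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place a class ", cls,
           " TSS without violating spacing/class constraints", call. = FALSE)
    }
  }
  placed$expected_plus_rate <- config$depth * config$enrichment
  placed$expected_minus_rate <- config$depth
  placed <- placed[order(placed$replicon, placed$position, placed$strand), ]
  rownames(placed) <- NULL
  class(placed) <- c("truth_table", "data.frame")
  placed
}

# Processed 5' ends: cleavage products that appear equally in both libraries.
# Placed inside gene bodies, away (>= 25 nt) from planted TSSs on the strand.
plant_processed_sites <- function(features, truth, config) {
  genes <- features[features$type == "gene", , drop = FALSE]
  if (config$n_processed == 0L || nrow(genes) == 0L) {
    return(data.frame(replicon = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  set.seed(config$seed + 2L)
  out <- list(); k <- 0L
  while (k < config$n_processed) {
    g <- genes[sample.int(nrow(genes), 1L), ]
    pos <- sample(g$start:g$end, 1L)
    near <- truth$replicon == g$replicon & truth$strand == g$strand &
      abs(truth$position - pos) < 25L
    if (any(near)) next
    prev <- if (k) do.call(rbind, out) else NULL
    if (!is.null(prev) && any(prev$replicon == g$replicon & prev$strand == g$strand &
                              abs(prev$position - pos) < 5L)) next
    k <- k + 1L
    out[[k]] <- data.frame(replicon = g$replicon, position = pos,
                           strand = g$strand, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate paired "+"/"-" 5'-end count profiles
#'
#' For every condition and replicate, draws a `plus_lib` and a `minus_lib`
#' [end_profile()]: at truth TSS positions the "+" count is
#' Poisson(depth x enrichment) and the "-" count Poisson(depth); at planted
#' processed sites both libraries share Poisson(processed_site_rate); every
#' transcribed position (gene bodies plus planted 5'UTRs, on the feature
#' strand) receives background Poisson(background_rate) noise in both
#' libraries. With `condition_specificity > 0`, each truth TSS is silenced in
#' any given condition with that probability (consistently across its
#' replicates).
#'
#' @param truth a `truth_table` from [plant_tss()].
#' @param features the companion [feature_table()].
#' @param config a [simulation_config()].
#' @param processed optional data frame of processed-site positions (from
#'   `plant_processed_sites`); `NULL` plants `config$n_processed` of them.
#' @return nested list: `profiles[[condition]][[replicate]]` is a list with
#'   elements `plus` and `minus`; also carries the `processed` table as an
#'   attribute.
#' @export
simulate_libraries <- function(truth, features, config, processed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  lens <- config$genome_length
  if (nrow(truth) && any(truth$position < 1L |
                         truth$position > lens[truth$replicon])) {
    stop("truth position outside replicon bounds", call. = FALSE)
  }
  if (is.null(processed)) processed <- plant_processed_sites(features, truth, config)
  set.seed(config$seed + 3L)
  # transcribed background positions: gene bodies + planted UTR spans
  bg <- list()
  genes <- features[features$type == "gene", , drop = FALSE]
  if (nrow(genes) && config$background_rate > 0) {
    n <- genes$end - genes$start + 1L
    bg[[1]] <- data.frame(
      replicon = rep(genes$replicon, n), strand = rep(genes$strand, n),
      pos = unlist(mapply(seq, genes$start, genes$end, SIMPLIFY = FALSE),
                   use.names = FALSE), stringsAsFactors = FALSE)
    pr <- truth[truth$planted_class == "P" & !is.na(truth$utr_length) &
                truth$utr_length > 0, , drop = FALSE]
    if (nrow(pr)) {
      spans <- lapply(seq_len(nrow(pr)), function(i) {
        u <- pr$utr_length[i]
        pos <- if (pr$strand[i] == "+") pr$position[i] + seq_len(u) - 1L
        else pr$position[i] - seq_len(u) + 1L
        data.frame(replicon = pr$replicon[i], strand = pr$strand[i], pos = pos,
                   stringsAsFactors = FALSE)
      })
      bg[[2]] <- do.call(rbind, spans)
    }
    bg <- unique(do.call(rbind, bg))
  } else bg <- data.frame(replicon = character(), strand = character(),
                          pos = integer(), stringsAsFactors = FALSE)

  active <- matrix(TRUE, nrow = nrow(truth), ncol = config$n_conditions)
  if (config$condition_specificity > 0 && nrow(truth)) {
    active[] <- stats::runif(length(active)) >= config$condition_specificity
  }
  lam_plus <- config$depth * config$enrichment
  lam_minus <- config$depth

  build <- function(pos_df, counts, kind, cond, rep) {
    keep <- counts > 0L
    end_profile(pos_df$replicon[keep], pos_df$strand[keep],
                pos_df$pos[keep], counts[keep],
                library_kind = kind, condition = cond, replicate = rep)
  }
  sites <- rbind(
    if (nrow(truth)) data.frame(replicon = truth$replicon, strand = truth$strand,
                                pos = truth$position, kind = "tss",
                                stringsAsFactors = FALSE),
    if (nrow(processed)) data.frame(replicon = processed$replicon,
                                    strand = processed$strand,
                                    pos = processed$position, kind = "proc",
                                    stringsAsFactors = FALSE),
    if (nrow(bg)) data.frame(bg, kind = "bg", stringsAsFactors = FALSE))
  out <- vector("list", config$n_conditions)
  for (cond in seq_len(config$n_conditions)) {
    out[[cond]] <- vector("list", config$n_replicates)
    for (rep in seq_len(config$n_replicates)) {
      if (is.null(sites) || nrow(sites) == 0L) {
        out[[cond]][[rep]] <- list(
          plus = end_profile(library_kind = "plus_lib", condition = cond, replicate = rep),
          minus = end_profile(library_kind = "minus_lib", condition = cond, replicate = rep))
        next
      }
      is_tss <- sites$kind == "tss"
      on <- rep(TRUE, nrow(sites))
      if (any(is_tss)) on[is_tss] <- active[, cond]
      rate_p <- ifelse(sites$kind == "tss", lam_plus,
                       ifelse(sites$kind == "proc", config$processed_site_rate,
                              config$background_rate)) * on
      rate_m <- ifelse(sites$kind == "tss", lam_minus,
                       ifelse(sites$kind == "proc", config$processed_site_rate,
                              config$background_rate)) * on
      kp <- stats::rpois(nrow(sites), rate_p)
      km <- stats::rpois(nrow(sites), rate_m)
      # duplicate coordinates (e.g. background under a processed site) sum
      agg <- function(counts) {
        key <- paste(sites$replicon, sites$strand, sites$pos, sep = "\r")
        tot <- rowsum(counts, key)
        parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
        data.frame(replicon = vapply(parts, `[`, "", 1L),
                   strand = vapply(parts, `[`, "", 2L),
                   pos = as.integer(vapply(parts, `[`, "", 3L)),
                   count = as.integer(tot[, 1L]), stringsAsFactors = FALSE)
      }
      ap <- agg(kp); am <- agg(km)
      out[[cond]][[rep]] <- list(
        plus = build(ap, ap$count, "plus_lib", cond, rep),
        minus = build(am, am$count, "minus_lib", cond, rep))
    }
  }
  attr(out, "processed") <- processed
  out
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [simulate_genome()], [plant_tss()],
#' `plant_processed_sites` and [simulate_libraries()] under one seed.
#'
#' @inheritParams simulate_genome
#' @return list with `genome`, `features`, `truth`, `processed`, `profiles`.
#' @export
simulate_dataset <- function(config) {
  g <- simulate_genome(config)
  truth <- plant_tss(g$features, config)
  profiles <- simulate_libraries(truth, g$features, config)
  list(genome = g$genome, features = g$features, truth = truth,
       processed = attr(profiles, "processed"), profiles = profiles)
}

#' Write a synthetic dataset to disk
#'
#' Emits FASTA (genome), GFF3 (features), one bedGraph per strand per library
#' per condition/replicate, and a tab-separated truth table.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_gff3(sim$features, file.path(outdir, "features.gff3"))
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cond in seq_along(sim$profiles)) {
    for (rep in seq_along(sim$profiles[[cond]])) {
      for (kind in c("plus", "minus")) {
        stem <- sprintf("c%d_r%d_%s", cond, rep, kind)
        write_bedgraph_pair(sim$profiles[[cond]][[rep]][[kind]],
                            file.path(outdir, paste0(stem, "_fwd.bedgraph")),
                            file.path(outdir, paste0(stem, "_rev.bedgraph")))
      }
    }
  }
  invisible(outdir)
}
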