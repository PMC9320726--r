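#' Pipeline configuration
#'
#' Bundles inputs and stage parameters for [run_tss_pipeline()]. Inputs may
#' be in-memory objects (as produced by [simulate_dataset()] /
#' [read_fasta()] / [read_bedgraph_pair()]) or paths understood by the
#' corresponding readers.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param features [feature_table()] or GFF3 path.
#' @param profiles nested list `profiles[[condition]][[replicate]]`, each a
#'   list with `plus` and `minus` [end_profile()]s.
#' @param detection a [detection_params()].
#' @param curation a [curation_params()].
#' @param classes a [class_params()].
#' @param motif_width motif width (nt) for the -10/-35 EM fits.
#' @param n_perm label permutations for motif enrichment scoring.
#' @param reference optional `reference_tss` table (or TSV path) for the
#'   cross-method comparison stage.
#' @param outdir optional directory; when set, every stage writes its
#'   artifact there.
#' @param seed seed forwarded to the stochastic stages (motif permutation
#'   test).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, features, profiles,
                            detection = detection_params(),
                            curation = curation_params(),
                            classes = class_params(),
                            motif_width = 6L, n_perm = 200L,
                            reference = NULL, outdir = NULL, seed = 1L) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("genome file not found: ", genome, call. = FALSE)
    genome <- read_fasta(genome)
  }
  if (is.character(features)) {
    if (!file.exists(features)) stop("feature file not found: ", features, call. = FALSE)
    features <- read_gff3(features, genome)
  }
  if (missing(profiles) || is.null(profiles) || length(profiles) == 0L) {
    stop("pipeline needs at least one condition of +/- profiles", call. = FALSE)
  }
  for (cond in seq_along(profiles)) {
    for (rep in seq_along(profiles[[cond]])) {
      pr <- profiles[[cond]][[rep]]
      if (is.null(pr$plus) || is.null(pr$minus)) {
        stop(sprintf("condition %d replicate %d is missing its %s profile",
                     cond, rep, if (is.null(pr$plus)) "plus" else "minus"),
             call. = FALSE)
      }
    }
  }
  if (is.character(reference)) reference <- read_reference_tss(reference)
  structure(list(genome = genome, features = features, profiles = profiles,
                 detection = detection, curation = curation, classes = classes,
                 motif_width = as.integer(motif_width),
                 n_perm = as.integer(n_perm), reference = reference,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full dRNA-seq TSS mapping pipeline
#'
#' Executes detection per condition and replicate, replicate consolidation,
#' cross-condition curation (cluster resolution then tRNA filtering),
#' positional classification and 5'UTR summaries, -10/-35 promoter motif
#' fitting on the primary/IP TSSs of the largest replicon, and, when a
#' reference table is configured, the cross-method positional comparison.
#' Stage in/out counts are recorded in a run manifest; with `outdir` set,
#' every stage writes its artifact.
#'
#' @param config a [pipeline_config()].
#' @return list of class `tss_pipeline_result` with elements `calls`
#'   (per-condition curated `tss_calls`), `tss` (final annotated table),
#'   `summary` ([summarize_tss()] output), `motifs` (per window: the window
#'   sets, `pwm_model` and enrichment score), `comparison` (or `NULL`),
#'   `manifest` (stage counts and parameters).
#' @export
run_tss_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed,
                   detection = unclass(config$detection),
                   curation = unclass(config$curation),
                   classes = unclass(config$classes),
                   stages = list())
  note <- function(stage, n_in, n_out) {
    manifest$stages[[stage]] <<- c(n_in = n_in, n_out = n_out)
    message(sprintf("[%s] %d -> %d", stage, n_in, n_out))
  }

  # detection + replicate consolidation, per condition
  per_cond <- vector("list", length(config$profiles))
  for (cond in seq_along(config$profiles)) {
    reps <- config$profiles[[cond]]
    calls <- lapply(reps, function(pr)
      call_tss(pr$plus, pr$minus, config$detection))
    cons <- Reduce(function(a, b)
      consolidate_replicates(a, b, config$curation), calls)
    note(sprintf("detect+consolidate_c%d", cond),
         sum(vapply(calls, nrow, 0L)), nrow(cons))
    per_cond[[cond]] <- cons
  }

  # cross-condition cluster resolution
  curated <- vector("list", length(per_cond))
  for (cond in seq_along(per_cond)) {
    other <- if (length(per_cond) > 1L) {
      do.call(rbind, lapply(per_cond[-cond], as.data.frame))
    } else NULL
    curated[[cond]] <- cluster_and_select(per_cond[[cond]], other, config$curation)
    note(sprintf("cluster_select_c%d", cond),
         nrow(per_cond[[cond]]), nrow(curated[[cond]]))
  }

  # union across conditions (identical coordinates merged)
  all_calls <- do.call(rbind, lapply(seq_along(curated), function(cond) {
    df <- as.data.frame(curated[[cond]])
    if (nrow(df)) df$condition <- cond
    df
  }))
  if (nrow(all_calls)) {
    key <- paste(all_calls$replicon, all_calls$strand, all_calls$position, sep = "\r")
    merged <- do.call(rbind, lapply(split(seq_len(nrow(all_calls)), key), function(idx) {
      r <- all_calls[idx[which.max(all_calls$k_plus[idx])], , drop = FALSE]
      r$conditions_detected <- paste(sort(unique(all_calls$condition[idx])),
                                     collapse = ",")
      r
    }))
    merged <- merged[order(merged$replicon, merged$strand, merged$position), ]
    rownames(merged) <- NULL
  } else {
    merged <- all_calls
    merged$conditions_detected <- character(0)
  }
  class(merged) <- c("tss_calls", "data.frame")
  note("condition_union", nrow(all_calls), nrow(merged))

  flt <- filter_trna(merged, config$features, config$curation)
  note("trna_filter", nrow(merged), nrow(flt$kept))

  annotated <- classify_tss(flt$kept, config$features, config$classes)
  summ <- summarize_tss(annotated, config$genome, config$classes)
  note("classify", nrow(flt$kept), nrow(annotated))

  # promoter motifs from primary (P / IP) TSSs of the largest replicon
  motifs <- NULL
  main_repl <- names(config$genome)[which.max(Biostrings::width(config$genome))]
  ptss <- as.data.frame(annotated)
  ptss <- ptss[grepl("(^|,)P(,|$)", ptss$classes) & ptss$replicon == main_repl, ]
  if (nrow(ptss) >= 10L) {
    motifs <- lapply(c(minus10 = "minus10", minus35 = "minus35"), function(which) {
      spec <- motif_window_spec(which)
      sets <- extract_window_sets(ptss, config$genome, spec)
      pwm <- oops_em(sets$positive, config$motif_width,
                     negative = sets$negative, seed = config$seed)
      enr <- score_enrichment(pwm, sets$positive, sets$negative,
                              n_perm = config$n_perm, seed = config$seed)
      list(spec = spec, sets = sets, pwm = pwm, enrichment = enr)
    })
    note("motifs", nrow(ptss), length(motifs))
  }

  comparison <- NULL
  if (!is.null(config$reference)) {
    comparison <- match_reference(annotated, config$reference)
    note("reference_compare", nrow(config$reference), sum(comparison$matched))
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_tss_outputs(annotated,
                      file.path(config$outdir, "tss_annotated.tsv"),
                      file.path(config$outdir, "tss_annotated.gff3"))
    utils::write.table(as.data.frame(flt$removed),
                       file.path(config$outdir, "tss_removed_trna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(motifs)) {
      for (nm in names(motifs)) {
        writeLines(paste0(">", names(motifs[[nm]]$sets$positive), "\n",
                          motifs[[nm]]$sets$positive),
                   file.path(config$outdir, paste0(nm, "_positive.fa")))
        writeLines(paste0(">", names(motifs[[nm]]$sets$negative), "\n",
                          motifs[[nm]]$sets$negative),
                   file.path(config$outdir, paste0(nm, "_negative.fa")))
        utils::write.table(consensus_report(motifs[[nm]]$pwm),
                           file.path(config$outdir, paste0(nm, "_pwm.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    manifest_lines <- c(sprintf("seed\t%d", config$seed),
                        vapply(names(manifest$stages), function(s)
                          sprintf("%s\t%d\t%d", s, manifest$stages[[s]]["n_in"],
                                  manifest$stages[[s]]["n_out"]), ""))
    writeLines(manifest_lines, file.path(config$outdir, "run_manifest.tsv"))
  }

  structure(list(calls = curated, tss = annotated, summary = summ,
                 motifs = motifs, comparison = comparison, manifest = manifest),
            class = "tss_pipeline_result")
}

#' @export
print.tss_pipeline_result <- function(x, ...) {
  cat("<tss_pipeline_result>\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-24s %6d -> %6d\n", s,
                x$manifest$stages[[s]]["n_in"], x$manifest$stages[[s]]["n_out"]))
  }
  print(x$summary)
  if (!is.null(x$motifs)) {
    for (nm in names(x$motifs)) {
      cat(sprintf("  %s consensus: %s (enrichment %.2f bits, perm p = %.3g)\n",
                  nm, x$motifs[[nm]]$pwm$consensus,
                  x$motifs[[nm]]$enrichment$statistic,
                  x$motifs[[nm]]$enrichment$p_value))
    }
  }
  invisible(x)
}
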