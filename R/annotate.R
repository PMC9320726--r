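#' Positional classification parameters
#'
#' @param primary_window nt upstream of a gene start within which a
#'   same-strand TSS is primary (`P`); a TSS at offset 0 (the gene start
#'   itself, a leaderless transcript) is also primary.
#' @param antisense_margin nt beyond an opposite-strand gene within which a
#'   TSS is downstream-antisense (`Ad`).
#' @param leaderless_max maximum 5'UTR length (nt) of a leaderless mRNA.
#' @param utr_max maximum reportable 5'UTR length (equals `primary_window`).
#' @return list of class `class_params`.
#' @export
class_params <- function(primary_window = 250L, antisense_margin = 30L,
                         leaderless_max = 9L, utr_max = 250L) {
  stopifnot(primary_window >= 0, antisense_margin >= 0,
            leaderless_max >= 0, leaderless_max < utr_max)
  structure(list(primary_window = as.integer(primary_window),
                 antisense_margin = as.integer(antisense_margin),
                 leaderless_max = as.integer(leaderless_max),
                 utr_max = as.integer(utr_max)),
            class = "class_params")
}

# Classify one position. Returns the accumulated label set, the exclusive
# label under the precedence P > I > Ai > Ad > O, the linked gene per label
# and the 5'UTR length when primary.
classify_position <- function(replicon, position, strand, features, params) {
  same <- features$replicon == replicon & features$strand == strand
  anti <- features$replicon == replicon & features$strand != strand
  labels <- character(0)
  gene_p <- gene_i <- gene_a <- NA_character_
  utr <- NA_integer_

  if (any(same)) {
    fs <- features[same, , drop = FALSE]
    off <- ifelse(fs$strand == "+", fs$start - position, position - fs$end)
    hit <- off >= 0L & off <= params$primary_window
    if (any(hit)) {
      labels <- c(labels, "P")
      j <- which(hit)[which.min(off[hit])]
      gene_p <- fs$locus_tag[j]
      utr <- as.integer(off[j])
    }
    inside <- position >= fs$start & position <= fs$end
    if (any(inside)) {
      labels <- c(labels, "I")
      gene_i <- fs$locus_tag[which(inside)[1L]]
    }
  }
  if (any(anti)) {
    fa <- features[anti, , drop = FALSE]
    inside <- position >= fa$start & position <= fa$end
    dist <- pmax(fa$start - position, position - fa$end)  # > 0 when outside
    marg <- !inside & dist >= 1L & dist <= params$antisense_margin
    if (any(inside)) {
      labels <- c(labels, "Ai")
      gene_a <- fa$locus_tag[which(inside)[1L]]
    } else if (any(marg)) {
      labels <- c(labels, "Ad")
      gene_a <- fa$locus_tag[which(marg)[which.min(dist[marg])]]
    }
  }
  if (length(labels) == 0L) labels <- "O"
  precedence <- c("P", "I", "Ai", "Ad", "O")
  list(labels = labels,
       exclusive = precedence[min(match(labels, precedence))],
       linked_gene = if ("P" %in% labels) gene_p else
         if ("I" %in% labels) gene_i else
           if (any(c("Ai", "Ad") %in% labels)) gene_a else NA_character_,
       gene_p = gene_p, gene_i = gene_i, gene_a = gene_a,
       utr_length = utr)
}

#' Classify TSS calls relative to gene annotation
#'
#' Applies the positional rules: a TSS is primary (`P`) when a same-strand
#' gene start lies 0..`primary_window` nt downstream (nearest such gene is
#' linked and defines the 5'UTR), internal (`I`) when inside a same-strand
#' gene body, internal-antisense (`Ai`) when inside an opposite-strand gene,
#' downstream-antisense (`Ad`) when within `antisense_margin` nt beyond an
#' opposite-strand gene, and orphan (`O`) when none applies. Labels
#' accumulate (a TSS can be both internal to one gene and primary for the
#' next); `O` is exclusive. The `class_exclusive` column resolves
#' multi-labels by the precedence P > I > Ai > Ad.
#'
#' @param calls data frame with columns replicon, position, strand (e.g. a
#'   `tss_calls` object).
#' @param features a [feature_table()].
#' @param params a [class_params()].
#' @return the input with added columns `classes` (comma-joined label set),
#'   `class_exclusive`, `linked_gene`, `gene`, `utr_length`, `leaderless`.
#' @export
classify_tss <- function(calls, features, params = class_params()) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- classify_position(calls$replicon[i], calls$position[i],
                                  calls$strand[i], features, params)
  }
  calls$classes <- vapply(res, function(r) paste(r$labels, collapse = ","), "")
  calls$class_exclusive <- vapply(res, `[[`, "", "exclusive")
  calls$linked_gene <- vapply(res, `[[`, "", "linked_gene")
  calls$gene <- calls$linked_gene
  calls$utr_length <- vapply(res, function(r) as.integer(r$utr_length), 1L)
  calls$leaderless <- ifelse(is.na(calls$utr_length), NA,
                             calls$utr_length <= params$leaderless_max)
  class(calls) <- c("annotated_tss", "data.frame")
  calls
}

#' 5'UTR length between a TSS and its gene start
#'
#' Length 0 means the TSS coincides with the first base of the start codon
#' (a leaderless transcript). Plus strand: `gene_start - tss`; minus strand:
#' `tss - gene_end`.
#'
#' @param tss_position 1-based TSS position.
#' @param gene_start,gene_end gene coordinates (1-based inclusive).
#' @param strand `"+"` or `"-"` (shared by TSS and gene).
#' @return non-negative integer length in nt.
#' @export
compute_utr <- function(tss_position, gene_start, gene_end, strand) {
  len <- ifelse(strand == "+", gene_start - tss_position, tss_position - gene_end)
  if (any(len < 0)) {
    stop("negative 5'UTR length: TSS downstream of its linked gene start",
         call. = FALSE)
  }
  as.integer(len)
}

#' Summary tables for an annotated TSS set
#'
#' @param annotated output of [classify_tss()].
#' @param genome optional `DNAStringSet` for per-replicon densities.
#' @param params a [class_params()].
#' @return list of class `tss_summary` with elements `per_replicon`
#'   (TSS counts, density per Mb when the genome is given), `per_class`
#'   (exclusive-precedence counts/fractions), `per_label` (multi-label
#'   tallies over all label combinations), and `utr` (histogram table, mean,
#'   median, leaderless fraction over primary TSSs).
#' @export
summarize_tss <- function(annotated, genome = NULL, params = class_params()) {
  ann <- as.data.frame(annotated)
  empty_levels <- c("P", "I", "Ai", "Ad", "O")
  per_class <- as.data.frame(table(factor(ann$class_exclusive, empty_levels)),
                             stringsAsFactors = FALSE)
  names(per_class) <- c("class", "count")
  per_class$fraction <- if (nrow(ann)) per_class$count / nrow(ann) else 0
  per_label <- if (nrow(ann)) {
    tab <- as.data.frame(table(classes = ann$classes), stringsAsFactors = FALSE)
    names(tab) <- c("classes", "count")
    tab[order(-tab$count), , drop = FALSE]
  } else data.frame(classes = character(), count = integer())
  per_repl <- if (nrow(ann)) {
    tab <- as.data.frame(table(replicon = ann$replicon), stringsAsFactors = FALSE)
    names(tab) <- c("replicon", "count")
    tab
  } else data.frame(replicon = character(), count = integer())
  if (!is.null(genome)) {
    len <- stats::setNames(Biostrings::width(genome), names(genome))
    per_repl <- data.frame(replicon = names(len),
                           length = as.integer(len),
                           count = as.integer(per_repl$count[
                             match(names(len), per_repl$replicon)]))
    per_repl$count[is.na(per_repl$count)] <- 0L
    per_repl$per_mb <- per_repl$count / (per_repl$length / 1e6)
  }
  utrs <- ann$utr_length[!is.na(ann$utr_length)]
  utr <- list(
    histogram = if (length(utrs)) as.data.frame(table(utr_length = utrs),
                                                stringsAsFactors = FALSE)
    else data.frame(utr_length = character(), Freq = integer()),
    mean = if (length(utrs)) mean(utrs) else NA_real_,
    median = if (length(utrs)) stats::median(utrs) else NA_real_,
    leaderless_fraction = if (length(utrs))
      mean(utrs <= params$leaderless_max) else NA_real_,
    n = length(utrs))
  structure(list(per_replicon = per_repl, per_class = per_class,
                 per_label = per_label, utr = utr, n = nrow(ann)),
            class = "tss_summary")
}

#' @export
print.tss_summary <- function(x, ...) {
  cat(sprintf("<tss_summary> %d TSSs\n", x$n))
  cat("  exclusive classes (P > I > Ai > Ad > O):\n")
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("    %-3s %6d  (%.1f%%)\n", x$per_class$class[i],
                x$per_class$count[i], 100 * x$per_class$fraction[i]))
  }
  if (x$utr$n) {
    cat(sprintf("  5'UTR (primary TSSs, n=%d): mean %.1f nt, median %.0f nt, %.1f%% leaderless\n",
                x$utr$n, x$utr$mean, x$utr$median,
                100 * x$utr$leaderless_fraction))
  }
  invisible(x)
}
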