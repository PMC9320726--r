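#' Read a multi-replicon genome from FASTA
#'
#' Returns the genome as an uppercase [Biostrings::DNAStringSet] keyed by
#' replicon name (first whitespace-delimited token of each header). This is
#' the coordinate frame for all downstream positions, which are 1-based
#' inclusive throughout the package.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  gs <- Biostrings::readDNAStringSet(path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  if (anyDuplicated(names(gs))) stop("duplicate replicon names in ", path, call. = FALSE)
  gs <- Biostrings::DNAStringSet(toupper(as.character(gs)))
  bad <- grepl("[^ACGTN]", as.character(gs))
  if (any(bad)) {
    stop("replicon ", names(gs)[bad][1], " contains letters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  gs
}

#' @rdname read_fasta
#' @param genome a named `DNAStringSet` (or named character vector).
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read gene/tRNA annotation from GFF3
#'
#' Parses a GFF3 file into a [feature_table()]. Rows of type `gene` or `CDS`
#' become `"gene"` features, `tRNA` rows become `"tRNA"` features (a tRNA row
#' shadowing a gene row with the same locus tag wins); all other types are
#' ignored. Locus tags are taken from the `locus_tag` attribute, falling back
#' to `ID`. Files are validated line by line first so that malformed rows are
#' reported with their line number.
#'
#' @param path path to a GFF3 file.
#' @param genome optional `DNAStringSet`; when supplied, feature coordinates
#'   are checked against replicon lengths.
#' @return a `feature_table`.
#' @export
read_gff3 <- function(path, genome = NULL) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) stop("GFF3 line ", i, ": fewer than 9 columns", call. = FALSE)
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e)) stop("GFF3 line ", i, ": non-integer coordinates", call. = FALSE)
    if (e < s) stop("GFF3 line ", i, ": end < start", call. = FALSE)
    if (!f[7] %in% c("+", "-", ".")) stop("GFF3 line ", i, ": unknown strand '", f[7], "'", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "CDS", "tRNA")
  gr <- gr[keep]
  if (length(gr) == 0L) return(feature_table())
  tag <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else rep(NA_character_, length(gr))
  if (!is.null(gr$ID)) tag[is.na(tag)] <- as.character(gr$ID)[is.na(tag)]
  if (anyNA(tag)) stop("GFF3 feature without locus_tag/ID attribute", call. = FALSE)
  df <- data.frame(replicon = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = ifelse(as.character(gr$type) == "tRNA", "tRNA", "gene"),
                   locus_tag = tag, stringsAsFactors = FALSE)
  # a locus annotated as both gene/CDS and tRNA is a tRNA
  df <- df[order(df$locus_tag, df$type != "tRNA"), ]
  df <- df[!duplicated(df$locus_tag), ]
  if (!is.null(genome)) {
    len <- stats::setNames(Biostrings::width(genome), names(genome))
    if (!all(df$replicon %in% names(len))) {
      stop("GFF3 replicon not present in genome: ",
           setdiff(df$replicon, names(len))[1], call. = FALSE)
    }
    if (any(df$end > len[df$replicon])) stop("feature beyond replicon end", call. = FALSE)
  }
  feature_table(df$replicon, df$start, df$end, df$strand, df$type, df$locus_tag)
}

#' @rdname read_gff3
#' @param features a `feature_table`.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(features$replicon,
                               IRanges::IRanges(features$start, features$end),
                               strand = features$strand)
  gr$type <- features$type
  gr$locus_tag <- features$locus_tag
  gr$ID <- features$locus_tag
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert aligned reads to a 5'-end count profile
#'
#' Each primary, mapped alignment contributes one count at its 5'-most
#' genomic base: the leftmost reference position for forward-strand
#' alignments and the rightmost for reverse-strand alignments. Secondary,
#' supplementary and unmapped records are ignored. SAM input is converted to
#' BAM in a temporary file first.
#'
#' @param path SAM or BAM file of aligned 5'-end reads.
#' @inheritParams end_profile
#' @return an `end_profile`.
#' @export
alignments_to_end_profile <- function(path, library_kind = c("plus_lib", "minus_lib"),
                                      condition = 1L, replicate = 1L) {
  library_kind <- match.arg(library_kind)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(path, param = param)
  if (length(aln) == 0L) {
    return(end_profile(library_kind = library_kind,
                       condition = condition, replicate = replicate))
  }
  str <- as.character(GenomicAlignments::strand(aln))
  pos5 <- ifelse(str == "+", GenomicAlignments::start(aln), GenomicAlignments::end(aln))
  key <- paste(as.character(GenomicAlignments::seqnames(aln)), str, pos5, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  end_profile(replicon = vapply(parts, `[`, "", 1L),
              strand = vapply(parts, `[`, "", 2L),
              pos = as.integer(vapply(parts, `[`, "", 3L)),
              count = as.integer(tab),
              library_kind = library_kind, condition = condition, replicate = replicate)
}

#' Read or write a strand pair of bedGraph coverage files
#'
#' One bedGraph per strand. bedGraph intervals are 0-based half-open per the
#' UCSC convention and are converted to the internal 1-based inclusive
#' representation at this boundary; multi-base intervals are expanded to
#' per-position counts.
#'
#' @param path_plus,path_minus bedGraph files for the "+" and "-" genomic
#'   strands.
#' @inheritParams end_profile
#' @return `read_bedgraph_pair`: an `end_profile`.
#' @export
read_bedgraph_pair <- function(path_plus, path_minus,
                               library_kind = c("plus_lib", "minus_lib"),
                               condition = 1L, replicate = 1L) {
  library_kind <- match.arg(library_kind)
  one <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) {
      return(data.frame(replicon = character(), strand = character(),
                        pos = integer(), count = integer()))
    }
    if (any(gr$score < 0)) stop("negative count in ", path, call. = FALSE)
    if (!GenomicRanges::isDisjoint(gr)) {
      stop("overlapping intervals in ", path, call. = FALSE)
    }
    gr <- gr[gr$score > 0]
    n <- GenomicRanges::width(gr)
    data.frame(
      replicon = rep(as.character(GenomicRanges::seqnames(gr)), n),
      strand = strand,
      pos = unlist(lapply(seq_along(gr), function(i)
        GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]), use.names = FALSE),
      count = rep(as.integer(round(gr$score)), n),
      stringsAsFactors = FALSE)
  }
  df <- rbind(one(path_plus, "+"), one(path_minus, "-"))
  end_profile(df$replicon, df$strand, df$pos, df$count,
              library_kind = library_kind, condition = condition, replicate = replicate)
}

#' @rdname read_bedgraph_pair
#' @param profile an `end_profile`.
#' @return `write_bedgraph_pair`: the two paths, invisibly.
#' @export
write_bedgraph_pair <- function(profile, path_plus, path_minus) {
  one <- function(df, path) {
    # one line per non-zero position: "chrom (pos-1) pos count"
    lines <- sprintf("%s\t%d\t%d\t%d", df$replicon, df$pos - 1L, df$pos, df$count)
    writeLines(lines, path)
  }
  one(profile[profile$strand == "+", , drop = FALSE], path_plus)
  one(profile[profile$strand == "-", , drop = FALSE], path_minus)
  invisible(c(path_plus, path_minus))
}

#' Write annotated TSSs as TSV and GFF3
#'
#' Writes the final TSS table with a stable column order
#' (replicon, position, strand, classes, gene, utr_length, leaderless,
#' k_plus, k_minus, p_value, conditions_detected) and a companion GFF3 with
#' one `TSS` feature per row.
#'
#' @param annotated data frame from [classify_tss()].
#' @param tsv_path,gff_path output paths (either may be `NULL` to skip).
#' @export
write_tss_outputs <- function(annotated, tsv_path = NULL, gff_path = NULL) {
  cols <- c("replicon", "position", "strand", "classes", "gene", "utr_length",
            "leaderless", "k_plus", "k_minus", "p_value", "conditions_detected")
  out <- as.data.frame(annotated)
  if (is.null(out$gene)) out$gene <- out$linked_gene
  if (is.null(out$conditions_detected)) out$conditions_detected <- out$condition
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  out <- out[cols]
  if (!is.null(tsv_path)) {
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(gff_path)) {
    attrs <- sprintf("ID=TSS%05d;classes=%s%s", seq_len(nrow(out)), out$classes,
                     ifelse(is.na(out$gene) | out$gene == "", "",
                            paste0(";gene=", out$gene)))
    lines <- c("##gff-version 3",
               sprintf("%s\ttssmapr\tTSS\t%d\t%d\t.\t%s\t.\t%s",
                       out$replicon, out$position, out$position, out$strand, attrs))
    writeLines(lines, gff_path)
  }
  invisible(out)
}

#' Read a TSS TSV written by [write_tss_outputs()]
#' @param path TSV path.
#' @return a data frame.
#' @export
read_tss_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "")
}
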