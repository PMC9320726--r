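#' Strand-specific 5'-end count profile
#'
#' An `end_profile` is a sparse per-position map of 5'-end read counts for one
#' sequencing library: one of the enriched ("+", `plus_lib`) or untreated
#' ("-", `minus_lib`) dRNA-seq banks, for one condition and replicate. It is a
#' plain data frame with columns `replicon`, `strand`, `pos` (1-based) and
#' `count` (positive integers); positions with zero reads are not stored.
#'
#' @param replicon character vector of replicon names.
#' @param strand character vector, "+" or "-" (the genomic strand the 5' end
#'   maps to, not the library kind).
#' @param pos integer vector of 1-based positions.
#' @param count integer vector of read counts (>= 1).
#' @param library_kind `"plus_lib"` (5'PP-treated, primary-end enriched) or
#'   `"minus_lib"` (untreated control).
#' @param condition,replicate identifiers recorded as attributes.
#' @return an object of class `end_profile`.
#' @export
end_profile <- function(replicon = character(), strand = character(),
                        pos = integer(), count = integer(),
                        library_kind = c("plus_lib", "minus_lib"),
                        condition = 1L, replicate = 1L) {
  library_kind <- match.arg(library_kind)
  df <- data.frame(replicon = as.character(replicon),
                   strand = as.character(strand),
                   pos = as.integer(pos),
                   count = as.integer(count),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$count < 1L)) stop("end_profile counts must be >= 1", call. = FALSE)
    if (any(df$pos < 1L)) stop("end_profile positions must be >= 1", call. = FALSE)
    if (!all(df$strand %in% c("+", "-"))) {
      stop("end_profile strand must be '+' or '-'", call. = FALSE)
    }
    df <- df[order(df$replicon, df$strand, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    if (anyDuplicated(df[c("replicon", "strand", "pos")])) {
      stop("duplicate positions in end_profile", call. = FALSE)
    }
  }
  structure(df, class = c("end_profile", "data.frame"),
            library_kind = library_kind,
            condition = condition, replicate = replicate)
}

#' Total read count of a profile
#' @param x an `end_profile`.
#' @return the sum of stored counts.
#' @export
total_count <- function(x) {
  stopifnot(inherits(x, "end_profile"))
  sum(x$count)
}

#' @export
print.end_profile <- function(x, ...) {
  cat(sprintf("<end_profile> %s library, condition %s, replicate %s\n",
              if (attr(x, "library_kind") == "plus_lib") "\"+\"" else "\"-\"",
              attr(x, "condition"), attr(x, "replicate")))
  cat(sprintf("  %d non-zero positions on %d replicon/strand tracks, %d reads total\n",
              nrow(x), nrow(unique(x[c("replicon", "strand")])), sum(x$count)))
  invisible(x)
}

#' Stranded gene/tRNA feature table
#'
#' Builds the annotation table used throughout the pipeline: one row per
#' feature with 1-based inclusive coordinates, strand, a `type` of `"gene"`
#' or `"tRNA"`, and a unique locus tag.
#'
#' @param replicon,start,end,strand,type,locus_tag parallel vectors.
#' @return a data frame of class `feature_table`.
#' @export
feature_table <- function(replicon = character(), start = integer(),
                          end = integer(), strand = character(),
                          type = character(), locus_tag = character()) {
  df <- data.frame(replicon = as.character(replicon),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), type = as.character(type),
                   locus_tag = as.character(locus_tag),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start > df$end)) stop("feature start > end", call. = FALSE)
    if (!all(df$strand %in% c("+", "-"))) stop("feature strand must be '+' or '-'", call. = FALSE)
    if (!all(df$type %in% c("gene", "tRNA"))) stop("feature type must be 'gene' or 'tRNA'", call. = FALSE)
    if (anyDuplicated(df$locus_tag)) stop("locus_tags must be unique", call. = FALSE)
    df <- df[order(df$replicon, df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

# strand-aware gene start / end (transcriptional orientation)
feature_tss_side <- function(features) {
  ifelse(features$strand == "+", features$start, features$end)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features (%d gene, %d tRNA) on %d replicon(s)\n",
              nrow(x), sum(x$type == "gene"), sum(x$type == "tRNA"),
              length(unique(x$replicon))))
  invisible(x)
}

profile_track <- function(profile, replicon, strand) {
  profile[profile$replicon == replicon & profile$strand == strand, , drop = FALSE]
}

# all (replicon, strand) tracks present in either of two profiles
shared_tracks <- function(...) {
  keys <- unique(do.call(rbind, lapply(list(...), function(p)
    unique(as.data.frame(p)[c("replicon", "strand")]))))
  keys[order(keys$replicon, keys$strand), , drop = FALSE]
}
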