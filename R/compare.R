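#' Load the packaged table of previously published TSSs
#'
#' A hand-curated table of TSSs for one-carbon-metabolism genes of
#' *Methylorubrum extorquens* DM4/AM1 and related strains, mapped earlier by
#' nuclease S1, primer extension or run-off transcription, together with the
#' dRNA-seq positions for strain DM4. Used to benchmark called TSSs against
#' orthogonal methods (positional offsets, 5'UTR differences, promoter-box
#' spacers).
#'
#' @param path optional path to an alternative reference TSV with the same
#'   columns (gene, strain, method, promoter, replicon, position, strand,
#'   utr_length, minus35_box, minus10_box, spacer, comment).
#' @return a data frame of class `reference_tss`.
#' @export
read_reference_tss <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_tss_dm4.tsv", package = "tssmapr")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "", na.strings = "NA")
  if (any(is.na(df$position) & is.na(df$utr_length))) {
    stop("reference rows need at least one of position/utr_length", call. = FALSE)
  }
  class(df) <- c("reference_tss", "data.frame")
  df
}

#' Match called TSSs against reference positions
#'
#' Each reference entry carrying a genomic position is matched to the
#' nearest same-strand call within `tolerance` nt; the signed offset is
#' `call - reference`. Two equidistant calls are resolved 5'-most and the
#' tie is flagged. References without a match are reported with `NA` offset.
#'
#' @param calls data frame with replicon, position, strand.
#' @param references a `reference_tss` table (rows without positions are
#'   ignored).
#' @param tolerance maximum |offset| in nt (default 5, covering the 0-4 nt
#'   method-to-method shifts seen between dRNA-seq and nuclease S1).
#' @return data frame with one row per positioned reference: gene, promoter,
#'   reference position, matched call position, signed `offset`, `matched`,
#'   `tie`.
#' @export
match_reference <- function(calls, references, tolerance = 5L) {
  calls <- as.data.frame(calls)
  refs <- as.data.frame(references)
  refs <- refs[!is.na(refs$position), , drop = FALSE]
  out <- lapply(seq_len(nrow(refs)), function(i) {
    r <- refs[i, ]
    same <- calls$replicon == r$replicon & calls$strand == r$strand
    cand <- calls$position[same]
    d <- cand - r$position
    ok <- abs(d) <= tolerance
    row <- data.frame(gene = r$gene, promoter = r$promoter,
                      reference_position = r$position, strand = r$strand,
                      call_position = NA_integer_, offset = NA_integer_,
                      matched = FALSE, tie = FALSE, stringsAsFactors = FALSE)
    if (any(ok)) {
      cand <- cand[ok]; d <- d[ok]
      nearest <- abs(d) == min(abs(d))
      row$tie <- sum(nearest) > 1L
      pick <- if (r$strand == "+") which.min(cand * ifelse(nearest, 1, NA))
      else which.max(cand * ifelse(nearest, 1, NA))
      row$call_position <- cand[pick]
      row$offset <- d[pick]
      row$matched <- TRUE
    }
    row
  })
  do.call(rbind, out)
}

#' Signed 5'UTR difference between two reference entries
#'
#' @param a,b rows of a `reference_tss` table (or any lists with
#'   `utr_length` and `gene`) describing the same gene.
#' @return `a$utr_length - b$utr_length` (signed nt).
#' @export
utr_offset <- function(a, b) {
  if (is.na(a$utr_length) || is.na(b$utr_length)) {
    stop("both entries must carry a 5'UTR length", call. = FALSE)
  }
  if (!identical(a$gene, b$gene)) {
    stop("5'UTR offsets are only meaningful within one gene", call. = FALSE)
  }
  as.integer(a$utr_length) - as.integer(b$utr_length)
}

#' Spacer length between -35 and -10 promoter boxes
#'
#' Counts the nucleotides strictly between the end of the -35 box match and
#' the start of the -10 box match in a promoter sequence. When a box occurs
#' several times, the in-order, non-overlapping pair with the shortest
#' spacer is used. The canonical bacterial sigma-70 spacer is ~17 nt with
#' variation between 15 and 20 nt; `typical` flags that range.
#'
#' @param sequence promoter-region sequence (5' to 3').
#' @param minus35_box,minus10_box box sequences as they read on `sequence`.
#' @return list with `spacer` (nt) and `typical` (logical).
#' @export
spacer_length <- function(sequence, minus35_box, minus10_box) {
  sequence <- toupper(sequence)
  m35 <- gregexpr(toupper(minus35_box), sequence, fixed = TRUE)[[1]]
  m10 <- gregexpr(toupper(minus10_box), sequence, fixed = TRUE)[[1]]
  if (m35[1] == -1L) stop("-35 box not found in sequence", call. = FALSE)
  if (m10[1] == -1L) stop("-10 box not found in sequence", call. = FALSE)
  w35 <- nchar(minus35_box)
  best <- NULL
  for (s35 in as.integer(m35)) {
    e35 <- s35 + w35 - 1L
    after <- as.integer(m10)[as.integer(m10) > e35]
    if (length(after) == 0L) next
    sp <- min(after) - e35 - 1L
    if (is.null(best) || sp < best) best <- sp
  }
  if (is.null(best)) {
    stop("boxes only occur overlapping or out of order", call. = FALSE)
  }
  list(spacer = as.integer(best), typical = best >= 15L && best <= 20L)
}
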