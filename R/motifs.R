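#' Promoter window specification
#'
#' TSS-relative windows used to build motif search sets. The `minus10`
#' positive set is the 20 nt immediately upstream of each TSS (offsets -20
#' to -1); the `minus35` positive set is the 20-nt window ending 15 nt
#' upstream (offsets -35 to -16, centred where the -35 box sits given the
#' canonical ~17-nt spacer). The negative set for both is the 20-nt window
#' at +100 downstream (offsets +100 to +119).
#'
#' @param name `"minus10"` or `"minus35"`.
#' @param positive_offsets,negative_offsets closed TSS-relative offset
#'   intervals `c(from, to)`; both must have the same length and the positive
#'   interval must exclude offset 0.
#' @return list of class `motif_window_spec`.
#' @export
motif_window_spec <- function(name = c("minus10", "minus35"),
                              positive_offsets = NULL,
                              negative_offsets = c(100L, 119L)) {
  name <- match.arg(name)
  if (is.null(positive_offsets)) {
    positive_offsets <- if (name == "minus10") c(-20L, -1L) else c(-35L, -16L)
  }
  w <- diff(positive_offsets) + 1L
  if (w != diff(negative_offsets) + 1L) {
    stop("positive and negative windows must have equal length", call. = FALSE)
  }
  if (positive_offsets[1] <= 0L && positive_offsets[2] >= 0L) {
    stop("positive window must exclude offset 0 (the TSS itself)", call. = FALSE)
  }
  structure(list(name = name, positive_offsets = as.integer(positive_offsets),
                 negative_offsets = as.integer(negative_offsets),
                 width = as.integer(w)),
            class = "motif_window_spec")
}

#' Extract promoter window sets around TSSs
#'
#' For each TSS the strand-aware subsequence at the spec's offset interval
#' is taken: on the plus strand, offset -1 is the base immediately left of
#' the TSS; on the minus strand offsets count rightward and the window is
#' reverse-complemented. TSSs whose windows run off the replicon are skipped
#' and counted.
#'
#' @param tss data frame with replicon, position, strand (typically the
#'   primary/IP subset of an annotated TSS table).
#' @param genome a `DNAStringSet`.
#' @param spec a [motif_window_spec()].
#' @return list with character vectors `positive` and `negative` (named by
#'   TSS coordinate) and `n_skipped`.
#' @export
extract_window_sets <- function(tss, genome, spec = motif_window_spec("minus10")) {
  tss <- as.data.frame(tss)
  if (nrow(tss) == 0L) stop("empty TSS set", call. = FALSE)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  seqs <- stats::setNames(as.character(genome), names(genome))
  grab <- function(offsets) {
    out <- character(0); skipped <- 0L
    for (i in seq_len(nrow(tss))) {
      p <- tss$position[i]; rn <- tss$replicon[i]
      if (tss$strand[i] == "+") {
        from <- p + offsets[1]; to <- p + offsets[2]
      } else {
        from <- p - offsets[2]; to <- p - offsets[1]
      }
      if (from < 1L || to > lens[[rn]]) { skipped <- skipped + 1L; next }
      s <- substr(seqs[[rn]], from, to)
      if (tss$strand[i] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      out[paste0(rn, ":", p, tss$strand[i])] <- s
    }
    list(seqs = out, skipped = skipped)
  }
  pos <- grab(spec$positive_offsets)
  neg <- grab(spec$negative_offsets)
  list(positive = pos$seqs, negative = neg$seqs,
       n_skipped = pos$skipped + neg$skipped)
}

BASES <- c("A", "C", "G", "T")

seq_matrix <- function(seqs) {
  t(vapply(strsplit(toupper(seqs), ""), function(ch) {
    ch[!ch %in% BASES] <- "A"   # ambiguity codes carry no motif information
    match(ch, BASES)
  }, integer(nchar(seqs[1]))))
}

base_frequencies <- function(seqs) {
  ch <- unlist(strsplit(toupper(paste(seqs, collapse = "")), ""))
  ch <- ch[ch %in% BASES]
  tab <- table(factor(ch, BASES))
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(pmax(p, 1e-9) / sum(pmax(p, 1e-9)), BASES)
}

# exact k-mers most enriched in the positive set relative to the negative
# set, ties broken towards words least likely under the background (the most
# surprising word seeds the EM when the sets do not discriminate)
discriminative_seeds <- function(positive, negative, width, bg, n_seeds = 5L) {
  kmers <- function(seqs) {
    unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < width) character(0) else
        substring(s, 1:(n - width + 1), width:n)
    }))
  }
  kp <- table(kmers(positive))
  kn <- table(kmers(negative))
  words <- names(kp)
  enr <- log((as.numeric(kp) + 1) / (as.numeric(kn[words]) %|NA|% 0 + 1))
  bg_ll <- vapply(strsplit(words, ""), function(ch) sum(log(bg[ch])), 0)
  ord <- order(-enr, bg_ll, words)
  words[utils::head(ord, n_seeds)]
}

`%|NA|%` <- function(x, default) { x[is.na(x)] <- default; x }

#' One-occurrence-per-sequence (OOPS) EM motif finder
#'
#' Fits a single position weight matrix of the given width to a set of
#' equal-length sequences under the OOPS model: each sequence contains
#' exactly one motif occurrence at an unknown position, all other positions
#' follow a fixed background (estimated from the negative window set). The
#' E-step computes each sequence's posterior over motif start positions
#' under the current PWM; the M-step re-estimates the PWM from
#' posterior-weighted base counts with a pseudocount of 0.25 per cell.
#' Initialization is discriminative: the exact k-mer most enriched in the
#' positive relative to the negative set seeds the first PWM. Iteration
#' stops when the penalized log-likelihood improves by less than `tol` or at
#' `max_iter`.
#'
#' The recorded `log_likelihood` trace is the EM objective including the
#' Dirichlet(0.25) pseudocount prior term, which is guaranteed
#' non-decreasing; it is the quantity asserted by the monotonicity
#' invariant.
#'
#' @param positive character vector of equal-length sequences (>= width nt).
#' @param width motif width in nt (>= 4).
#' @param negative character vector used for the background composition (and
#'   the discriminative seed); defaults to the positive set itself.
#' @param seed integer; kept for interface symmetry (the fit is
#'   deterministic given its initialization) and used by downstream
#'   permutation scoring.
#' @param max_iter,tol stopping rule.
#' @return an object of class `pwm_model`: `theta` (4 x width column-
#'   stochastic matrix), `background`, `consensus`, `ic` (2 - entropy bits
#'   per column), `relative_entropy` (per column vs background),
#'   `log_likelihood` (trace), `width`, `n_sequences`, `seed`.
#' @export
oops_em <- function(positive, width, negative = NULL, seed = 1L,
                    max_iter = 200L, tol = 1e-6) {
  if (width < 4L) stop("motif width must be at least 4", call. = FALSE)
  short <- nchar(positive) < width
  if (any(short)) {
    stop("sequence shorter than motif width: ",
         names(positive)[short][1] %|NA|% positive[short][1], call. = FALSE)
  }
  if (length(unique(nchar(positive))) != 1L) {
    stop("OOPS sequences must have equal length", call. = FALSE)
  }
  if (is.null(negative) || length(negative) == 0L) negative <- positive
  bg <- base_frequencies(negative)
  X <- seq_matrix(positive)           # n x L base indices
  n <- nrow(X); L <- ncol(X); m <- L - width + 1L
  log_bg_seq <- rowSums(matrix(log(bg)[X], n, L))
  pseudo <- 0.25

  em_from <- function(seedword) {
    theta <- matrix(0.1 / 3, 4L, width, dimnames = list(BASES, NULL))
    theta[cbind(match(strsplit(seedword, "")[[1]], BASES), seq_len(width))] <- 0.9
    ll_trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      lt <- log(theta); lb <- log(bg)
      # log odds of a motif window starting at column j of each sequence
      lo <- matrix(0, n, m)
      for (j in seq_len(m)) {
        idx <- X[, j:(j + width - 1L), drop = FALSE]
        lo[, j] <- rowSums(matrix(lt[cbind(as.vector(idx),
                                           rep(seq_len(width), each = n))],
                                  n, width)) -
          rowSums(matrix(lb[idx], n, width))
      }
      mx <- apply(lo, 1L, max)
      wgt <- exp(lo - mx)
      Z <- wgt / rowSums(wgt)
      ll <- sum(log_bg_seq + mx + log(rowSums(wgt)) - log(m)) +
        pseudo * sum(log(theta))
      ll_trace <- c(ll_trace, ll)
      counts <- matrix(pseudo, 4L, width, dimnames = list(BASES, NULL))
      for (j in seq_len(m)) {
        for (c in seq_len(width)) {
          b <- X[, j + c - 1L]
          counts[, c] <- counts[, c] + vapply(1:4, function(bb)
            sum(Z[b == bb, j]), 0)
        }
      }
      theta_new <- sweep(counts, 2L, colSums(counts), "/")
      conv <- iter > 1L && (ll - ll_trace[iter - 1L]) < tol
      theta <- theta_new
      if (conv) break
    }
    list(theta = theta, ll_trace = ll_trace)
  }

  # multiple discriminative starts; keep the best-likelihood fit
  seeds <- discriminative_seeds(positive, negative, width, bg)
  fits <- lapply(seeds, em_from)
  finals <- vapply(fits, function(f) utils::tail(f$ll_trace, 1L), 0)
  best <- fits[[which.max(finals)]]
  theta <- best$theta
  ll_trace <- best$ll_trace
  consensus <- paste(BASES[apply(theta, 2L, which.max)], collapse = "")
  ic <- 2 + colSums(theta * log2(theta))
  relent <- colSums(theta * log2(theta / bg))
  structure(list(theta = theta, background = bg, consensus = consensus,
                 ic = ic, relative_entropy = relent,
                 log_likelihood = ll_trace, width = width,
                 n_sequences = n, seed = seed),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("<pwm_model> width %d, fitted to %d sequences in %d EM iterations\n",
              x$width, x$n_sequences, length(x$log_likelihood)))
  cat("  consensus:", x$consensus, "\n")
  cat("  IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' @export
logLik.pwm_model <- function(object, ...) {
  structure(utils::tail(object$log_likelihood, 1L),
            df = 3L * object$width, class = "logLik")
}

#' Text logo of a fitted PWM
#' @param x a `pwm_model`.
#' @param ... unused.
#' @export
consensus_report <- function(x, ...) {
  stopifnot(inherits(x, "pwm_model"))
  data.frame(column = seq_len(x$width),
             consensus = strsplit(x$consensus, "")[[1]],
             ic_bits = round(x$ic, 3),
             t(round(x$theta, 3)))
}

# best motif-window log-odds score of one sequence under a PWM
best_window_score <- function(seqs, pwm) {
  X <- seq_matrix(seqs)
  n <- nrow(X); L <- ncol(X); w <- pwm$width; m <- L - w + 1L
  lt <- log2(pwm$theta); lb <- log2(pwm$background)
  best <- rep(-Inf, n)
  for (j in seq_len(m)) {
    idx <- X[, j:(j + w - 1L), drop = FALSE]
    sc <- rowSums(matrix(lt[cbind(as.vector(idx), rep(seq_len(w), each = n))],
                         n, w)) -
      rowSums(matrix(lb[idx], n, w))
    best <- pmax(best, sc)
  }
  best
}

#' Differential motif enrichment score
#'
#' The statistic is the mean best-window log-odds score of the PWM in the
#' positive set minus the same in the negative set; its null distribution is
#' obtained by permuting the positive/negative labels.
#'
#' @param pwm a fitted [oops_em()] model.
#' @param positive,negative character vectors of sequences.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `statistic`, `p_value`, `n_perm`, and the per-set mean
#'   scores.
#' @export
score_enrichment <- function(pwm, positive, negative, n_perm = 1000L, seed = 1L) {
  sp <- best_window_score(positive, pwm)
  sn <- best_window_score(negative, pwm)
  stat <- mean(sp) - mean(sn)
  pool <- c(sp, sn)
  n1 <- length(sp)
  set.seed(seed)
  perm <- replicate(n_perm, {
    idx <- sample.int(length(pool), n1)
    mean(pool[idx]) - mean(pool[-idx])
  })
  list(statistic = stat,
       p_value = (1 + sum(perm >= stat)) / (n_perm + 1),
       n_perm = n_perm,
       mean_positive = mean(sp), mean_negative = mean(sn))
}
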