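#' TSS detection parameters
#'
#' Defaults are the stringent caller settings: at least 10 reads in the
#' enriched library at a candidate (`noise`), adjacent candidates at most
#' 1 nt apart fused into a single TSS (`merge`), and a raw one-sided Skellam
#' p-value threshold of 0.01 (`alpha`, no multiple-testing correction).
#'
#' @param noise minimum "+"-library read count at a candidate position.
#' @param merge maximum distance (nt) between adjacent significant positions
#'   fused into one TSS.
#' @param alpha p-value threshold.
#' @param rate_policy `"global_nonzero"` (one rate pair per replicon/strand,
#'   averaged over positions with at least one read in either library) or
#'   `"windowed"` (the same statistic within tiling windows of
#'   `window_width` nt).
#' @param window_width window size in nt for the windowed policy.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(noise = 10L, merge = 1L, alpha = 0.01,
                             rate_policy = c("global_nonzero", "windowed"),
                             window_width = 10000L) {
  rate_policy <- match.arg(rate_policy)
  stopifnot(noise >= 1, merge >= 0, alpha > 0, alpha < 1, window_width >= 1)
  structure(list(noise = as.integer(noise), merge = as.integer(merge),
                 alpha = alpha, rate_policy = rate_policy,
                 window_width = as.integer(window_width)),
            class = "detection_params")
}

#' Estimate per-library Poisson rates
#'
#' Rates are estimated over the union of positions carrying at least one
#' read in either library; untranscribed (all-zero) positions are excluded
#' so that the zero inflation of intergenic space does not dilute the rate.
#' Under the `windowed` policy the same statistic is computed inside tiling
#' windows and each position takes the value of its window.
#'
#' @param plus,minus `end_profile`s for the same libraries' "+" and "-"
#'   banks, restricted internally to one replicon/strand track.
#' @param replicon,strand track selector.
#' @param params a [detection_params()].
#' @return for `global_nonzero`: list with `lambda_plus`, `lambda_minus`,
#'   `n_positions`; for `windowed`: additionally a `lookup(pos)` function
#'   returning the per-position rate pair.
#' @export
estimate_rates <- function(plus, minus, replicon, strand,
                           params = detection_params()) {
  p <- profile_track(plus, replicon, strand)
  m <- profile_track(minus, replicon, strand)
  pos <- sort(unique(c(p$pos, m$pos)))
  if (length(pos) == 0L) {
    return(list(lambda_plus = 0, lambda_minus = 0, n_positions = 0L,
                flagged_empty = TRUE))
  }
  kp <- stats::setNames(rep(0L, length(pos)), pos)
  kp[as.character(p$pos)] <- p$count
  km <- stats::setNames(rep(0L, length(pos)), pos)
  km[as.character(m$pos)] <- m$count
  if (params$rate_policy == "global_nonzero") {
    return(list(lambda_plus = mean(kp), lambda_minus = mean(km),
                n_positions = length(pos), flagged_empty = FALSE))
  }
  win <- (pos - 1L) %/% params$window_width
  lp <- tapply(kp, win, mean)
  lm <- tapply(km, win, mean)
  gp <- mean(kp); gm <- mean(km)
  lookup <- function(at) {
    w <- as.character((at - 1L) %/% params$window_width)
    l1 <- unname(lp[w]); l2 <- unname(lm[w])
    l1[is.na(l1)] <- gp; l2[is.na(l2)] <- gm
    list(lambda_plus = l1, lambda_minus = l2)
  }
  list(lambda_plus = gp, lambda_minus = gm, n_positions = length(pos),
       flagged_empty = FALSE, lookup = lookup)
}

#' Call TSSs by the position-wise Skellam test
#'
#' For every genomic position, the "+"-library count is tested against the
#' "-"-library count under a Skellam null with the estimated per-library
#' rates. Candidates must carry at least `noise` "+" reads and a positive
#' count difference; the one-sided p-value is `skellam_sf(k_plus - k_minus)`
#' and positions with p <= `alpha` are kept (raw p-values, matching the
#' caller this reimplements). Runs of significant positions at most `merge`
#' nt apart are fused into a single TSS, retaining the position with the
#' largest count difference (ties resolved 5'-most: smallest coordinate on
#' "+", largest on "-").
#'
#' @param plus,minus `end_profile`s of the enriched and control banks for
#'   one condition/replicate (all replicons/strands).
#' @param params a [detection_params()].
#' @param rates optional fixed rate pair `list(lambda_plus=, lambda_minus=)`
#'   applied to every track instead of estimating from the profiles (e.g.
#'   rates pooled across replicates).
#' @return data frame of class `tss_calls` with columns replicon, position,
#'   strand, k_plus, k_minus, diff, p_value, condition, support.
#' @export
call_tss <- function(plus, minus, params = detection_params(), rates = NULL) {
  stopifnot(inherits(plus, "end_profile"), inherits(minus, "end_profile"))
  if (attr(plus, "library_kind") != "plus_lib" ||
      attr(minus, "library_kind") != "minus_lib") {
    stop("call_tss expects (plus_lib, minus_lib) profiles in that order",
         call. = FALSE)
  }
  if (!identical(attr(plus, "condition"), attr(minus, "condition"))) {
    stop("profiles come from different conditions", call. = FALSE)
  }
  tracks <- shared_tracks(plus, minus)
  out <- list()
  for (i in seq_len(nrow(tracks))) {
    rn <- tracks$replicon[i]; st <- tracks$strand[i]
    track_rates <- if (is.null(rates)) estimate_rates(plus, minus, rn, st, params)
    else rates
    p <- profile_track(plus, rn, st)
    m <- profile_track(minus, rn, st)
    cand <- p[p$count >= params$noise, , drop = FALSE]
    if (nrow(cand) == 0L) next
    km <- stats::setNames(m$count, m$pos)[as.character(cand$pos)]
    km[is.na(km)] <- 0L
    d <- cand$count - km
    keep <- d > 0L
    cand <- cand[keep, , drop = FALSE]; km <- km[keep]; d <- d[keep]
    if (nrow(cand) == 0L) next
    if (params$rate_policy == "windowed" && !is.null(track_rates$lookup)) {
      lam <- track_rates$lookup(cand$pos)
      pv <- vapply(seq_len(nrow(cand)), function(j)
        skellam_sf(d[j], lam$lambda_plus[j], lam$lambda_minus[j]), 0)
    } else {
      pv <- vapply(d, skellam_sf, 0, lambda1 = track_rates$lambda_plus,
                   lambda2 = track_rates$lambda_minus)
    }
    keep <- pv <= params$alpha
    cand <- cand[keep, , drop = FALSE]; km <- km[keep]; d <- d[keep]; pv <- pv[keep]
    if (nrow(cand) == 0L) next
    ord <- order(cand$pos)
    calls <- data.frame(replicon = rn, position = cand$pos[ord], strand = st,
                        k_plus = cand$count[ord], k_minus = as.integer(km[ord]),
                        diff = d[ord], p_value = pv[ord],
                        stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- merge_adjacent(calls, params$merge, st)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicon = character(), position = integer(), strand = character(),
               k_plus = integer(), k_minus = integer(), diff = integer(),
               p_value = numeric(), stringsAsFactors = FALSE)
  res$condition <- rep(attr(plus, "condition"), nrow(res))
  res$support <- rep(1L, nrow(res))
  res <- res[order(res$replicon, res$strand, res$position), ]
  rownames(res) <- NULL
  class(res) <- c("tss_calls", "data.frame")
  res
}

# fuse runs of candidates <= merge nt apart; keep max diff, tie -> 5'-most
merge_adjacent <- function(calls, merge, strand) {
  if (nrow(calls) <= 1L) return(calls)
  gap <- diff(calls$position)
  grp <- cumsum(c(0L, as.integer(gap > merge)))
  keep <- vapply(split(seq_len(nrow(calls)), grp), function(idx) {
    d <- calls$diff[idx]
    best <- idx[d == max(d)]
    if (strand == "+") min(best) else max(best)
  }, 0L)
  calls[sort(keep), , drop = FALSE]
}

#' @export
print.tss_calls <- function(x, ...) {
  cat(sprintf("<tss_calls> %d TSSs on %d replicon/strand track(s)", nrow(x),
              nrow(unique(as.data.frame(x)[c("replicon", "strand")]))))
  if (nrow(x)) {
    cat(sprintf("; median k+ %d, median p %.2g", stats::median(x$k_plus),
                stats::median(x$p_value)))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.tss_calls <- function(object, ...) {
  df <- as.data.frame(object)
  list(n = nrow(df),
       per_track = if (nrow(df)) table(df$replicon, df$strand) else table(NULL),
       k_plus = if (nrow(df)) summary(df$k_plus) else NULL,
       p_value = if (nrow(df)) summary(df$p_value) else NULL)
}
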