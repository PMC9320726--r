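#' Curation parameters
#'
#' @param cluster_window nt window within which same-strand calls with
#'   similar read numbers are treated as one TSS observed with jitter.
#' @param similar_fold maximum "+"-count ratio for two calls to count as
#'   having "similar read numbers".
#' @param require_replicate_support `"any"` keeps the union of replicate
#'   calls, `"both"` keeps only positions supported (within
#'   `cluster_window`) in both replicates.
#' @param trna_upstream_window nt; calls with a same-strand tRNA start within
#'   this distance downstream are removed.
#' @return list of class `curation_params`.
#' @export
curation_params <- function(cluster_window = 10L, similar_fold = 2,
                            require_replicate_support = c("any", "both"),
                            trna_upstream_window = 250L) {
  require_replicate_support <- match.arg(require_replicate_support)
  stopifnot(cluster_window >= 0, similar_fold >= 1, trna_upstream_window >= 0)
  structure(list(cluster_window = as.integer(cluster_window),
                 similar_fold = similar_fold,
                 require_replicate_support = require_replicate_support,
                 trna_upstream_window = as.integer(trna_upstream_window)),
            class = "curation_params")
}

#' Consolidate TSS calls across biological replicates
#'
#' Calls at identical (replicon, position, strand) are merged with summed
#' counts and the number of supporting replicates recorded (the merged
#' p-value is the smaller of the two). Under `"any"` the union of the two
#' replicates is kept; under `"both"` only calls matched within
#' `cluster_window` nt in the other replicate survive.
#'
#' @param calls_rep1,calls_rep2 `tss_calls` from the same condition.
#' @param params a [curation_params()].
#' @return a consolidated `tss_calls` data frame.
#' @export
consolidate_replicates <- function(calls_rep1, calls_rep2,
                                   params = curation_params()) {
  a <- as.data.frame(calls_rep1); b <- as.data.frame(calls_rep2)
  if (nrow(a) && nrow(b) && !identical(a$condition[1], b$condition[1])) {
    stop("replicates come from different conditions", call. = FALSE)
  }
  both <- rbind(a, b)
  if (nrow(both) == 0L) {
    class(both) <- c("tss_calls", "data.frame")
    return(both)
  }
  key <- paste(both$replicon, both$strand, both$position, sep = "\r")
  agg <- do.call(rbind, lapply(split(seq_len(nrow(both)), key), function(idx) {
    r <- both[idx[1L], , drop = FALSE]
    r$k_plus <- sum(both$k_plus[idx])
    r$k_minus <- sum(both$k_minus[idx])
    r$diff <- r$k_plus - r$k_minus
    r$p_value <- min(both$p_value[idx])
    r$support <- length(idx)
    r
  }))
  if (params$require_replicate_support == "both") {
    near <- function(x, other) {
      vapply(seq_len(nrow(x)), function(i) {
        same <- other$replicon == x$replicon[i] & other$strand == x$strand[i]
        any(abs(other$position[same] - x$position[i]) <= params$cluster_window)
      }, TRUE)
    }
    supported <- agg$support >= 2L | (near(agg, a) & near(agg, b))
    agg <- agg[supported, , drop = FALSE]
  }
  agg <- agg[order(agg$replicon, agg$strand, agg$position), ]
  rownames(agg) <- NULL
  class(agg) <- c("tss_calls", "data.frame")
  agg
}

#' Resolve clusters of nearby similar TSS calls
#'
#' Same-strand calls within `cluster_window` nt of each other whose "+"
#' counts lie within `similar_fold` of one another form a cluster: jittered
#' observations of one TSS. Exactly one call per cluster is kept, preferring
#' (1) a member whose position is matched within `cluster_window` in the
#' other culture condition, then (2) the largest "+" count, then (3) the
#' 5'-most position. Calls not in any cluster pass through unchanged.
#'
#' @param calls `tss_calls` for one condition.
#' @param other_condition_calls `tss_calls` from the other condition (may be
#'   empty).
#' @param params a [curation_params()].
#' @return filtered `tss_calls`.
#' @export
cluster_and_select <- function(calls, other_condition_calls = NULL,
                               params = curation_params()) {
  # removing cluster members can leave two survivors that are newly similar
  # and nearby; re-apply until the call set is a fixed point
  repeat {
    res <- cluster_pass(calls, other_condition_calls, params)
    if (nrow(res) == nrow(calls)) return(res)
    calls <- res
  }
}

cluster_pass <- function(calls, other_condition_calls, params) {
  df <- as.data.frame(calls)
  if (nrow(df) <= 1L) return(calls)
  other <- if (is.null(other_condition_calls)) {
    data.frame(replicon = character(), position = integer(),
               strand = character(), stringsAsFactors = FALSE)
  } else as.data.frame(other_condition_calls)
  keep <- logical(nrow(df))
  for (tr in split(seq_len(nrow(df)),
                   paste(df$replicon, df$strand, sep = "\r"))) {
    tr <- tr[order(df$position[tr])]
    # chain: join the next call when it is within the window of the previous
    # member and the cluster stays fold-similar in k_plus
    grp <- integer(length(tr)); grp[1] <- 1L
    gmin <- df$k_plus[tr[1]]; gmax <- gmin
    for (j in seq_along(tr)[-1]) {
      close <- df$position[tr[j]] - df$position[tr[j - 1]] <= params$cluster_window
      nmin <- min(gmin, df$k_plus[tr[j]]); nmax <- max(gmax, df$k_plus[tr[j]])
      if (close && nmax <= params$similar_fold * nmin) {
        grp[j] <- grp[j - 1]; gmin <- nmin; gmax <- nmax
      } else {
        grp[j] <- grp[j - 1] + 1L
        gmin <- gmax <- df$k_plus[tr[j]]
      }
    }
    for (g in split(tr, grp)) {
      if (length(g) == 1L) { keep[g] <- TRUE; next }
      # preference 1: the member best matched in the other culture condition
      # (nearest other-condition call, considered only within the window)
      dist_other <- vapply(g, function(i) {
        same <- other$replicon == df$replicon[i] & other$strand == df$strand[i]
        d <- abs(other$position[same] - df$position[i])
        if (length(d) && min(d) <= params$cluster_window) min(d) else Inf
      }, 0)
      pool <- if (any(is.finite(dist_other))) g[dist_other == min(dist_other)]
      else g
      pool <- pool[df$k_plus[pool] == max(df$k_plus[pool])]
      pick <- if (df$strand[pool[1]] == "+") pool[which.min(df$position[pool])]
      else pool[which.max(df$position[pool])]
      keep[pick] <- TRUE
    }
  }
  res <- df[keep, , drop = FALSE]
  res <- res[order(res$replicon, res$strand, res$position), ]
  rownames(res) <- NULL
  class(res) <- c("tss_calls", "data.frame")
  res
}

#' Remove TSSs upstream of tRNA genes
#'
#' A call is removed iff a same-strand tRNA start lies within
#' `trna_upstream_window` nt downstream of it (0 = the tRNA start itself).
#' Removed calls are returned separately as an audit trail.
#'
#' @param calls `tss_calls`.
#' @param features a [feature_table()] containing the tRNA records.
#' @param params a [curation_params()].
#' @return list with elements `kept` and `removed`, both `tss_calls`.
#' @export
filter_trna <- function(calls, features, params = curation_params()) {
  df <- as.data.frame(calls)
  trna <- features[features$type == "tRNA", , drop = FALSE]
  if (nrow(df) == 0L || nrow(trna) == 0L) {
    empty <- df[0, , drop = FALSE]
    class(empty) <- class(df) <- c("tss_calls", "data.frame")
    return(list(kept = calls, removed = empty))
  }
  tstart <- feature_tss_side(trna)
  hit <- vapply(seq_len(nrow(df)), function(i) {
    same <- trna$replicon == df$replicon[i] & trna$strand == df$strand[i]
    off <- if (df$strand[i] == "+") tstart[same] - df$position[i]
    else df$position[i] - tstart[same]
    any(off >= 0L & off <= params$trna_upstream_window)
  }, TRUE)
  kept <- df[!hit, , drop = FALSE]; removed <- df[hit, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  class(kept) <- class(removed) <- c("tss_calls", "data.frame")
  list(kept = kept, removed = removed)
}
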