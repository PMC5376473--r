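#' Enumerate source/target bipartitions of a channel set
#'
#' A bipartition is an ordered pair (source group B, target group A) of
#' disjoint non-empty channel subsets. Two modes are supported:
#' `"disjoint_pairs"` enumerates every ordered pair of disjoint non-empty
#' subsets (the union need not cover all channels; 3^n - 2^(n+1) + 1
#' pairs, e.g. 12 for three channels), while `"covering"` enumerates
#' ordered two-block set partitions (target = complement of source;
#' 2^n - 2 pairs). Order is canonical and deterministic: sources sorted
#' by size then lexicographically by member index, then targets likewise.
#'
#' @param channels character vector of channel names (length >= 2).
#' @param mode `"disjoint_pairs"` (default) or `"covering"`.
#' @return data frame with list-columns `source` and `target` holding
#'   character vectors of channel names.
#' @export
enumerate_bipartitions <- function(channels,
                                   mode = c("disjoint_pairs", "covering")) {
  mode <- match.arg(mode)
  channels <- as.character(channels)
  n <- length(channels)
  if (n < 2L) stop("need at least 2 channels to bipartition")
  subsets <- lapply(seq_len(2L^n - 1L), function(m)
    which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L))
  ord <- order(lengths(subsets),
               vapply(subsets, function(s)
                 paste(sprintf("%03d", s), collapse = ""), ""))
  subsets <- subsets[ord]
  masks <- vapply(subsets, function(s) sum(bitwShiftL(1L, s - 1L)), 0)
  full <- 2L^n - 1L
  src <- list(); tgt <- list()
  k <- 0L
  for (i in seq_along(subsets)) {
    for (j in seq_along(subsets)) {
      if (bitwAnd(masks[i], masks[j]) != 0L) next
      if (mode == "covering" && bitwOr(masks[i], masks[j]) != full) next
      k <- k + 1L
      src[[k]] <- subsets[[i]]
      tgt[[k]] <- subsets[[j]]
    }
  }
  data.frame(source = I(lapply(src, function(s) channels[s])),
             target = I(lapply(tgt, function(s) channels[s])))
}

#' Transfer-entropy table over all bipartitions of a window
#'
#' Evaluates the Gaussian transfer entropy for every enumerated
#' bipartition of the channel set within one analysis window. A single
#' pooled 2n x 2n covariance of the lag-stacked window is computed once;
#' every bipartition's four entropy terms are determinants of its
#' sub-blocks, so the data are traversed once per window.
#'
#' @param rec an [eeg_recording()].
#' @param window one row of [make_windows()] output, or `NULL` for the
#'   whole recording.
#' @param channels channels to scan (default: all in the recording).
#' @param tau lag in samples (default 2, i.e. 7.8 ms at 256 Hz).
#' @param mode bipartition mode, see [enumerate_bipartitions()].
#' @return a data frame of class `te_table` with list-columns `source`,
#'   `target` and numeric `te` (nats); attributes `mode`, `tau`,
#'   `window_start_s`.
#' @export
te_table <- function(rec, window = NULL, channels = rec$channels, tau = 2L,
                     mode = c("disjoint_pairs", "covering")) {
  mode <- match.arg(mode)
  miss <- setdiff(channels, rec$channels)
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  x <- if (is.null(window)) rec$data else window_slice(rec, window)
  x <- x[, channels, drop = FALSE]
  if (tau < 1L || tau >= nrow(x)) stop("tau must be in [1, window length)")
  x <- sweep(x, 2L, colMeans(x))
  C2 <- pooled_lag_cov(x, tau)
  n <- length(channels)
  bp <- enumerate_bipartitions(channels, mode)
  te <- vapply(seq_len(nrow(bp)), function(i)
    te_from_pooled(C2, match(bp$target[[i]], channels),
                   match(bp$source[[i]], channels), n), 0)
  structure(data.frame(source = I(bp$source), target = I(bp$target), te = te),
            mode = mode, tau = as.integer(tau),
            window_start_s = if (is.null(window)) 0 else window$start_s,
            class = c("te_table", "data.frame"))
}

#' @export
print.te_table <- function(x, ...) {
  cat(sprintf("<te_table> %d bipartitions (%s mode, tau = %s)\n",
              nrow(x), attr(x, "mode"), attr(x, "tau")))
  cat(sprintf("  te range [%.4g, %.4g], mean %.4g\n",
              min(x$te), max(x$te), mean(x$te)))
  invisible(x)
}

bipartition_label <- function(chs) paste(chs, collapse = "+")

#' Maximal-flow principle bipartition (T_max)
#'
#' The bipartition carrying the largest transfer entropy; ties are broken
#' by canonical enumeration order.
#'
#' @param table a [te_table()].
#' @return list with `value` (nats), `source`, `target`.
#' @export
index_tmax <- function(table) {
  if (!nrow(table)) stop("empty table")
  i <- which.max(table$te)
  list(value = table$te[i], source = table$source[[i]],
       target = table$target[[i]])
}

#' Minimum information bipartition (T_min)
#'
#' With `rule = "min"` (default) returns the single smallest
#' transfer-entropy entry. With `rule = "maxmin"` each unordered channel
#' split is scored by the smaller of its two directed entries, the split
#' with the largest such score is selected, and that smaller directed
#' value (with its direction) is reported — the integrated-information
#' style reading of the minimum information bipartition. Ties break by
#' canonical order.
#'
#' @param table a [te_table()].
#' @param rule `"min"` or `"maxmin"`.
#' @return list with `value` (nats), `source`, `target`.
#' @export
index_tmin <- function(table, rule = c("min", "maxmin")) {
  rule <- match.arg(rule)
  if (!nrow(table)) stop("empty table")
  if (rule == "min") {
    i <- which.min(table$te)
    return(list(value = table$te[i], source = table$source[[i]],
                target = table$target[[i]]))
  }
  key_fwd <- vapply(seq_len(nrow(table)), function(i)
    paste(bipartition_label(sort(table$source[[i]])),
          bipartition_label(sort(table$target[[i]])), sep = "|"), "")
  key_rev <- vapply(seq_len(nrow(table)), function(i)
    paste(bipartition_label(sort(table$target[[i]])),
          bipartition_label(sort(table$source[[i]])), sep = "|"), "")
  pair_key <- pmin(key_fwd, key_rev)
  best_val <- -Inf; best_i <- NA_integer_
  for (k in unique(pair_key)) {
    idx <- which(pair_key == k)
    v <- min(table$te[idx])
    if (v > best_val + 1e-15) {
      best_val <- v
      best_i <- idx[which.min(table$te[idx])]
    }
  }
  list(value = table$te[best_i], source = table$source[[best_i]],
       target = table$target[[best_i]])
}

#' Mean transfer entropy over all bipartitions (T_mean)
#'
#' @param table a [te_table()].
#' @return arithmetic mean of all table entries (nats).
#' @export
index_tmean <- function(table) {
  if (!nrow(table)) stop("empty table")
  mean(table$te)
}

#' Serialize a transfer-entropy table
#'
#' CSV columns: `window_start_s`, `source`, `target` (channel names joined
#' by `+`), `te_nats`.
#'
#' @param table a [te_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_te_table <- function(table, path) {
  out <- data.frame(
    window_start_s = attr(table, "window_start_s"),
    source = vapply(table$source, bipartition_label, ""),
    target = vapply(table$target, bipartition_label, ""),
    te_nats = table$te)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
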