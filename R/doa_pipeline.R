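#' Index time course over a recording
#'
#' Computes one depth-of-anesthesia index value per sliding window of the
#' recording: the bipartition transfer-entropy indices (`tmax`, `tmin`,
#' `tmean`), a user-fixed `arbitrary` bipartition, or the single-channel
#' spectral comparators (`sef`, `spe`, `sfs`). Defaults follow the study
#' conditions: 60 s windows every 30 s, lag `tau = 2` samples (7.8 ms at
#' 256 Hz), comparators from channel Fp1.
#'
#' @param rec an [eeg_recording()].
#' @param index one of `"tmax"`, `"tmin"`, `"tmean"`, `"arbitrary"`,
#'   `"sef"`, `"spe"`, `"sfs"`.
#' @param window_s,step_s window length and step in seconds.
#' @param tau lag in samples for transfer entropy.
#' @param mode bipartition mode, see [enumerate_bipartitions()].
#' @param rule T_min rule, see [index_tmin()].
#' @param channels channels entering the bipartition scan (default: all).
#' @param bipartition for `index = "arbitrary"`: a list with character
#'   vectors `source` and `target`.
#' @param channel single channel for the spectral comparators
#'   (default `"Fp1"`, falling back to the first channel if absent).
#' @return object of class `index_course`: data frame with `time_s`
#'   (window starts) and `value`; attributes record all parameters.
#' @export
compute_course <- function(rec,
                           index = c("tmin", "tmax", "tmean", "arbitrary",
                                     "sef", "spe", "sfs"),
                           window_s = 60, step_s = 30, tau = 2L,
                           mode = c("disjoint_pairs", "covering"),
                           rule = c("min", "maxmin"),
                           channels = rec$channels,
                           bipartition = NULL, channel = "Fp1") {
  index <- match.arg(index)
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  wins <- make_windows(rec, window_s, step_s)
  if (index %in% c("sef", "spe", "sfs") && !channel %in% rec$channels)
    channel <- rec$channels[1L]
  if (index == "arbitrary") {
    if (is.null(bipartition) || is.null(bipartition$source) ||
        is.null(bipartition$target))
      stop("index = \"arbitrary\" needs bipartition = list(source=, target=)")
  }
  values <- vapply(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    switch(index,
      tmax = index_tmax(te_table(rec, w, channels, tau, mode))$value,
      tmin = index_tmin(te_table(rec, w, channels, tau, mode), rule)$value,
      tmean = index_tmean(te_table(rec, w, channels, tau, mode)),
      arbitrary = transfer_entropy(rec, bipartition$target,
                                   bipartition$source, w, tau),
      sef = sef(window_slice(rec, w)[, channel], rec$fs),
      spe = spectral_entropy(window_slice(rec, w)[, channel], rec$fs),
      sfs = sfs(window_slice(rec, w)[, channel], rec$fs))
  }, 0)
  structure(data.frame(time_s = wins$start_s, value = values),
            index = index,
            params = list(window_s = window_s, step_s = step_s, tau = tau,
                          mode = mode, rule = rule, channel = channel,
                          bipartition = bipartition),
            class = c("index_course", "data.frame"))
}

#' @export
print.index_course <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("<index_course> %s: %d windows (%g s / %g s)\n",
              attr(x, "index"), nrow(x), p$window_s, p$step_s))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' Single-pair transfer-entropy time course
#'
#' Transfer entropy from one channel into another per window, e.g. the
#' frontoparietal feedback pathway F3 -> P3 versus the feedforward
#' P3 -> F3.
#'
#' @inheritParams compute_course
#' @param src,dst source and destination channel names (distinct).
#' @return an `index_course` (see [compute_course()]).
#' @export
pairwise_course <- function(rec, src, dst, window_s = 60, step_s = 30,
                            tau = 2L) {
  if (identical(src, dst)) stop("source and destination must differ")
  compute_course(rec, "arbitrary", window_s, step_s, tau,
                 bipartition = list(source = src, target = dst))
}

#' Default concentration-phase sections
#'
#' Five consecutive sections anchored at infusion start: A baseline
#' (4 min before infusion), B concentration increase (20 min), C
#' maintenance (15 min), D decrease (20 min), E recovery (10 min).
#'
#' @param infusion_start_s infusion start in seconds.
#' @return data frame with `label`, `start_s`, `end_s`.
#' @export
default_sections <- function(infusion_start_s = 240) {
  dur_min <- c(A = 4, B = 20, C = 15, D = 20, E = 10)
  edges <- infusion_start_s + 60 * cumsum(c(-4, dur_min))
  data.frame(label = names(dur_min),
             start_s = edges[-length(edges)],
             end_s = edges[-1L], row.names = NULL)
}

#' Per-section summary of an index course
#'
#' Mean and SD of the window values whose start time falls in each
#' labeled section (half-open `[start_s, end_s)`); optionally all values
#' are first normalized by the mean of a reference section (baseline A),
#' removing subject-level scale.
#'
#' @param course an `index_course` from [compute_course()].
#' @param sections data frame with `label`, `start_s`, `end_s` (e.g.
#'   [default_sections()]).
#' @param normalize_to optional section label whose mean divides all
#'   values before summarizing (`NULL` = none).
#' @return data frame with `label`, `n`, `mean`, `sd`.
#' @export
summarize_sections <- function(course, sections, normalize_to = NULL) {
  vals <- course$value
  if (!is.null(normalize_to)) {
    ref <- sections[sections$label == normalize_to, ]
    if (!nrow(ref)) stop("unknown reference section: ", normalize_to)
    sel <- course$time_s >= ref$start_s & course$time_s < ref$end_s
    if (!any(sel)) stop("reference section contains no windows")
    vals <- vals / mean(vals[sel])
  }
  out <- lapply(seq_len(nrow(sections)), function(i) {
    sel <- course$time_s >= sections$start_s[i] &
           course$time_s < sections$end_s[i]
    if (!any(sel))
      stop("section ", sections$label[i], " contains no windows")
    data.frame(label = sections$label[i], n = sum(sel),
               mean = mean(vals[sel]), sd = stats::sd(vals[sel]))
  })
  do.call(rbind, out)
}

#' Write an index course
#'
#' CSV columns `time_s`, `value`; a JSON sidecar `<path>.json` records the
#' computation parameters for reproducibility.
#'
#' @param course an `index_course`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_course <- function(course, path) {
  utils::write.csv(as.data.frame(course), path, row.names = FALSE)
  meta <- attr(course, "params")
  meta$index <- attr(course, "index")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
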