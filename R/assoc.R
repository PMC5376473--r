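#' Somers' D with asymptotic standard error
#'
#' Asymmetric rank association D(y|x): over all unordered observation
#' pairs, (concordant - discordant) divided by the number of pairs not
#' tied on x (the independent variable). The standard error is the
#' delta-method estimate for the ratio of pair-sum U-statistics,
#' `SE^2 = 4 / Q^2 * sum_i (p_i - D q_i)^2`, where `p_i` is observation
#' i's net concordance score `sum_j sign(x_i - x_j) sign(y_i - y_j)` and
#' `q_i = sum_j |sign(x_i - x_j)|` its count of x-untied pairs, `Q` the
#' total x-untied pair score.
#'
#' @param x independent variable (e.g. effect-site concentration).
#' @param y dependent variable (e.g. an EEG index).
#' @return list with `D` and `se`.
#' @export
somers_d <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  p_i <- rowSums(sx * sy)
  q_i <- rowSums(abs(sx))
  Q <- sum(q_i)
  if (Q == 0) stop("all x values tied: Somers' D undefined")
  D <- sum(p_i) / Q
  se <- 2 * sqrt(sum((p_i - D * q_i)^2)) / Q
  list(D = D, se = se)
}

#' Prediction probability P_K
#'
#' Rescales Somers' D from [-1, 1] to the [0.5, 1] prediction-probability
#' scale: `P_K = 1 - (1 - |D|) / 2`, with `SE(P_K) = SE(D) / 2`. 0.5 is
#' chance-level prediction of ordinal anesthetic state by the index, 1 is
#' perfect.
#'
#' @inheritParams somers_d
#' @return list with `pk`, `se` and the underlying `D`.
#' @export
pk_statistic <- function(x, y) {
  d <- somers_d(x, y)
  list(pk = 1 - (1 - abs(d$D)) / 2, se = d$se / 2, D = d$D)
}

#' Pearson product-moment correlation
#'
#' @inheritParams somers_d
#' @return list with `r` and two-sided `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spearman rank correlation
#'
#' Midranks for ties; equals the Pearson correlation of the rank
#' transforms.
#'
#' @inheritParams somers_d
#' @return list with `rho` and two-sided `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Index-versus-concentration association summary
#'
#' Convenience wrapper producing one summary row per index course:
#' Pearson r and p, Spearman rho and p, and P_K with SE, of index values
#' against a concentration curve interpolated to the window times.
#'
#' @param courses named list of `index_course` objects.
#' @param conc_time_s,conc concentration curve (seconds, ug/mL).
#' @return data frame with one row per index.
#' @export
association_summary <- function(courses, conc_time_s, conc) {
  rows <- lapply(names(courses), function(nm) {
    co <- courses[[nm]]
    ce <- stats::approx(conc_time_s, conc, xout = co$time_s, rule = 2)$y
    pe <- pearson_cor(ce, co$value)
    sp <- spearman_cor(ce, co$value)
    pk <- pk_statistic(ce, co$value)
    data.frame(index = nm, r = pe$r, r_p = pe$p, rho = sp$rho,
               rho_p = sp$p, pk = pk$pk, pk_se = pk$se)
  })
  do.call(rbind, rows)
}
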