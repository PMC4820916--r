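#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to normal quantiles of its (mid-)ranks,
#' `qnorm((rank - offset) / (n - 2 * offset + 1))`. The default offset 0.5
#' gives `qnorm((r - 0.5) / n)`; `method = "blom"` uses the Blom offset 3/8.
#' Ties receive average ranks, so tied inputs map to the same z-value and the
#' rank order of the input is preserved exactly.
#'
#' Lipid concentrations show wide, skewed inter-individual variability; this
#' transform places every species on a common z-scale before survival
#' screening and score construction.
#'
#' @param x Numeric vector, `length(x) >= 2`, all finite.
#' @param method Rank offset rule: `"half"` (default, offset 1/2) or
#'   `"blom"` (offset 3/8).
#' @return Numeric vector of z-values, same length and order as `x`.
#' @examples
#' inverse_normalize(c(5, 9))          # -0.6745, +0.6745
#' inverse_normalize(c(3, 1, 2, 5, 4)) # rank order preserved
#' @export
inverse_normalize <- function(x, method = c("half", "blom")) {
  method <- match.arg(method)
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("all values identical: ranks are degenerate", call. = FALSE)
  }
  n <- length(x)
  r <- rank(x, ties.method = "average")
  c_off <- if (method == "half") 0.5 else 3 / 8
  stats::qnorm((r - c_off) / (n - 2 * c_off + 1))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: with p-values sorted ascending,
#' `p_adj[i] = min over j >= i of min(1, m * p[j] / j)`, returned in the
#' original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` entries are
#'   preserved and excluded from the multiplicity count.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5)) # 0.04 0.04 0.04 0.50
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Tertile group labels
#'
#' Cuts a score at its empirical 1/3 and 2/3 quantiles (type 7) into ordered
#' groups `lower < middle < upper`. Heavy ties that empty a tertile are an
#' error.
#'
#' @param x Numeric vector, `length(x) >= 3`.
#' @param labels Group labels, length 3, lowest first.
#' @return Ordered factor, same length and order as `x`.
#' @examples
#' table(tertile_groups(1:9))
#' @export
tertile_groups <- function(x, labels = c("lower", "middle", "upper")) {
  if (!is.numeric(x) || length(x) < 3L) {
    stop("`x` must be numeric with length >= 3", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  qs <- stats::quantile(x, probs = c(1, 2) / 3, names = FALSE)
  if (anyDuplicated(qs)) {
    stop("ties produced an empty tertile group", call. = FALSE)
  }
  g <- cut(x, breaks = c(-Inf, qs, Inf), labels = labels,
           right = TRUE, ordered_result = TRUE)
  if (any(table(g) == 0L)) {
    stop("ties produced an empty tertile group", call. = FALSE)
  }
  g
}

#' Inverse-normalize cohort columns in place
#'
#' Applies [inverse_normalize()] to each named column of a cohort table,
#' writing columns prefixed `"inv_"` (so raw concentrations stay available).
#'
#' @param data A data frame.
#' @param cols Character vector of column names to transform.
#' @param method Passed to [inverse_normalize()].
#' @return `data` as a tibble with the added `inv_*` columns.
#' @export
inverse_normalize_cols <- function(data, cols, method = c("half", "blom")) {
  method <- match.arg(method)
  assert_columns(data, cols)
  out <- tibble::as_tibble(data)
  for (cl in cols) {
    out[[paste0("inv_", cl)]] <- inverse_normalize(out[[cl]], method = method)
  }
  out
}
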