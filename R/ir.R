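# Surrogate insulin-resistance indices and their association with score
# tertiles.

#' Insulin-resistance index panel
#'
#' Adds the six surrogate insulin-resistance measures to a cohort:
#' fasting plasma glucose (FPG, mg/dl) and insulin (FPI, IU/L) as supplied,
#' plus
#' `HOMA-IR = FPG * FPI / 405`,
#' `QUICKI = 1 / (log10(FPI) + log10(FPG))`,
#' `McAuley = exp(2.63 - 0.28 ln(FPI) - 0.31 ln(TG mmol/l))`,
#' and the leptin/adiponectin ratio. QUICKI uses base-10 logarithms (the
#' index's original definition); `log_base` makes this explicit and
#' overridable. Any non-positive input yields a missing value for the
#' affected measures only.
#'
#' @param data Cohort data frame.
#' @param fpg,fpi,triglycerides,leptin,adiponectin Column names (FPG in
#'   mg/dl, FPI in IU/L, triglycerides in mmol/l).
#' @param log_base Base of the QUICKI logarithms.
#' @return `data` as a tibble with columns `homa_ir`, `quicki`, `mcauley`
#'   and `lep_adi_ratio` added.
#' @examples
#' d <- tibble::tibble(fpg = 100, fpi = 10, triglycerides = 1,
#'                     leptin = 12, adiponectin = 8)
#' compute_ir_panel(d)$homa_ir # 2.4691
#' @export
compute_ir_panel <- function(data, fpg = "fpg", fpi = "fpi",
                             triglycerides = "triglycerides",
                             leptin = "leptin", adiponectin = "adiponectin",
                             log_base = 10) {
  assert_columns(data, c(fpg, fpi, triglycerides, leptin, adiponectin))
  out <- tibble::as_tibble(data)
  g <- out[[fpg]]; i <- out[[fpi]]; tg <- out[[triglycerides]]
  lep <- out[[leptin]]; adi <- out[[adiponectin]]
  pos <- function(x) ifelse(is.finite(x) & x > 0, x, NA_real_)
  g <- pos(g); i <- pos(i); tg <- pos(tg); lep <- pos(lep); adi <- pos(adi)
  out$homa_ir <- g * i / 405
  out$quicki <- 1 / (log(i, base = log_base) + log(g, base = log_base))
  out$mcauley <- exp(2.63 - 0.28 * log(i) - 0.31 * log(tg))
  out$lep_adi_ratio <- lep / adi
  out
}

#' Association of insulin-resistance measures with score tertiles
#'
#' For each measure: medians and interquartile ranges per score tertile, a
#' Kruskal-Wallis test across tertiles, and the Koenker-Machado pseudo-R1
#' of a median regression on the tertile indicators. Because the design is
#' a factor, the median-regression fit is exactly the per-tertile medians
#' and the null fit the overall median, so
#' `R1 = 1 - sum|y - median_tertile| / sum|y - median_overall|`.
#'
#' @param data Cohort data frame (run [compute_ir_panel()] first).
#' @param score Numeric risk score, one value per row.
#' @param measures Columns to summarize.
#' @param ngt_only Restrict to normoglycemic subjects before forming
#'   tertiles?
#' @param glycemic Column holding the glycemic class.
#' @return Tibble of class `ir_association`: one row per measure x tertile
#'   with `median`, `q25`, `q75`, and per-measure `kw_p` and `r1`.
#' @export
tertile_ir_association <- function(data, score,
                                   measures = c("fpg", "fpi", "homa_ir",
                                                "quicki", "mcauley",
                                                "lep_adi_ratio"),
                                   ngt_only = FALSE,
                                   glycemic = "glycemic_class") {
  assert_columns(data, measures)
  d <- tibble::as_tibble(data)
  d$.score <- score
  if (ngt_only) {
    assert_columns(d, glycemic)
    d <- d[d[[glycemic]] == "NGT", , drop = FALSE]
  }
  d$.tertile <- tertile_groups(d$.score)
  if (any(table(d$.tertile) < 3L)) {
    stop("each tertile needs at least 3 subjects", call. = FALSE)
  }
  out <- purrr::map_dfr(measures, function(m) {
    y <- d[[m]]
    ok <- !is.na(y)
    yt <- y[ok]; g <- droplevels(d$.tertile[ok])
    if (nlevels(g) < 3L) stop("empty tertile for measure ", m, call. = FALSE)
    kw <- stats::kruskal.test(yt, g)$p.value
    med_g <- tapply(yt, g, stats::median)
    r1 <- 1 - sum(abs(yt - med_g[g])) / sum(abs(yt - stats::median(yt)))
    summ <- tibble::tibble(
      measure = m,
      tertile = levels(g),
      median = as.numeric(tapply(yt, g, stats::median)),
      q25 = as.numeric(tapply(yt, g, stats::quantile, 0.25)),
      q75 = as.numeric(tapply(yt, g, stats::quantile, 0.75)),
      kw_p = kw, r1 = r1)
    summ
  })
  class(out) <- c("ir_association", class(out))
  out
}
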