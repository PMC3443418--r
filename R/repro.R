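#' Percent difference between replicate-scan scores
#'
#' The primary reproducibility measure: the absolute difference between the
#' two scans' scores relative to their mean,
#' `|x1 - x2| / ((x1 + x2) / 2) * 100`. Symmetric, scale-invariant and
#' bounded in `[0, 200]`. Undefined when both scores are zero: such pairs
#' return `NA` and are excluded (and counted) by
#' [reproducibilityTable()].
#'
#' @param x1,x2 Non-negative scores from the first and second scan
#'   (vectorized).
#' @return Percent difference(s); `NA` where `x1 + x2 == 0`.
#' @examples
#' percentDifference(3, 1)   # 100
#' percentDifference(10, 0)  # 200, the statistic's maximum
#' @export
percentDifference <- function(x1, x2) {
  if (any(x1 < 0, na.rm = TRUE) || any(x2 < 0, na.rm = TRUE))
    stop("scores must be non-negative")
  out <- abs(x1 - x2) / ((x1 + x2) / 2) * 100
  out[x1 + x2 == 0] <- NA_real_
  out
}

#' Intraclass correlation for replicate scans
#'
#' One-way random-effects ICC(1,1) from the standard ANOVA decomposition:
#' with k replicates per participant,
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`, which for the paired-scan
#' case (k = 2) is `(MSB - MSW) / (MSB + MSW)`. Scan order within a
#' participant is treated as exchangeable (scans were randomized), which is
#' what makes the one-way model appropriate; a two-way random-effects
#' agreement variant ICC(2,1) is available for designs with a systematic
#' scan effect.
#'
#' @param x1,x2 Paired scores (equal-length vectors), or `x1` an n x 2
#'   matrix/data.frame with `x2` missing.
#' @param type `"oneway"` (default, ICC(1,1)) or `"twoway"` (ICC(2,1),
#'   absolute agreement).
#' @return ICC in `[-1, 1]`.
#' @examples
#' icc(c(1, 5, 9), c(1, 5, 9))  # 1: zero within-pair variance
#' @export
icc <- function(x1, x2 = NULL, type = c("oneway", "twoway")) {
  type <- match.arg(type)
  if (is.null(x2)) {
    m <- as.matrix(x1)
    if (ncol(m) != 2) stop("need paired scores (n x 2)")
  } else {
    m <- cbind(x1, x2)
  }
  if (nrow(m) < 3) stop("ICC needs at least 3 participants")
  if (any(!is.finite(m))) stop("scores must be finite")
  n <- nrow(m)
  k <- 2
  rowm <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((rowm - grand)^2) / (n - 1)
  msw <- sum((m - rowm)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0)
    stop("all scores identical: ICC undefined (zero variance)")
  if (type == "oneway") {
    (msb - msw) / (msb + (k - 1) * msw)
  } else {
    colm <- colMeans(m)
    msc <- n * sum((colm - grand)^2) / (k - 1)
    sse <- sum((m - grand)^2) - (n - 1) * msb - (k - 1) * msc
    mse <- max(sse / ((n - 1) * (k - 1)), 0)  # guard tiny negative rounding
    (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n)
  }
}

#' Pair per-scan scores into a wide replicate table
#'
#' @param scores data.frame from [scoreTable()] / [readScores()] with two
#'   scans per participant (participants with any other number of scans
#'   are dropped with a message).
#' @return data.frame: participant_id, as1, as2, swcs1, swcs2.
#' @export
pairScores <- function(scores) {
  sp <- split(scores, scores$participant_id)
  keep <- vapply(sp, nrow, integer(1)) == 2L
  if (any(!keep))
    message(sum(!keep), " participant(s) without exactly 2 scans dropped")
  rows <- lapply(sp[keep], function(g) {
    g <- g[order(g$scan_id), ]
    data.frame(participant_id = g$participant_id[1],
               as1 = g$agatston[1], as2 = g$agatston[2],
               swcs1 = g$swcs[1], swcs2 = g$swcs[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id), , drop = FALSE]
}

#' Replicate-scan reproducibility comparison of AS and SWCS
#'
#' Applies a participant subset filter, computes per-method percent
#' differences on the identical participant set, the per-participant
#' paired contrast (Agatston percent difference minus SWCS percent
#' difference) with 95% bootstrap percentile confidence intervals
#' (resampling participants), and the ICC of each method on the subset.
#'
#' Subsets mirror the standard reporting strata: `"either"` keeps
#' participants with Agatston score > 0 on at least one scan, `"both"`
#' requires it on both scans, and `"both-lt"` further restricts `"both"`
#' to participants with both scans below `cutoff`. `"all"` applies no
#' filter. Pairs for which a method's percent difference is undefined
#' (both replicate scores zero) are excluded from both methods and
#' counted.
#'
#' @param paired data.frame from [pairScores()] (columns participant_id,
#'   as1, as2, swcs1, swcs2).
#' @param subset `"either"` (default), `"both"`, `"both-lt"`, or `"all"`.
#' @param cutoff Agatston cutoff for `"both-lt"` (e.g. 50 or 100).
#' @param nBoot Bootstrap draws; default 2000.
#' @param seed Seed for the bootstrap; default 1.
#' @return A [ReproSummary-class].
#' @export
reproducibilityTable <- function(paired,
                                 subset = c("either", "both", "both-lt",
                                            "all"),
                                 cutoff = NULL, nBoot = 2000, seed = 1) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    all = rep(TRUE, nrow(paired)),
    either = paired$as1 > 0 | paired$as2 > 0,
    both = paired$as1 > 0 & paired$as2 > 0,
    "both-lt" = {
      if (is.null(cutoff)) stop("subset 'both-lt' needs a cutoff")
      paired$as1 > 0 & paired$as2 > 0 &
        paired$as1 < cutoff & paired$as2 < cutoff
    })
  sub <- paired[keep, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no participants left after subset filtering")
  pdAS <- percentDifference(sub$as1, sub$as2)
  pdSW <- percentDifference(sub$swcs1, sub$swcs2)
  ok <- !is.na(pdAS) & !is.na(pdSW)
  nUndef <- sum(!ok)
  sub <- sub[ok, , drop = FALSE]
  pdAS <- pdAS[ok]
  pdSW <- pdSW[ok]
  if (nrow(sub) < 3)
    stop("fewer than 3 usable pairs after exclusions")
  dif <- pdAS - pdSW
  boots <- withr::with_seed(seed, {
    n <- length(dif)
    t(vapply(seq_len(nBoot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      c(median(dif[i]), mean(dif[i]))
    }, numeric(2)))
  })
  ciMed <- stats::quantile(boots[, 1], c(0.025, 0.975), names = FALSE)
  ciMean <- stats::quantile(boots[, 2], c(0.025, 0.975), names = FALSE)
  methods <- data.frame(
    method = c("AS", "SWCS"),
    median_pct_diff = c(median(pdAS), median(pdSW)),
    mean_pct_diff = c(mean(pdAS), mean(pdSW)),
    icc = c(icc(sub$as1, sub$as2), icc(sub$swcs1, sub$swcs2)),
    stringsAsFactors = FALSE)
  pairedDf <- data.frame(
    stat = c("median", "mean"),
    estimate = c(median(dif), mean(dif)),
    ci_lower = c(ciMed[1], ciMean[1]),
    ci_upper = c(ciMed[2], ciMean[2]),
    stringsAsFactors = FALSE)
  new("ReproSummary", subset = subset, n = nrow(sub),
      nUndefined = as.integer(nUndef), methods = methods, paired = pairedDf)
}
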