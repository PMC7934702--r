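#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements, penalising both decorrelation and
#' location/scale shifts:
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)`,
#' with moments estimated using 1/n denominators (Lin 1989). Always lies in
#' `[-1, 1]` and never exceeds the Pearson correlation in absolute value.
#'
#' @param x,y numeric vectors of equal length >= 2, not both constant.
#' @return the concordance correlation coefficient.
#' @export
concordance_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("schema error: x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 paired values", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0) {
    stop("undefined CCC: both inputs are constant", call. = FALSE)
  }
  sxy <- mean((x - mx) * (y - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Screen features for test-retest reproducibility
#'
#' Computes the CCC between test and retest values of every feature and
#' keeps those at or above the threshold (features with CCC below 0.85 are
#' conventionally excluded as non-reproducible).
#'
#' @param test,retest feature tables sharing `sample_id`s and feature
#'   columns; rows are matched by `sample_id`.
#' @param threshold minimum CCC to keep a feature (default 0.85).
#' @return data.frame with columns `feature`, `ccc`, `kept`.
#' @export
screen_reproducible <- function(test, retest, threshold = 0.85) {
  feats <- feature_columns(test)
  if (!setequal(feats, feature_columns(retest))) {
    stop("schema error: test and retest feature columns differ", call. = FALSE)
  }
  if (!"sample_id" %in% names(test) || !"sample_id" %in% names(retest) ||
      !setequal(test$sample_id, retest$sample_id)) {
    stop("schema error: test and retest sample_ids differ", call. = FALSE)
  }
  retest <- retest[match(test$sample_id, retest$sample_id), , drop = FALSE]
  ccc <- vapply(feats, function(f) {
    concordance_correlation(test[[f]], retest[[f]])
  }, numeric(1))
  data.frame(feature = feats, ccc = unname(ccc),
             kept = unname(ccc) >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
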