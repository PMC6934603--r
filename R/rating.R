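# ROC/AUC comparison of ordinal rating samples.
#
# Two conditions of a piece are compared through the Mann-Whitney kernel:
# AUC = P(X > Y) + 0.5 * P(X = Y) over all pairs, with X the manipulated and
# Y the original condition, so AUC > 0.5 means the manipulation was rated
# higher and AUC < 0.5 a preference for the original. The variance uses
# DeLong's structural components with the 0 / 0.5 / 1 tie kernel — 4-point
# scales are tie-dense, so the tie term matters. The design is unpaired
# (each listener heard only one version of a piece).

#' An ordinal rating sample
#'
#' @param ratings integer ratings on the 4-point scale (1 = "not at all" to
#'   4 = "very much").
#' @param piece piece label.
#' @param condition one of `"original"`, `"quantized"`, `"exaggerated"`,
#'   `"inverted"`.
#' @return an object of class `rating_sample`.
#' @export
rating_sample <- function(ratings, piece = NA_character_,
                          condition = c("original", "quantized",
                                        "exaggerated", "inverted")) {
  condition <- match.arg(condition)
  stopifnot(length(ratings) >= 1, all(ratings %in% 1:4))
  structure(list(ratings = as.integer(ratings), piece = piece,
                 condition = condition),
            class = "rating_sample")
}

as_ratings <- function(x) {
  if (inherits(x, "rating_sample")) x$ratings else as.numeric(x)
}

#' ROC curve and AUC with a DeLong confidence interval
#'
#' Compares two ordinal rating samples via the area under the ROC curve:
#' `AUC = P(x > y) + 0.5 * P(x = y)` over all pairs, the Mann-Whitney
#' two-sample statistic with the midrank tie convention. The 95% (by default)
#' confidence interval uses DeLong's asymptotic variance from the structural
#' components of each observation, clipped to `[0, 1]`. The ROC curve is
#' built from cumulative proportions of the answer categories, from 4
#' ("very much") down to 1, with the comparison sample on the horizontal
#' axis; it runs from (0, 0) to (1, 1).
#'
#' @param x ratings of the condition of interest (e.g. a manipulation), as a
#'   numeric vector or [rating_sample()].
#' @param y ratings of the comparison condition (e.g. the original).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `var_auc`, `curve` (data frame `category`, `x`, `y`), `n_x`,
#'   `n_y`, `conf_level` and `significant` (CI excludes 0.5).
#' @examples
#' roc_auc(c(1, 1, 2, 2), c(3, 4, 4, 2))  # x rated clearly lower: AUC < 0.5
#' @export
roc_auc <- function(x, y, conf_level = 0.95) {
  x <- as_ratings(x)
  y <- as_ratings(y)
  stopifnot(length(x) >= 1, length(y) >= 1,
            conf_level > 0, conf_level < 1)
  nx <- length(x)
  ny <- length(y)

  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- sum(psi) / (nx * ny)
  v10 <- rowMeans(psi)   # structural components of x observations
  v01 <- colMeans(psi)   # structural components of y observations
  var_auc <- var_or_zero(v10) / nx + var_or_zero(v01) / ny
  if (var_auc == 0) {
    warning("degenerate samples: DeLong variance is zero, CI collapses to the AUC")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- auc + c(-1, 1) * z * sqrt(var_auc)

  cats <- sort(unique(c(x, y, 1:4)), decreasing = TRUE)
  curve <- data.frame(
    category = c(NA, cats),
    x = c(0, cumsum(vapply(cats, function(k) mean(y == k), numeric(1)))),
    y = c(0, cumsum(vapply(cats, function(k) mean(x == k), numeric(1))))
  )

  structure(
    list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[2]),
         var_auc = var_auc, curve = curve, n_x = nx, n_y = ny,
         conf_level = conf_level,
         significant = ci[1] > 0.5 || ci[2] < 0.5),
    class = "roc_result"
  )
}

var_or_zero <- function(v) if (length(v) >= 2) stats::var(v) else 0

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f, %d%% CI %.3f-%.3f (n = %d vs %d)\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_x, x$n_y))
  cat(if (x$significant) "  conditions differ (CI excludes 0.5)\n"
      else "  no significant difference between conditions (CI contains 0.5)\n")
  invisible(x)
}

#' Distribution of ratings over the answer categories
#'
#' @param ratings numeric vector or [rating_sample()].
#' @param levels the answer categories (default `1:4`).
#' @return named numeric vector of proportions summing to 1.
#' @examples
#' rating_distribution(c(1, 2, 3, 4))
#' @export
rating_distribution <- function(ratings, levels = 1:4) {
  ratings <- as_ratings(ratings)
  stopifnot(length(ratings) >= 1, all(ratings %in% levels))
  prop <- vapply(levels, function(k) mean(ratings == k), numeric(1))
  names(prop) <- as.character(levels)
  prop
}

#' Export ratings as a long survey-shaped table
#'
#' One row per rating with columns `participant`, `piece`, `condition`,
#' `musician_category`, `rating` — the layout mixed ordinal-regression
#' software consumes. The survey design allows each participant to hear only
#' one version of a piece, so duplicated participant-piece combinations are
#' rejected.
#'
#' @param ratings data frame with columns `participant`, `piece`,
#'   `condition`, `musician_category`, `rating`.
#' @param path output CSV path.
#' @return the exported data frame, invisibly.
#' @export
export_long_table <- function(ratings, path) {
  required <- c("participant", "piece", "condition", "musician_category",
                "rating")
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols)) {
    stop("ratings is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(ratings$rating %in% 1:4))
  dup <- duplicated(ratings[c("participant", "piece")])
  if (any(dup)) {
    stop("each participant may rate only one version of a piece; duplicated: ",
         paste(unique(paste(ratings$participant[dup], ratings$piece[dup],
                            sep = "/")), collapse = ", "))
  }
  utils::write.csv(ratings[required], path, row.names = FALSE)
  invisible(ratings[required])
}

#' Read a long survey-shaped ratings table
#'
#' @param path CSV written by [export_long_table()] (or shaped like it).
#' @return data frame with the five survey columns.
#' @export
read_long_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "piece", "condition", "musician_category",
                "rating")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop("table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out[required]
}

#' Per-piece ROC/AUC between two conditions of a long ratings table
#'
#' @param ratings long table as from [read_long_table()].
#' @param condition_a condition of interest (e.g. `"inverted"`).
#' @param condition_b comparison condition (default `"original"`).
#' @param conf_level confidence level passed to [roc_auc()].
#' @return data frame with one row per piece: `piece`, `auc`, `ci_low`,
#'   `ci_high`, `n_a`, `n_b`, `significant`.
#' @export
roc_by_piece <- function(ratings, condition_a, condition_b = "original",
                         conf_level = 0.95) {
  pieces <- sort(unique(ratings$piece))
  rows <- lapply(pieces, function(p) {
    a <- ratings$rating[ratings$piece == p & ratings$condition == condition_a]
    b <- ratings$rating[ratings$piece == p & ratings$condition == condition_b]
    if (!length(a) || !length(b)) return(NULL)
    res <- roc_auc(a, b, conf_level = conf_level)
    data.frame(piece = p, auc = res$auc, ci_low = res$ci_low,
               ci_high = res$ci_high, n_a = res$n_x, n_b = res$n_y,
               significant = res$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
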