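# mid-ranks (average ranks for ties), written out explicitly so the
# implementation stays independent of base rank()'s internals
midrank <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1
  }
  r
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks; ties receive average ranks. Constant
#' input makes the correlation undefined and raises an error (callers that
#' rank many features catch this and flag the feature instead).
#'
#' @param x,y Equal-length numeric vectors, length >= 3, finite values.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must be equal-length with n >= 3", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  rx <- midrank(x); ry <- midrank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  r <- sum(dx * dy) / (sx * sy)
  max(-1, min(1, r))
}

#' Rank features by robustness to contact pressure
#'
#' Computes the Spearman correlation of each feature column (`f1`..`f17`)
#' against the cycle-mean contact pressure and orders features by ascending
#' absolute correlation: features early in the ordering are least affected
#' by sensor contact pressure. Ties are broken by feature index. Features
#' with undefined correlation (constant column) get `rho = NA`, are flagged,
#' and sort after all defined ones.
#'
#' @param matrix A [feature_matrix()] result containing a contact-pressure
#'   column.
#' @param cp_col Name of the pressure column (default `"cp_mmHg"`).
#' @param channel,state,replica Optional labels stored in the result.
#' @return A list of class `"ranking_result"`: `rho` (named numeric, one
#'   entry per feature), `ordering` (feature names, ascending `|rho|`),
#'   `undefined` (names of flagged features), plus the labels.
#' @export
rank_features <- function(matrix, cp_col = "cp_mmHg",
                          channel = NA_character_, state = NA_character_,
                          replica = NA_integer_) {
  if (!cp_col %in% names(matrix)) {
    stop(sprintf("missing contact-pressure column '%s'", cp_col),
         call. = FALSE)
  }
  cp <- matrix[[cp_col]]
  if (nrow(matrix) < 3) stop("need >= 3 cycles", call. = FALSE)
  if (length(unique(cp)) < 2) {
    stop("contact-pressure column is constant", call. = FALSE)
  }
  feats <- paste0("f", 1:17)
  rho <- vapply(feats, function(f) {
    tryCatch(spearman_rho(matrix[[f]], cp), error = function(e) NA_real_)
  }, numeric(1))
  key <- abs(rho)
  key[is.na(key)] <- Inf  # undefined features sort last
  ordering <- feats[order(key, seq_along(feats))]
  structure(list(rho = rho, ordering = ordering,
                 undefined = feats[is.na(rho)],
                 channel = channel, state = state, replica = replica),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("<ranking_result> ascending |rho|:\n  ",
      paste(x$ordering, collapse = " "), "\n")
  invisible(x)
}

#' Summarise rank positions by feature class
#'
#' Aggregates one or more [rank_features()] results: the median rank
#' position of each feature class (temporal / amplitude / geometric) across
#' states, replicas and channels, and a clustering flag `temporal_robust`
#' that is `TRUE` when the temporal median rank is smaller than the
#' amplitude median rank (temporal features cluster at the
#' least-pressure-affected end).
#'
#' @param results A single `ranking_result` or a list of them.
#' @return A list with `by_class` (data.frame: class, median_rank, n),
#'   `by_feature` (data.frame: feature, class, median_rank) and
#'   `temporal_robust`.
#' @export
class_summary <- function(results) {
  if (inherits(results, "ranking_result")) results <- list(results)
  if (length(results) == 0) stop("no results", call. = FALSE)
  cls <- feature_classes()
  pos <- lapply(results, function(r) match(cls$feature, r$ordering))
  posm <- do.call(cbind, pos)  # 17 x n_results
  med_feat <- apply(posm, 1, stats::median)
  by_feature <- data.frame(feature = cls$feature, class = cls$class,
                           median_rank = med_feat,
                           stringsAsFactors = FALSE)
  agg <- tapply(as.vector(posm), rep(cls$class, ncol(posm)), stats::median)
  by_class <- data.frame(class = names(agg),
                         median_rank = as.numeric(agg),
                         n = length(results),
                         stringsAsFactors = FALSE)
  structure(list(
    by_class = by_class, by_feature = by_feature,
    temporal_robust = by_class$median_rank[by_class$class == "temporal"] <
      by_class$median_rank[by_class$class == "amplitude"]
  ), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  print(x$by_class)
  cat("temporal_robust:", x$temporal_robust, "\n")
  invisible(x)
}
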