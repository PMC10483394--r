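# Empirical ROC evaluation of top-ranked genotype patterns: pattern presence
# is read as a phenotype predictor, each pattern's 2x2 table yields one
# (FPR, TPR) point, points are averaged within FPR classes, and AUC is the
# trapezoid area of the anchored polyline.

#' Decision rates of one pattern table
#'
#' Treats occurrence of a pattern as a predictor of phenotype. Direction
#' `"F2"` (pattern predicts case): `TPR = a/(a+b)`, `FPR = c/(c+d)`.
#' Direction `"F1"` (pattern predicts control): `TPR = c/(c+d)`,
#' `FPR = a/(a+b)`.
#'
#' @param t a [two_by_two].
#' @param direction `"F1"` or `"F2"`.
#' @return A list with `fpr` and `tpr`.
#' @export
decision_rates <- function(t, direction = c("F1", "F2")) {
  direction <- match.arg(direction)
  if (t$a + t$b == 0 || t$c + t$d == 0) {
    stop("undefined rates: empty phenotype group", call. = FALSE)
  }
  case_rate <- t$a / (t$a + t$b)
  ctrl_rate <- t$c / (t$c + t$d)
  if (direction == "F2") list(fpr = ctrl_rate, tpr = case_rate)
  else list(fpr = case_rate, tpr = ctrl_rate)
}

#' Binned empirical ROC curve from top patterns
#'
#' Selects the `top_k` patterns with the smallest one-sided Fisher p-value
#' matching `direction` (F1 for pattern-predicts-control, F2 for
#' pattern-predicts-case), converts each to an (FPR, TPR) point, splits the
#' FPR axis into `n_classes` equal-width classes, and represents each
#' nonempty class by its mean FPR and mean TPR. Anchors (0,0) and (1,1) are
#' always appended; empty interior classes are filled at their midpoints by
#' linear interpolation between the nearest nonempty neighbours. AUC is the
#' trapezoid area of the anchored polyline.
#'
#' @param patterns data frame with columns `a`, `b`, `c`, `d` (e.g. the
#'   `results` of [scan_genotype_pairs()] or a [pairsnps_report()]), or a
#'   list of [two_by_two] tables.
#' @param direction `"F1"` or `"F2"`.
#' @param n_classes number of FPR classes (default 20).
#' @param top_k number of best patterns to use (default 100).
#' @param dedupe when `TRUE` and the data carry variant indices `i`, `j`,
#'   walk the p-ranked list and skip patterns sharing a variant with an
#'   already-selected one before taking `top_k` (default `FALSE`).
#' @return An object of class `roc_curve`: `points` (data frame `fpr`,
#'   `tpr`, `n`, `interpolated`), `auc`, `n_classes`, `direction`,
#'   `n_patterns`.
#' @export
binned_roc <- function(patterns, direction = c("F1", "F2"), n_classes = 20,
                       top_k = 100, dedupe = FALSE) {
  direction <- match.arg(direction)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  if (inherits(patterns, "gpairs_result")) patterns <- patterns$results
  if (is.list(patterns) && !is.data.frame(patterns)) {
    patterns <- do.call(rbind, lapply(patterns, function(t)
      data.frame(a = t$a, b = t$b, c = t$c, d = t$d)))
  }
  if (is.null(patterns) || nrow(patterns) == 0) {
    stop("no pattern tables supplied", call. = FALSE)
  }
  p <- vapply(seq_len(nrow(patterns)), function(r)
    fisher_exact(two_by_two(patterns$a[r], patterns$b[r], patterns$c[r],
                            patterns$d[r]), side = direction),
    numeric(1))
  ord <- order(p, seq_len(nrow(patterns)))
  if (dedupe && all(c("i", "j") %in% names(patterns))) {
    seen <- character(0)
    pick <- logical(length(ord))
    for (q in seq_along(ord)) {
      vs <- as.character(c(patterns$i[ord[q]], patterns$j[ord[q]]))
      if (!any(vs %in% seen)) {
        pick[q] <- TRUE
        seen <- c(seen, vs)
      }
    }
    ord <- ord[pick]
  }
  sel <- patterns[utils::head(ord, top_k), , drop = FALSE]

  rates <- lapply(seq_len(nrow(sel)), function(r)
    decision_rates(two_by_two(sel$a[r], sel$b[r], sel$c[r], sel$d[r]),
                   direction))
  fpr <- vapply(rates, `[[`, numeric(1), "fpr")
  tpr <- vapply(rates, `[[`, numeric(1), "tpr")

  cls <- pmin(floor(fpr * n_classes), n_classes - 1) + 1
  occupied <- sort(unique(cls))
  pts <- data.frame(
    fpr = vapply(occupied, function(b) mean(fpr[cls == b]), numeric(1)),
    tpr = vapply(occupied, function(b) mean(tpr[cls == b]), numeric(1)),
    n = vapply(occupied, function(b) sum(cls == b), numeric(1)),
    interpolated = FALSE
  )
  pts <- pts[order(pts$fpr), , drop = FALSE]
  anchored <- rbind(data.frame(fpr = 0, tpr = 0, n = 0, interpolated = FALSE),
                    pts,
                    data.frame(fpr = 1, tpr = 1, n = 0, interpolated = FALSE))
  # fill empty interior classes at their midpoints along the polyline
  empty <- setdiff(seq_len(n_classes), occupied)
  mid <- (empty - 0.5) / n_classes
  mid <- mid[mid > min(anchored$fpr) & mid < max(anchored$fpr)]
  if (length(mid)) {
    yi <- stats::approx(anchored$fpr, anchored$tpr, xout = mid,
                        ties = "ordered")$y
    anchored <- rbind(anchored,
                      data.frame(fpr = mid, tpr = yi, n = 0,
                                 interpolated = TRUE))
    anchored <- anchored[order(anchored$fpr, anchored$tpr), , drop = FALSE]
  }
  rownames(anchored) <- NULL
  structure(
    list(points = anchored, auc = trapezoid_auc(anchored$fpr, anchored$tpr),
         n_classes = n_classes, direction = direction,
         n_patterns = nrow(sel)),
    class = "roc_curve"
  )
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("empirical ROC (%s, %d patterns, %d FPR classes): AUC = %.3f\n",
              x$direction, x$n_patterns, x$n_classes, x$auc))
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param x a `roc_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "b", pch = 19,
                 xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR", ylab = "TPR",
                 main = sprintf("Empirical ROC (%s), AUC = %.3f",
                                x$direction, x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
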