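# Group comparisons of index values, age/passage correlation, and the
# sample-level outlier rules.

#' One-sided independent two-sample t-test
#'
#' Implements the closed-form two-sample t statistic with either the
#' pooled-variance Student's variant (df = na + nb - 2, the default) or the
#' Welch variant (Welch-Satterthwaite df). The one-sided p-value follows the
#' declared alternative. When both groups are constant and equal the
#' statistic is defined as 0 and p = 0.5.
#'
#' @param a,b Numeric vectors of index values (each length >= 2).
#' @param alternative `"a_greater"` (H1: mean(a) > mean(b)) or
#'   `"b_greater"`.
#' @param variant `"pooled"` or `"welch"`.
#' @return A `GroupComparison` list: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `alternative`, `variant`.
#' @export
one_sided_t_test <- function(a, b, alternative = c("a_greater", "b_greater"),
                             variant = c("pooled", "welch")) {
  alternative <- match.arg(alternative)
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "pooled") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    if (!is.finite(df)) df <- na + nb - 2
  }
  diff <- ma - mb
  t <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / se
  }
  p <- if (alternative == "a_greater") {
    stats::pt(t, df, lower.tail = FALSE)
  } else {
    stats::pt(t, df, lower.tail = TRUE)
  }
  if (t == 0) p <- 0.5   # exact under symmetry
  structure(list(t = t, df = df, p = p, mean_a = ma, mean_b = mb,
                 alternative = alternative, variant = variant),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("One-sided t-test (%s, %s): t = %.4g, df = %.4g, p = %.4g\n",
              x$variant, x$alternative, x$t, x$df, x$p))
  cat(sprintf("  mean(a) = %.4f, mean(b) = %.4f\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' Flag outlier samples by global methylation
#'
#' Two reproducible rules. `anchor_range` flags any sample whose global
#' mean methylation lies outside the interval spanned by two anchor samples
#' (the rule used to drop an adult sample lying outside the
#' neonatal-centenarian range). `zscore` flags samples with |z| > 3 on the
#' global means, the rule applied within groups for sparse single-cell
#' data.
#'
#' @param x Named numeric vector of per-sample global mean methylation, or
#'   a list of `Methylome` objects (means computed with
#'   [methylome_mean()]).
#' @param rule `"anchor_range"` or `"zscore"`.
#' @param anchors For `anchor_range`: length-2 numeric values, or names of
#'   two samples in `x`.
#' @param z_cut z-score magnitude cutoff (default 3).
#' @return An `OutlierReport` list: `means`, `rule`, `flagged` (names or
#'   indices), and `z` for the zscore rule.
#' @export
detect_outliers <- function(x, rule = c("anchor_range", "zscore"),
                            anchors = NULL, z_cut = 3) {
  rule <- match.arg(rule)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "Methylome"))) {
    means <- vapply(x, methylome_mean, numeric(1))
    names(means) <- vapply(x, function(m) m$sample_id, "")
  } else {
    means <- as.numeric(x)
    names(means) <- names(x) %||% as.character(seq_along(x))
  }
  if (rule == "anchor_range") {
    if (is.null(anchors) || length(anchors) != 2) {
      stop("anchor_range needs two anchors", call. = FALSE)
    }
    av <- if (is.character(anchors)) {
      if (!all(anchors %in% names(means))) {
        stop("anchor sample(s) not found", call. = FALSE)
      }
      means[anchors]
    } else {
      as.numeric(anchors)
    }
    lo <- min(av); hi <- max(av)
    flagged <- names(means)[means < lo | means > hi]
    return(structure(list(means = means, rule = rule, flagged = flagged,
                          range = c(lo, hi)),
                     class = "OutlierReport"))
  }
  if (length(means) < 3) stop("zscore rule needs >= 3 samples", call. = FALSE)
  z <- (means - mean(means)) / stats::sd(means)
  flagged <- names(means)[abs(z) > z_cut]
  structure(list(means = means, rule = rule, flagged = flagged, z = z),
            class = "OutlierReport")
}

#' @export
print.OutlierReport <- function(x, ...) {
  cat(sprintf("Outlier screen (%s): %d of %d sample(s) flagged\n",
              x$rule, length(x$flagged), length(x$means)))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Correlate index values with age or passage number
#'
#' Pearson correlation with a two-sided p-value and the least-squares line,
#' the summary used for age series and passage series.
#'
#' @param index Numeric vector of PRC2-AgeIndex values.
#' @param covariate Numeric vector (age in years, or passage number).
#' @return list with `r`, `p`, `intercept`, `slope`, `n`.
#' @export
correlate <- function(index, covariate) {
  stopifnot(length(index) == length(covariate))
  ok <- !is.na(index) & !is.na(covariate)
  index <- index[ok]; covariate <- covariate[ok]
  if (length(index) < 3) stop("need >= 3 paired values", call. = FALSE)
  if (stats::var(covariate) == 0) stop("covariate is constant", call. = FALSE)
  ct <- stats::cor.test(index, covariate, method = "pearson")
  fit <- stats::lm(index ~ covariate)
  list(r = unname(ct$estimate), p = ct$p.value,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]), n = length(index))
}
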