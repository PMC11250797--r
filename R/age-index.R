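# The PRC2-AgeIndex and its companion statistics: per-chromosome indices,
# ranked sliding-window methylation profiles, per-region young/old deltas,
# the hypermethylated fraction, and the share of genome-wide methylation
# gain captured by the high-PRC2 set.

#' Compute the PRC2-AgeIndex of a sample
#'
#' The index is the average DNA methylation within the high-PRC2 LMR set.
#' Two weightings are available: `pooled_cpg` (unweighted mean beta over
#' all covered CpGs inside the set; default, robust to region-size
#' variation) and `region_mean` (mean over regions of their per-region mean
#' betas). Regions with no covered CpG are excluded and counted in the
#' diagnostics rather than imputed.
#'
#' @param m A `Methylome` (any assay).
#' @param hp The high-PRC2 region set (data.frame with chrom/start/end).
#' @param weighting `"pooled_cpg"` or `"region_mean"`.
#' @return An `AgeIndexResult`: list with `sample_id`, `index`,
#'   `n_regions_covered`, `n_cpgs_used`, `weighting`.
#' @export
compute_index <- function(m, hp, weighting = c("pooled_cpg", "region_mean")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(m, "Methylome"))
  assert_regions(hp, "high-PRC2 set")
  if (nrow(hp) == 0) stop("empty high-PRC2 set", call. = FALSE)
  scored <- score_regions(hp[, c("chrom", "start", "end")], m)
  cov_reg <- scored$n_cpgs > 0
  if (!any(cov_reg)) {
    stop("no covered CpG in the high-PRC2 set for sample ", m$sample_id,
         call. = FALSE)
  }
  idx <- if (weighting == "pooled_cpg") {
    sum(scored$mean_level[cov_reg] * scored$n_cpgs[cov_reg]) /
      sum(scored$n_cpgs[cov_reg])
  } else {
    mean(scored$mean_level[cov_reg])
  }
  structure(list(sample_id = m$sample_id, index = idx,
                 n_regions_covered = sum(cov_reg),
                 n_cpgs_used = sum(scored$n_cpgs[cov_reg]),
                 weighting = weighting),
            class = "AgeIndexResult")
}

#' @export
print.AgeIndexResult <- function(x, ...) {
  cat(sprintf("PRC2-AgeIndex [%s] for '%s': %.4f\n", x$weighting,
              x$sample_id, x$index))
  cat(sprintf("  %d region(s) covered, %d CpG(s) used\n",
              x$n_regions_covered, x$n_cpgs_used))
  invisible(x)
}

#' Per-chromosome PRC2-AgeIndex
#'
#' [compute_index()] restricted to each chromosome's members; chromosomes
#' with no covered member are omitted.
#'
#' @inheritParams compute_index
#' @return Named numeric vector, one entry per chromosome with coverage.
#' @export
per_chromosome_index <- function(m, hp, weighting = c("pooled_cpg", "region_mean")) {
  weighting <- match.arg(weighting)
  assert_regions(hp, "high-PRC2 set")
  chroms <- unique(hp$chrom)
  out <- vapply(chroms, function(ch) {
    sub <- hp[hp$chrom == ch, , drop = FALSE]
    tryCatch(compute_index(m, sub, weighting)$index,
             error = function(e) NA_real_)
  }, numeric(1))
  out[!is.na(out)]
}

#' Ranked sliding-window methylation profile
#'
#' Orders regions from lowest to highest PRC2 binding (most bound last) and
#' computes the mean of their per-region mean methylation within sliding
#' windows along the rank axis -- the standard display in which the
#' age-dependent gain concentrates at the right edge. Smoothing is a plain
#' moving average; regions uncovered in the sample are skipped within each
#' window.
#'
#' @param m A `Methylome`.
#' @param scored Ranked scored regions (output of [aggregate_binding()];
#'   `rank` 1 = most bound).
#' @param window Window size in regions (default 100).
#' @param step Step between windows (default 10).
#' @return A `RankedProfile`: list with `centers` (rank coordinate of each
#'   window center, most-bound last), `values`, `window`, `step`.
#' @export
ranked_profile <- function(m, scored, window = 100, step = 10) {
  stopifnot(inherits(m, "Methylome"))
  if (window <= 0 || step <= 0) stop("window and step must be positive",
                                     call. = FALSE)
  if (!"rank" %in% names(scored)) stop("regions must carry ranks", call. = FALSE)
  n <- nrow(scored)
  if (window > n) stop("window exceeds the number of regions", call. = FALSE)
  scored <- score_regions(scored[, c("chrom", "start", "end")],
                          m)[order(scored$rank, decreasing = TRUE), ]
  # now ordered lowest binding first, most bound last
  vals <- scored$mean_level
  n_win <- floor((n - window) / step) + 1
  starts <- (seq_len(n_win) - 1) * step + 1
  values <- vapply(starts, function(s0) {
    w <- vals[s0:(s0 + window - 1)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  structure(list(centers = starts + (window - 1) / 2, values = values,
                 window = window, step = step),
            class = "RankedProfile")
}

#' Per-region methylation change between two samples
#'
#' For each region, delta = mean methylation in `old` minus mean
#' methylation in `young`, each over the CpGs covered in the respective
#' sample. Regions covered in only one sample are dropped and counted in
#' the `n_dropped` attribute.
#'
#' @param regions Region data.frame.
#' @param young,old `Methylome` objects.
#' @return data.frame with `chrom`, `start`, `end`, `mean_young`,
#'   `mean_old`, `delta`.
#' @export
delta_dnam <- function(regions, young, old) {
  assert_regions(regions)
  sy <- score_regions(regions[, c("chrom", "start", "end")], young)
  so <- score_regions(regions[, c("chrom", "start", "end")], old)
  both <- sy$n_cpgs > 0 & so$n_cpgs > 0
  out <- data.frame(chrom = sy$chrom[both], start = sy$start[both],
                    end = sy$end[both], mean_young = sy$mean_level[both],
                    mean_old = so$mean_level[both],
                    delta = so$mean_level[both] - sy$mean_level[both],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!both)
  out
}

#' Fraction of regions that gain methylation
#'
#' Proportion of deltas strictly greater than zero, optionally restricted
#' to a subset (e.g. the high-PRC2 members).
#'
#' @param deltas Output of [delta_dnam()], or a numeric vector of deltas.
#' @param subset Optional logical or integer filter on the records.
#' @return Proportion in `[0, 1]`.
#' @export
fraction_hypermethylated <- function(deltas, subset = NULL) {
  d <- if (is.data.frame(deltas)) deltas$delta else deltas
  if (!is.null(subset)) d <- d[subset]
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("no deltas after subsetting", call. = FALSE)
  mean(d > 0)
}

#' Share of methylation gain captured by the high-PRC2 set
#'
#' Quantifies how much of the positive age-dependent methylation change
#' falls inside the high-PRC2 LMRs. Per-CpG deltas are computed over sites
#' covered in both samples; the numerator sums `max(delta, 0)` over CpGs
#' inside the high-PRC2 set and the denominator sums it over the comparison
#' scope. Scope `"genome"` uses every shared CpG (the literal genome-wide
#' ratio; at low coverage the positive part of symmetric sampling noise
#' inflates the denominator, so group-pooled methylomes are recommended --
#' see [pool_methylomes()]); scope `"lmrs"` restricts the denominator to
#' CpGs inside the full LMR complement, where methylation gain is possible
#' at all.
#'
#' @param young,old Count-based `Methylome` objects (pooling replicates
#'   first is recommended).
#' @param hp High-PRC2 region set.
#' @param all_lmrs Full LMR set (used by scope `"lmrs"`).
#' @param scope `"genome"` (default) or `"lmrs"`.
#' @return list with `gain_in_set`, `gain_total`, `share`.
#' @export
gain_share <- function(young, old, hp, all_lmrs = NULL,
                       scope = c("genome", "lmrs")) {
  scope <- match.arg(scope)
  stopifnot(inherits(young, "Methylome"), inherits(old, "Methylome"))
  assert_regions(hp, "high-PRC2 set")
  if (scope == "lmrs" && is.null(all_lmrs)) {
    stop("scope='lmrs' needs the full LMR set", call. = FALSE)
  }
  ys <- young$sites[covered_sites(young$sites), c("chrom", "pos", "beta")]
  os <- old$sites[covered_sites(old$sites), c("chrom", "pos", "beta")]
  dt <- merge(data.table::as.data.table(ys), data.table::as.data.table(os),
              by = c("chrom", "pos"), suffixes = c("_young", "_old"))
  if (nrow(dt) == 0) stop("no CpG covered in both samples", call. = FALSE)
  delta <- dt$beta_old - dt$beta_young
  gain <- pmax(delta, 0)
  gr_sites <- GenomicRanges::GRanges(dt$chrom,
                                     IRanges::IRanges(dt$pos + 1L, width = 1L))
  in_hp <- overlaps_count(gr_sites, regions_to_gr(hp)) > 0
  denom_mask <- if (scope == "genome") {
    rep(TRUE, nrow(dt))
  } else {
    overlaps_count(gr_sites, regions_to_gr(all_lmrs)) > 0 | in_hp
  }
  gain_total <- sum(gain[denom_mask])
  if (gain_total == 0) stop("no methylation gain anywhere in scope", call. = FALSE)
  gain_in_set <- sum(gain[in_hp & denom_mask])
  list(gain_in_set = gain_in_set, gain_total = gain_total,
       share = gain_in_set / gain_total)
}
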