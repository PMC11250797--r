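# Aggregation of PRC2 (EZH2/SUZ12) ChIP signal over LMRs, blacklist
# filtering, top-k selection, and the site-level LMC variant.

#' Aggregate ChIP signal over regions and rank them
#'
#' Per factor, a region's score is the base-length-weighted mean of the
#' signal track over `[start, end)`, with uncovered bases contributing 0
#' (fold-change semantics) or 1 (p-value semantics). The PRC2 score is the
#' unweighted mean across factors (e.g. EZH2 and SUZ12), and regions are
#' ranked with rank 1 = most bound: highest score for fold-change, lowest
#' mean p for p-value semantics. Ties are broken by genomic coordinate.
#'
#' @param regions Region data.frame.
#' @param tracks A `SignalTrack` or list of them; all must share semantics.
#' @return data.frame of scored regions with one `score_<factor>` column
#'   per track, `prc2_score` and `rank`; attribute `semantics` records the
#'   score direction.
#' @export
aggregate_binding <- function(regions, tracks) {
  assert_regions(regions)
  if (inherits(tracks, "SignalTrack")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1,
            all(vapply(tracks, inherits, TRUE, "SignalTrack")))
  sem <- unique(vapply(tracks, function(t) t$semantics, ""))
  if (length(sem) != 1) {
    stop("all tracks must share semantics (got: ",
         paste(sem, collapse = ", "), ")", call. = FALSE)
  }
  pad <- if (sem == "p_value") 1 else 0
  nm <- names(tracks) %||% NULL
  if (is.null(nm)) nm <- sprintf("factor%d", seq_along(tracks))
  nm[nm == ""] <- sprintf("factor%d", which(nm == ""))

  gr_r <- regions_to_gr(regions)
  len <- regions$end - regions$start
  scores <- matrix(NA_real_, nrow(regions), length(tracks),
                   dimnames = list(NULL, paste0("score_", nm)))
  for (f in seq_along(tracks)) {
    iv <- tracks[[f]]$intervals
    total <- rep(0, nrow(regions))
    covered <- rep(0, nrow(regions))
    if (nrow(iv) > 0) {
      gr_t <- regions_to_gr(iv)
      hits <- overlaps_hits(gr_r, gr_t)
      if (length(hits) > 0) {
        ow <- GenomicRanges::width(GenomicRanges::pintersect(
          gr_r[S4Vectors::queryHits(hits)], gr_t[S4Vectors::subjectHits(hits)]))
        v <- iv$value[S4Vectors::subjectHits(hits)]
        agg <- rowsum(cbind(v * ow, ow), S4Vectors::queryHits(hits))
        ridx <- as.integer(rownames(agg))
        total[ridx] <- agg[, 1]
        covered[ridx] <- agg[, 2]
      }
    }
    scores[, f] <- (total + pad * (len - covered)) / len
  }
  out <- regions
  out <- cbind(out, as.data.frame(scores))
  out$prc2_score <- rowMeans(scores)
  ord <- if (sem == "p_value") {
    order(out$prc2_score, out$chrom, out$start)
  } else {
    order(-out$prc2_score, out$chrom, out$start)
  }
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "semantics") <- sem
  out
}

#' Remove regions overlapping a blacklist
#'
#' Any region overlapping any blacklist interval by at least one base is
#' removed before ranking.
#'
#' @param regions Region data.frame.
#' @param blacklist Region data.frame of artifact-prone intervals.
#' @return The retained regions.
#' @export
filter_blacklist <- function(regions, blacklist) {
  assert_regions(regions)
  if (nrow(regions) == 0 || is.null(blacklist) || nrow(blacklist) == 0) {
    return(regions)
  }
  assert_regions(blacklist, "blacklist")
  hits <- overlaps_hits(regions_to_gr(regions),
                                      regions_to_gr(blacklist))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) return(regions)
  out <- regions[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k selection configuration
#' @param k Size of the high-PRC2 set (default 1000, the standard choice).
#' @param semantics `"fold_change"` (highest k selected) or `"p_value"`
#'   (lowest k selected).
#' @return A list of class `SelectionConfig`.
#' @export
selection_config <- function(k = 1000, semantics = c("fold_change", "p_value")) {
  semantics <- match.arg(semantics)
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), semantics = semantics),
            class = "SelectionConfig")
}

#' Select the high-PRC2 set
#'
#' Keeps the `k` most PRC2-bound regions under the declared semantics, ties
#' broken by (chrom, start). Membership is invariant to input order.
#'
#' @param scored Output of [aggregate_binding()].
#' @param cfg A [selection_config()]; its semantics must match the scores'.
#' @return A `HighPRC2Set`: data.frame of the selected regions ordered by
#'   rank, with attributes `k` and `semantics`.
#' @export
select_top_k <- function(scored, cfg = selection_config()) {
  stopifnot(inherits(cfg, "SelectionConfig"))
  if (is.null(scored) || nrow(scored) == 0) {
    stop("select_top_k: empty input", call. = FALSE)
  }
  if (!"prc2_score" %in% names(scored)) {
    stop("select_top_k: scores missing; run aggregate_binding first",
         call. = FALSE)
  }
  sem <- attr(scored, "semantics") %||% cfg$semantics
  if (sem != cfg$semantics) {
    stop("semantics mismatch between scores (", sem, ") and config (",
         cfg$semantics, ")", call. = FALSE)
  }
  ord <- if (sem == "p_value") {
    order(scored$prc2_score, scored$chrom, scored$start)
  } else {
    order(-scored$prc2_score, scored$chrom, scored$start)
  }
  k <- cfg$k
  if (k > nrow(scored)) {
    warning(sprintf("k = %d exceeds the %d available regions; returning all",
                    k, nrow(scored)))
    k <- nrow(scored)
  }
  out <- scored[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  attr(out, "k") <- cfg$k
  attr(out, "semantics") <- sem
  class(out) <- c("HighPRC2Set", class(out))
  out
}

#' Rank low-methylated CpGs (LMCs) by PRC2 binding
#'
#' The site-level variant used when regions cannot be segmented (arrays,
#' RRBS, single-cell): sites whose baseline methylation across the
#' reference methylome(s) is below `low_threshold` are retained, each site's
#' PRC2 signal is the track value at its position (mean across factors),
#' and sites are ranked as in [select_top_k()].
#'
#' @param reference A `Methylome` or list of them defining the baseline
#'   beta per site (unweighted mean across the references).
#' @param tracks A `SignalTrack` or list of them.
#' @param low_threshold Baseline beta below which a site counts as
#'   low-methylated (default 0.3).
#' @return A `RankedSites` data.frame: `chrom`, `pos`, `ref_beta`,
#'   `signal`, `rank` (1 = most bound), sorted by rank.
#' @export
rank_lmcs <- function(reference, tracks, low_threshold = 0.3) {
  if (inherits(reference, "Methylome")) reference <- list(reference)
  stopifnot(length(reference) >= 1,
            all(vapply(reference, inherits, TRUE, "Methylome")))
  if (inherits(tracks, "SignalTrack")) tracks <- list(tracks)
  sem <- unique(vapply(tracks, function(t) t$semantics, ""))
  if (length(sem) != 1) stop("all tracks must share semantics", call. = FALSE)
  pad <- if (sem == "p_value") 1 else 0

  dt <- data.table::rbindlist(lapply(reference, function(m) {
    s <- m$sites[covered_sites(m$sites), c("chrom", "pos", "beta")]
    data.table::as.data.table(s)
  }))
  base <- dt[, list(ref_beta = mean(beta)), by = c("chrom", "pos")]
  base <- base[base$ref_beta < low_threshold, ]
  if (nrow(base) == 0) {
    stop("no site passes the low-methylation threshold", call. = FALSE)
  }
  base <- base[order(base$chrom, base$pos), ]

  sig <- matrix(pad, nrow(base), length(tracks))
  gr_s <- GenomicRanges::GRanges(base$chrom,
                                 IRanges::IRanges(base$pos + 1L, width = 1L))
  for (f in seq_along(tracks)) {
    iv <- tracks[[f]]$intervals
    if (nrow(iv) == 0) next
    hits <- overlaps_hits(gr_s, regions_to_gr(iv))
    sig[S4Vectors::queryHits(hits), f] <- iv$value[S4Vectors::subjectHits(hits)]
  }
  out <- data.frame(chrom = base$chrom, pos = base$pos,
                    ref_beta = base$ref_beta, signal = rowMeans(sig),
                    stringsAsFactors = FALSE)
  ord <- if (sem == "p_value") {
    order(out$signal, out$chrom, out$pos)
  } else {
    order(-out$signal, out$chrom, out$pos)
  }
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "semantics") <- sem
  attr(out, "low_threshold") <- low_threshold
  class(out) <- c("RankedSites", class(out))
  out
}

#' Filter regions or ranked sites by CpG density
#'
#' Keeps elements whose CpG density reaches `min_cpgs_per_kb`, the guard
#' used for sparse single-cell data. For regions the density is
#' `n_cpgs / (length in kb)` (CpGs counted from `methylome` when given,
#' otherwise the existing `n_cpgs` column); for `RankedSites` it is the
#' number of reference CpGs within a centered window.
#'
#' @param x Region data.frame or `RankedSites`.
#' @param min_cpgs_per_kb Density cutoff (default 10).
#' @param methylome Optional `Methylome` providing CpG coordinates.
#' @param window Window size in bp for site densities (default 1000).
#' @return The filtered object.
#' @export
density_filter <- function(x, min_cpgs_per_kb = 10, methylome = NULL,
                           window = 1000) {
  if (inherits(x, "RankedSites")) {
    if (is.null(methylome)) {
      stop("density_filter on sites needs a methylome for CpG coordinates",
           call. = FALSE)
    }
    half <- window / 2
    reg <- data.frame(chrom = x$chrom,
                      start = pmax(0L, as.integer(x$pos - half)),
                      end = as.integer(x$pos + half))
    counts <- score_regions(reg, methylome)$n_cpgs
    dens <- counts / (window / 1000)
    out <- x[dens >= min_cpgs_per_kb, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  assert_regions(x)
  if (!is.null(methylome)) x <- score_regions(x, methylome)
  if (!"n_cpgs" %in% names(x)) {
    stop("regions need an n_cpgs column (or pass a methylome)", call. = FALSE)
  }
  dens <- x$n_cpgs / ((x$end - x$start) / 1000)
  out <- x[dens >= min_cpgs_per_kb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance between two high-PRC2 sets
#'
#' Fraction of `a`'s members overlapping any member of `b` (>= 1 bp), plus
#' the Spearman correlation of ranks over the overlapping pairs. Summarizes
#' how well two rankings (e.g. ESC-based vs tissue-specific ChIP) agree.
#'
#' @param a,b `HighPRC2Set` (or any ranked region data.frames) on the same
#'   genome.
#' @return list with `overlap` and `rank_cor`.
#' @export
rank_concordance <- function(a, b) {
  assert_regions(a, "a"); assert_regions(b, "b")
  if (nrow(a) == 0) return(list(overlap = NA_real_, rank_cor = NA_real_))
  hits <- overlaps_hits(regions_to_gr(a), regions_to_gr(b))
  overlap <- length(unique(S4Vectors::queryHits(hits))) / nrow(a)
  rank_cor <- NA_real_
  if (length(hits) >= 3 && all(c("rank") %in% names(a)) &&
      "rank" %in% names(b)) {
    first <- !duplicated(S4Vectors::queryHits(hits))
    ra <- a$rank[S4Vectors::queryHits(hits)[first]]
    rb <- b$rank[S4Vectors::subjectHits(hits)[first]]
    if (length(unique(ra)) > 1 && length(unique(rb)) > 1) {
      rank_cor <- stats::cor(ra, rb, method = "spearman")
    }
  }
  list(overlap = overlap, rank_cor = rank_cor)
}
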