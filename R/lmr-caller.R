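# Two-state beta-binomial HMM segmentation of a methylome into
# low-methylated regions (LMRs). The genome alternates between a highly
# methylated background state and a hypomethylated state; per-CpG
# (meth_count, total_count) pairs are modelled with beta-binomial emissions
# to absorb the overdispersion of real bisulfite data. Chains are broken at
# CpG deserts so that segments never bridge large assay gaps.

#' HMM segmentation parameters
#'
#' Defaults are deliberately fixed and documented (no random restarts), so
#' segmentation is deterministic for a given methylome.
#'
#' @param p_stay Initial per-state self-transition probability.
#' @param mean_low,mean_high Initial emission means of the low and high
#'   methylation states; the reported low state always ends up the one with
#'   the smaller fitted mean, regardless of initialization.
#' @param precision Beta-binomial precision (alpha + beta) of the emission
#'   distributions, held fixed during EM; smaller values allow more
#'   overdispersion.
#' @param desert_size Inter-CpG gap in bp above which the HMM chain is
#'   split; regions never span a desert.
#' @param min_cpgs Minimum CpGs for a reported region.
#' @param max_iter,tol Baum-Welch stopping controls: stop when the
#'   log-likelihood improves by less than `tol`, or after `max_iter`
#'   iterations (with a warning).
#' @param posterior_cut Posterior probability threshold for calling a CpG
#'   low-state during decoding.
#' @param decoding `"posterior"` (forward-backward, default) or `"viterbi"`.
#' @return A list of class `HmmParams`.
#' @export
hmm_params <- function(p_stay = 0.95, mean_low = 0.1, mean_high = 0.8,
                       precision = 15, desert_size = 1000, min_cpgs = 10,
                       max_iter = 100, tol = 1e-4, posterior_cut = 0.5,
                       decoding = c("posterior", "viterbi")) {
  decoding <- match.arg(decoding)
  stopifnot(p_stay > 0, p_stay < 1, mean_low < mean_high,
            mean_low > 0, mean_high < 1, precision > 0,
            desert_size > 0, min_cpgs >= 1, max_iter >= 1, tol > 0,
            posterior_cut > 0, posterior_cut < 1)
  structure(list(p_stay = p_stay, mean_low = mean_low, mean_high = mean_high,
                 precision = precision, desert_size = desert_size,
                 min_cpgs = min_cpgs, max_iter = max_iter, tol = tol,
                 posterior_cut = posterior_cut, decoding = decoding),
            class = "HmmParams")
}

# log beta-binomial pmf parameterized by mean m and precision s.
dbetabinom_log <- function(k, n, m, s) {
  a <- m * s
  b <- (1 - m) * s
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Segment a methylome into low-methylated regions
#'
#' Fits a two-state HMM with beta-binomial emissions by Baum-Welch EM
#' (transition probabilities in closed form; state means by 1-D numerical
#' maximization of the weighted emission likelihood at fixed precision),
#' then reports maximal runs of CpGs whose low-state posterior reaches
#' `posterior_cut` and that contain at least `min_cpgs` CpGs. Chains are
#' split at inter-CpG gaps larger than `desert_size` and at chromosome
#' boundaries. Region ends are half-open: `end = last CpG position + 1`.
#'
#' @param m A count-based `Methylome` (array and single-cell methylomes are
#'   rejected; the site-level LMC path serves them).
#' @param params An [hmm_params()] list.
#' @return A `SegmentationResult`: list with `regions` (data.frame of
#'   chrom/start/end/n_cpgs/mean_level), fitted `params`, `loglik_trace`,
#'   `n_iter` and `converged`.
#' @export
call_lmrs <- function(m, params = hmm_params()) {
  stopifnot(inherits(m, "Methylome"), inherits(params, "HmmParams"))
  if (m$assay %in% c("array", "scwgbs")) {
    stop("call_lmrs requires a count-based bulk methylome (assay '", m$assay,
         "'); use the LMC ranking path for arrays and single-cell data",
         call. = FALSE)
  }
  s <- m$sites
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), mean_level = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(s) == 0 || !any(covered_sites(s))) {
    return(structure(list(regions = empty, params = params,
                          loglik_trace = numeric(), n_iter = 0L,
                          converged = TRUE),
                     class = "SegmentationResult"))
  }
  if (all(is.na(s$total_count))) {
    stop("call_lmrs needs meth/total counts", call. = FALSE)
  }

  # keep chromosomes with enough sites to ever report a region
  chrom_n <- table(s$chrom)
  keep_chroms <- names(chrom_n)[chrom_n >= params$min_cpgs]
  s <- s[s$chrom %in% keep_chroms, , drop = FALSE]
  if (nrow(s) == 0) {
    return(structure(list(regions = empty, params = params,
                          loglik_trace = numeric(), n_iter = 0L,
                          converged = TRUE),
                     class = "SegmentationResult"))
  }

  k <- s$meth_count
  n <- s$total_count
  k[is.na(k)] <- 0L
  n[is.na(n)] <- 0L

  # chain ids: new chain at chromosome change or desert gap
  newchr <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)])
  gap <- c(0L, diff(s$pos))
  chain <- cumsum(newchr | (gap > params$desert_size))

  # aggregate by unique (k, n) so EM cost is independent of genome size
  uid <- k * (max(n) + 1) + n
  u <- !duplicated(uid)
  ku <- k[u]; nu <- n[u]
  idx <- match(uid, uid[u])

  means <- c(params$mean_low, params$mean_high)
  prec <- params$precision
  trans <- matrix(c(params$p_stay, 1 - params$p_stay,
                    1 - params$p_stay, params$p_stay), 2, 2, byrow = TRUE)
  init <- c(0.5, 0.5)

  chains <- split(seq_len(nrow(s)), chain)
  trace <- numeric(0)
  converged <- FALSE
  gamma <- NULL

  for (iter in seq_len(params$max_iter)) {
    logemit_u <- cbind(dbetabinom_log(ku, nu, means[1], prec),
                       dbetabinom_log(ku, nu, means[2], prec))
    logemit <- logemit_u[idx, , drop = FALSE]

    loglik <- 0
    xi <- matrix(0, 2, 2)
    gamma <- matrix(0, nrow(s), 2)
    for (ix in chains) {
      fb <- .fb_two_state(logemit[ix, , drop = FALSE], trans, init)
      loglik <- loglik + fb$loglik
      xi <- xi + fb$xi
      gamma[ix, ] <- fb$gamma
    }
    trace <- c(trace, loglik)
    if (iter > 1 && abs(loglik - trace[iter - 1]) < params$tol) {
      converged <- TRUE
      break
    }

    # M-step: transitions in closed form, means by 1-D maximization of the
    # expected complete-data emission log-likelihood (precision fixed)
    rs <- rowSums(xi)
    if (all(rs > 0)) {
      trans <- xi / rs
      trans[] <- pmin(pmax(trans, 1e-8), 1 - 1e-8)
      trans <- trans / rowSums(trans)
    }
    for (st in 1:2) {
      w <- rowsum(gamma[, st], idx)
      wk <- ku[as.integer(rownames(w))]
      wn <- nu[as.integer(rownames(w))]
      f <- function(mm) sum(w * (lbeta(wk + mm * prec, wn - wk + (1 - mm) * prec) -
                                   lbeta(mm * prec, (1 - mm) * prec)))
      means[st] <- optimize(f, interval = c(1e-4, 1 - 1e-4),
                            maximum = TRUE, tol = 1e-6)$maximum
    }
    # label symmetry: state 1 is always the low-methylation state
    if (means[1] > means[2]) {
      means <- rev(means)
      trans <- trans[2:1, 2:1]
      gamma <- gamma[, 2:1, drop = FALSE]
    }
  }
  if (!converged) {
    warning("EM did not converge within max_iter; using last iterate")
  }

  fitted <- params
  fitted$mean_low <- means[1]
  fitted$mean_high <- means[2]
  fitted$p_stay <- c(low = trans[1, 1], high = trans[2, 2])

  # degeneracy guard: on a uniformly methylated methylome the two states
  # collapse onto the background; a "low" state that is not hypomethylated
  # in absolute terms (mean >= 0.5) is not an LMR state
  if (means[1] >= 0.5) {
    message("call_lmrs: low-state mean ", sprintf("%.3f", means[1]),
            " is not hypomethylated; no LMRs reported")
    return(structure(list(regions = empty, params = fitted,
                          loglik_trace = trace, n_iter = length(trace),
                          converged = converged),
                     class = "SegmentationResult"))
  }

  # decode
  if (params$decoding == "viterbi") {
    logemit_u <- cbind(dbetabinom_log(ku, nu, means[1], prec),
                       dbetabinom_log(ku, nu, means[2], prec))
    logemit <- logemit_u[idx, , drop = FALSE]
    low <- logical(nrow(s))
    for (ix in chains) {
      low[ix] <- .viterbi_two_state(logemit[ix, , drop = FALSE], trans, init) == 0L
    }
  } else {
    low <- gamma[, 1] >= params$posterior_cut
  }

  regions <- decode_runs(s, low, chain, params$min_cpgs)
  structure(list(regions = regions, params = fitted, loglik_trace = trace,
                 n_iter = length(trace), converged = converged),
            class = "SegmentationResult")
}

# Turn a per-CpG low-state indicator into regions: maximal low runs within
# a chain, filtered by min_cpgs.
decode_runs <- function(s, low, chain, min_cpgs) {
  grp <- cumsum(c(TRUE, diff(chain) != 0 | diff(low) != 0))
  keep <- which(low)
  if (length(keep) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), mean_level = numeric(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::data.table(
    grp = grp[keep], chrom = s$chrom[keep], pos = s$pos[keep],
    beta = s$beta[keep], covered = covered_sites(s[keep, , drop = FALSE])
  )
  runs <- dt[, list(chrom = chrom[1], start = pos[1], end = pos[.N] + 1L,
                    n_cpgs = sum(covered),
                    mean_level = mean(beta[covered]), n_total = .N),
             by = "grp"]
  runs <- runs[runs$n_total >= min_cpgs & runs$n_cpgs > 0, ]
  out <- data.frame(chrom = runs$chrom, start = runs$start, end = runs$end,
                    n_cpgs = as.integer(runs$n_cpgs),
                    mean_level = runs$mean_level, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("SegmentationResult: %d LMR(s); EM %s after %d iteration(s)\n",
              nrow(x$regions),
              if (x$converged) "converged" else "stopped",
              x$n_iter))
  cat(sprintf("  fitted emission means: low %.4f, high %.4f\n",
              x$params$mean_low, x$params$mean_high))
  invisible(x)
}

#' Annotate regions with CpG counts and mean methylation
#'
#' For each region, counts the covered CpGs inside `[start, end)` and takes
#' the unweighted mean of their betas. Regions overlapping no covered CpG
#' get `n_cpgs = 0` and `mean_level = NA`.
#'
#' @param regions Region data.frame (`chrom`, `start`, `end`), sorted.
#' @param m A `Methylome`.
#' @return `regions` with `n_cpgs` and `mean_level` columns (re)filled.
#' @export
score_regions <- function(regions, m) {
  assert_regions(regions)
  stopifnot(inherits(m, "Methylome"))
  regions$n_cpgs <- 0L
  regions$mean_level <- NA_real_
  s <- m$sites[covered_sites(m$sites), , drop = FALSE]
  if (nrow(s) == 0 || nrow(regions) == 0) return(regions)
  hits <- overlaps_hits(sites_to_gr(s), regions_to_gr(regions))
  if (length(hits) == 0) return(regions)
  agg <- rowsum(cbind(s$beta[S4Vectors::queryHits(hits)], 1),
                S4Vectors::subjectHits(hits))
  ridx <- as.integer(rownames(agg))
  regions$n_cpgs[ridx] <- as.integer(agg[, 2])
  regions$mean_level[ridx] <- agg[, 1] / agg[, 2]
  regions
}
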