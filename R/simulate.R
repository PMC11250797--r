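# Synthetic methylome and ChIP-track generator. Plants the genome
# architecture the method assumes -- hypomethylated islands in a highly
# methylated background, age-dependent global background loss, and
# age-dependent gain confined to the PRC2-bound LMR subset -- together
# with correlated two-factor ChIP tracks and assay downsamplers, so every
# stage of the pipeline can be tested against known ground truth.

#' Simulation parameters
#'
#' Defaults encode the study conditions the method targets: a highly
#' methylated background (beta 0.85) slowly losing methylation with age
#' (0.001/year), hypomethylated LMRs (beta 0.05) of which the PRC2-target
#' subset gains 0.004/year, Poisson coverage 30 with mild beta-binomial
#' overdispersion, and ChIP fold enrichment well separated between targets
#' and non-targets.
#'
#' @param m_bg0 Baseline background beta.
#' @param m_low0 Baseline LMR beta.
#' @param loss_rate Background beta loss per year.
#' @param gain_rate PRC2-target LMR beta gain per year.
#' @param beta_floor,beta_ceiling Clamps applied to true betas.
#' @param mean_coverage Mean per-CpG read coverage (Poisson).
#' @param dispersion Beta-binomial dispersion rho in `[0, 1)`; 0 gives
#'   pure binomial sampling.
#' @param chip_target_mean,chip_target_sd Fold-enrichment distribution of
#'   PRC2-target LMRs.
#' @param chip_nontarget_mean,chip_nontarget_sd Fold-enrichment
#'   distribution of non-target LMRs.
#' @param chip_noise_sd Per-bin factor-specific noise SD of emitted tracks.
#' @param chip_baseline Background track level outside LMRs.
#' @param chip_bin Bin width (bp) of the piecewise-constant track inside
#'   LMRs.
#' @return A list of class `SimParams`.
#' @export
sim_params <- function(m_bg0 = 0.85, m_low0 = 0.05, loss_rate = 0.001,
                       gain_rate = 0.004, beta_floor = 0.01,
                       beta_ceiling = 0.99, mean_coverage = 30,
                       dispersion = 0.02, chip_target_mean = 8,
                       chip_target_sd = 1.5, chip_nontarget_mean = 1,
                       chip_nontarget_sd = 0.3, chip_noise_sd = 1,
                       chip_baseline = 0.1, chip_bin = 200) {
  stopifnot(m_bg0 > m_low0, loss_rate >= 0, gain_rate >= 0,
            beta_floor >= 0, beta_ceiling <= 1, beta_floor < beta_ceiling,
            mean_coverage > 0, dispersion >= 0, dispersion < 1,
            chip_target_mean > chip_nontarget_mean, chip_bin >= 1)
  structure(as.list(environment()), class = "SimParams")
}

#' Plant a genome layout of LMRs and CpG positions
#'
#' Places `n_lmrs` disjoint LMR intervals (log-normal lengths around 3 kb)
#' on the chromosome(s), assigns a fraction of them as PRC2 targets with
#' high true binding strength, and lays down CpG positions: roughly one per
#' 100 bp in the background and one per 10 bp inside LMRs (LMRs are
#' CpG-dense regulatory islands).
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param n_lmrs Total number of LMRs planted.
#' @param target_fraction Fraction of LMRs that are PRC2 targets.
#' @param seed Integer seed; the layout is reproducible given the seed.
#' @param mean_lmr_len Mean LMR length (bp).
#' @param lmr_len_sdlog Log-scale SD of LMR lengths.
#' @param bg_spacing,lmr_spacing Mean inter-CpG spacing (bp) outside and
#'   inside LMRs.
#' @param min_gap Minimum gap between planted LMRs (bp).
#' @param params A [sim_params()] list (binding-strength distributions).
#' @return A `SimLayout`: list with `chrom_lens`, `lmrs` (data.frame with
#'   `chrom`, `start`, `end`, `is_target`, `strength`), and `cpgs`
#'   (data.frame with `chrom`, `pos`, `lmr` index or NA).
#' @export
make_layout <- function(n_chroms = 1, chrom_len = 10e6, n_lmrs = 50,
                        target_fraction = 0.5, seed = 1,
                        mean_lmr_len = 3000, lmr_len_sdlog = 0.285,
                        bg_spacing = 100, lmr_spacing = 10,
                        min_gap = 5000, params = sim_params()) {
  stopifnot(n_chroms >= 1, n_lmrs >= 0, target_fraction >= 0,
            target_fraction <= 1)
  with_seed(seed, {
    per_chrom <- diff(round(seq(0, n_lmrs, length.out = n_chroms + 1)))
    lmr_list <- list()
    cpg_list <- list()
    lmr_id0 <- 0L
    for (ci in seq_len(n_chroms)) {
      chrom <- sprintf("chr%d", ci)
      nl <- per_chrom[ci]
      lens <- if (nl > 0) {
        pmax(200L, round(rlnorm(nl, log(mean_lmr_len) - lmr_len_sdlog^2 / 2,
                                lmr_len_sdlog)))
      } else integer(0)
      free <- chrom_len - sum(lens) - (nl + 1) * min_gap
      if (free < 0) {
        stop("infeasible packing: LMRs plus minimum gaps exceed chromosome",
             call. = FALSE)
      }
      w <- diff(c(0, sort(runif(nl)), 1))
      gaps <- min_gap + floor(free * w)
      starts <- integer(nl)
      at <- 0L
      for (i in seq_len(nl)) {
        at <- at + gaps[i]
        starts[i] <- at
        at <- at + lens[i]
      }
      lmrs <- data.frame(chrom = chrom, start = starts,
                         end = starts + lens, stringsAsFactors = FALSE)
      # CpGs: background segments between/around LMRs, dense inside LMRs
      seg_bounds <- rbind(
        cbind(c(0L, lmrs$end), c(lmrs$start, chrom_len)))
      pos_list <- list()
      lmr_of <- list()
      for (si in seq_len(nrow(seg_bounds))) {
        p <- draw_positions(seg_bounds[si, 1], seg_bounds[si, 2], bg_spacing)
        pos_list[[length(pos_list) + 1]] <- p
        lmr_of[[length(lmr_of) + 1]] <- rep(NA_integer_, length(p))
      }
      for (li in seq_len(nl)) {
        p <- draw_positions(lmrs$start[li], lmrs$end[li], lmr_spacing)
        pos_list[[length(pos_list) + 1]] <- p
        lmr_of[[length(lmr_of) + 1]] <- rep(lmr_id0 + li, length(p))
      }
      pos <- unlist(pos_list)
      lof <- unlist(lmr_of)
      o <- order(pos)
      cpg_list[[ci]] <- data.frame(chrom = chrom, pos = pos[o], lmr = lof[o],
                                   stringsAsFactors = FALSE)
      lmr_list[[ci]] <- lmrs
      lmr_id0 <- lmr_id0 + nl
    }
    lmrs <- do.call(rbind, lmr_list)
    n_target <- round(n_lmrs * target_fraction)
    is_target <- rep(FALSE, n_lmrs)
    if (n_target > 0) is_target[sample.int(n_lmrs, n_target)] <- TRUE
    strength <- ifelse(
      is_target,
      pmax(0.5, rnorm(n_lmrs, params$chip_target_mean, params$chip_target_sd)),
      pmax(0.05, rnorm(n_lmrs, params$chip_nontarget_mean,
                       params$chip_nontarget_sd)))
    lmrs$is_target <- is_target
    lmrs$strength <- strength
    structure(list(
      chrom_lens = stats::setNames(rep(chrom_len, n_chroms),
                                   sprintf("chr%d", seq_len(n_chroms))),
      lmrs = lmrs,
      cpgs = do.call(rbind, cpg_list),
      seed = seed
    ), class = "SimLayout")
  })
}

# Strictly increasing integer positions in [from, to) with geometric
# spacing of the given mean (minimum 2 bp: CpG dyads cannot overlap).
draw_positions <- function(from, to, spacing) {
  len <- to - from
  if (len < 2) return(integer(0))
  n_guess <- ceiling(len / spacing * 1.6) + 10
  steps <- 2L + stats::rgeom(n_guess, 1 / (spacing - 1))
  pos <- from + cumsum(steps)
  pos[pos < to - 1]
}

#' @export
print.SimLayout <- function(x, ...) {
  cat(sprintf("SimLayout: %d chromosome(s), %d LMR(s) (%d PRC2 target(s)), %d CpG(s)\n",
              length(x$chrom_lens), nrow(x$lmrs), sum(x$lmrs$is_target),
              nrow(x$cpgs)))
  invisible(x)
}

#' Simulate a count-based methylome at a given age
#'
#' True per-CpG betas follow the planted architecture: background CpGs sit
#' at `m_bg0 - loss_rate * age`, non-target LMR CpGs stay at `m_low0`, and
#' PRC2-target LMR CpGs rise to `m_low0 + gain_rate * age`; all clamped to
#' `[beta_floor, beta_ceiling]`. Observed coverage is Poisson and
#' methylated counts are beta-binomial around the true beta.
#'
#' @param layout A [make_layout()] result.
#' @param age Age in years (>= 0).
#' @param params A [sim_params()] list.
#' @param seed Integer seed; identical seeds give identical methylomes.
#' @param sample_id Optional sample identifier.
#' @return A count-based `Methylome` (assay `"wgbs"`, strand `"."`).
#' @export
simulate_methylome <- function(layout, age, params = sim_params(), seed = 1,
                               sample_id = NULL) {
  stopifnot(inherits(layout, "SimLayout"), age >= 0,
            inherits(params, "SimParams"))
  if (is.null(sample_id)) sample_id <- sprintf("sim_age%g_seed%d", age, seed)
  cp <- layout$cpgs
  is_lmr <- !is.na(cp$lmr)
  is_target <- is_lmr & layout$lmrs$is_target[ifelse(is_lmr, cp$lmr, 1L)]
  truth <- ifelse(is_target, params$m_low0 + params$gain_rate * age,
                  ifelse(is_lmr, params$m_low0,
                         params$m_bg0 - params$loss_rate * age))
  truth <- pmin(pmax(truth, params$beta_floor), params$beta_ceiling)
  with_seed(seed, {
    n <- stats::rpois(nrow(cp), params$mean_coverage)
    p <- if (params$dispersion > 0) {
      s <- (1 - params$dispersion) / params$dispersion
      stats::rbeta(nrow(cp), truth * s, (1 - truth) * s)
    } else truth
    k <- stats::rbinom(nrow(cp), n, p)
    sites <- data.frame(
      chrom = cp$chrom, pos = cp$pos, strand = ".",
      meth_count = k, total_count = n,
      beta = ifelse(n > 0, k / n, NA_real_), stringsAsFactors = FALSE
    )
    new_methylome(sites, sample_id, "wgbs")
  })
}

#' Simulate correlated ChIP fold-enrichment tracks
#'
#' Each factor's track is piecewise constant: background gaps at
#' `chip_baseline` and, inside each LMR, bins of `chip_bin` bp at the LMR's
#' true binding strength plus factor-specific Gaussian noise (clipped at
#' zero). Two factors emulate EZH2 and SUZ12: different noise, same
#' underlying strengths.
#'
#' @param layout A [make_layout()] result.
#' @param n_factors Number of factors (default 2).
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @return A named list of `SignalTrack` objects (fold-change semantics).
#' @export
simulate_chip_tracks <- function(layout, n_factors = 2, params = sim_params(),
                                 seed = 1) {
  stopifnot(inherits(layout, "SimLayout"), n_factors >= 1)
  factor_names <- c("ezh2", "suz12", sprintf("factor%d", seq_len(max(0, n_factors - 2)) + 2))
  factor_names <- factor_names[seq_len(n_factors)]
  lmrs <- layout$lmrs
  out <- list()
  for (f in seq_len(n_factors)) {
    iv_list <- with_seed(derive_seed(seed, f), {
      lapply(seq_len(nrow(lmrs)), function(li) {
        st <- lmrs$start[li]; en <- lmrs$end[li]
        brk <- unique(c(seq(st, en, by = params$chip_bin), en))
        nb <- length(brk) - 1
        data.frame(chrom = lmrs$chrom[li], start = brk[-length(brk)],
                   end = brk[-1],
                   value = pmax(0, lmrs$strength[li] +
                                  stats::rnorm(nb, 0, params$chip_noise_sd)),
                   stringsAsFactors = FALSE)
      })
    })
    lmr_iv <- do.call(rbind, iv_list)
    bg_list <- lapply(names(layout$chrom_lens), function(ch) {
      l <- lmrs[lmrs$chrom == ch, , drop = FALSE]
      bounds <- cbind(c(0L, l$end), c(l$start, layout$chrom_lens[[ch]]))
      keep <- bounds[, 1] < bounds[, 2]
      data.frame(chrom = ch, start = bounds[keep, 1], end = bounds[keep, 2],
                 value = params$chip_baseline, stringsAsFactors = FALSE)
    })
    iv <- rbind(lmr_iv, do.call(rbind, bg_list))
    iv <- iv[iv$value != 0, , drop = FALSE]
    out[[factor_names[f]]] <- new_signal_track(iv, "fold_change")
  }
  out
}

#' Simulate a cohort of methylomes
#'
#' One global seed; each sample uses a derived substream so adding a sample
#' never perturbs existing ones.
#'
#' @param layout A [make_layout()] result.
#' @param ages Numeric vector of ages, one per sample.
#' @param params A [sim_params()] list.
#' @param seed Global integer seed.
#' @param prefix Sample-id prefix.
#' @return Named list of `Methylome` objects.
#' @export
simulate_cohort <- function(layout, ages, params = sim_params(), seed = 1,
                            prefix = "sim") {
  out <- lapply(seq_along(ages), function(i) {
    simulate_methylome(layout, ages[i], params,
                       seed = derive_seed(seed, 100 + i),
                       sample_id = sprintf("%s_%02d_age%g", prefix, i, ages[i]))
  })
  names(out) <- vapply(out, function(m) m$sample_id, "")
  out
}

# ---- assay downsamplers ----------------------------------------------------

#' Downsample a methylome to an array-like beta table
#'
#' Keeps a seeded random subset of sites (each kept independently with
#' probability `probe_fraction`, emulating the sparse probe set of a
#' methylation array covering ~1.5% of genomic CpGs), drops the counts and
#' carries the beta values only.
#'
#' @param m A count-based `Methylome`.
#' @param probe_fraction Fraction of sites retained, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `Methylome` with assay `"array"` (no counts).
#' @export
downsample_array <- function(m, probe_fraction = 0.015, seed = 1) {
  stopifnot(inherits(m, "Methylome"))
  if (probe_fraction <= 0 || probe_fraction > 1) {
    stop("probe_fraction must be in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    keep <- stats::runif(nrow(m$sites)) <= probe_fraction
    s <- m$sites[keep, , drop = FALSE]
    s$meth_count <- NA_integer_
    s$total_count <- NA_integer_
    s$strand <- "."
    new_methylome(s, paste0(m$sample_id, "_array"), "array")
  })
}

#' Downsample a methylome to RRBS-like coverage
#'
#' Retains CpG-dense neighborhoods preferentially: each site's retention
#' probability scales with the local CpG density (count within a centered
#' 1 kb window), emulating the CpG-island enrichment of
#' reduced-representation libraries without an in-silico digestion.
#'
#' @param m A count-based `Methylome`.
#' @param layout The `SimLayout` the methylome was simulated from (provides
#'   CpG coordinates); defaults to using `m`'s own sites.
#' @param target_fraction Overall fraction of sites to retain.
#' @param seed Integer seed.
#' @return A `Methylome` with assay `"rrbs"`.
#' @export
downsample_rrbs <- function(m, layout = NULL, target_fraction = 0.2, seed = 1) {
  stopifnot(inherits(m, "Methylome"))
  if (target_fraction <= 0 || target_fraction > 1) {
    stop("target_fraction must be in (0, 1]", call. = FALSE)
  }
  s <- m$sites
  # local density: CpGs within +/- 500 bp, per chromosome
  dens <- unlist(lapply(split(s$pos, s$chrom), function(p) {
    findInterval(p + 500, p) - findInterval(p - 501, p)
  }), use.names = FALSE)
  # order of split() is alphabetical by chrom, matching sorted sites
  prob <- dens / sum(dens) * target_fraction * nrow(s)
  prob <- pmin(prob, 1)
  with_seed(seed, {
    keep <- stats::runif(nrow(s)) <= prob
    new_methylome(s[keep, , drop = FALSE], paste0(m$sample_id, "_rrbs"), "rrbs")
  })
}

#' Downsample a methylome to single-cell sparsity
#'
#' Keeps a small seeded fraction of sites and binarizes each kept site:
#' the observation becomes a single read whose methylation state is
#' Bernoulli with the site's beta, the hallmark of single-cell bisulfite
#' data.
#'
#' @param m A count-based `Methylome`.
#' @param site_fraction Fraction of sites retained, in `(0, 1]`.
#' @param seed Integer seed.
#' @return A `Methylome` with assay `"scwgbs"`, coverage 1 and betas in
#'   `{0, 1}`.
#' @export
downsample_single_cell <- function(m, site_fraction = 0.05, seed = 1) {
  stopifnot(inherits(m, "Methylome"))
  if (site_fraction <= 0 || site_fraction > 1) {
    stop("site_fraction must be in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    s <- m$sites[covered_sites(m$sites), , drop = FALSE]
    keep <- stats::runif(nrow(s)) <= site_fraction
    s <- s[keep, , drop = FALSE]
    call <- stats::rbinom(nrow(s), 1L, s$beta)
    s$meth_count <- call
    s$total_count <- 1L
    s$beta <- as.numeric(call)
    s$strand <- "."
    new_methylome(s, paste0(m$sample_id, "_sc"), "scwgbs")
  })
}
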