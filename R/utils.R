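# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded simulator calls never perturb user randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible substream seed
#'
#' One global seed controls a whole simulated cohort: each sample draws its
#' randomness from a seed derived deterministically from the global seed and
#' its stream number, so adding a sample never perturbs existing ones.
#'
#' @param seed Integer global seed.
#' @param stream Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), is.numeric(stream), stream >= 0)
  # affine hash modulo the Mersenne prime 2^31 - 1; stays a valid R integer
  as.integer((abs(as.numeric(seed)) %% 1e6 * 2099 + as.numeric(stream) * 7919 + 1) %%
               2147483647)
}

# Regions data.frame (0-based half-open) -> GRanges (1-based closed).
regions_to_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

# CpG sites -> width-1 GRanges at the forward-strand C.
sites_to_gr <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}

# TRUE for sites whose methylation level is usable: a defined beta and,
# when counts exist, at least one read.
covered_sites <- function(sites) {
  ok <- !is.na(sites$beta)
  if ("total_count" %in% names(sites)) {
    ok <- ok & (is.na(sites$total_count) | sites$total_count > 0L)
  }
  ok
}

assert_regions <- function(regions, what = "regions") {
  stopifnot(is.data.frame(regions))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions))) {
    stop(sprintf("%s must have columns chrom, start, end", what), call. = FALSE)
  }
  bad <- which(regions$start >= regions$end)
  if (length(bad)) {
    stop(sprintf("%s: start >= end at row %d (%s:%d-%d)", what, bad[1],
                 regions$chrom[bad[1]], regions$start[bad[1]], regions$end[bad[1]]),
         call. = FALSE)
  }
  invisible(regions)
}

# findOverlaps/countOverlaps with the "no common seqlevels" warning muted:
# a query on chromosomes absent from the subject is an expected empty result
# here, not a user error.
overlaps_hits <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject))
}
overlaps_count <- function(query, subject) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject))
}

# Base-level Jaccard similarity between two region sets (0-based half-open).
#' Base-level Jaccard similarity of two region sets
#'
#' Fraction of genomic bases shared between two interval sets:
#' `|A intersect B| / |A union B|`, computed on merged intervals. Used to
#' compare called LMRs against planted truth.
#'
#' @param a,b Region data.frames with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A single number in `[0, 1]`.
#' @export
jaccard_bases <- function(a, b) {
  assert_regions(a, "a"); assert_regions(b, "b")
  ga <- GenomicRanges::reduce(regions_to_gr(a))
  gb <- GenomicRanges::reduce(regions_to_gr(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  if (uni == 0) return(NA_real_)
  inter / uni
}
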