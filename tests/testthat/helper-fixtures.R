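# Fixture builders and independent brute-force oracles used across tests.
# All fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# Build a Methylome directly from vectors (bypasses the readers).
make_meth <- function(chrom, pos, beta = NULL, meth = NULL, total = NULL,
                      strand = ".", sample_id = "fix", assay = "wgbs") {
  n <- length(pos)
  if (is.null(total)) total <- rep(10L, n)
  if (is.null(meth)) meth <- as.integer(round(beta * total))
  if (is.null(beta)) beta <- ifelse(total > 0, meth / total, NA_real_)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                      strand = rep_len(strand, n),
                      meth_count = as.integer(meth),
                      total_count = as.integer(total),
                      beta = beta, stringsAsFactors = FALSE)
  prc2index:::new_methylome(sites, sample_id, assay)
}

make_track <- function(chrom, start, end, value, semantics = "fold_change") {
  prc2index:::new_signal_track(
    data.frame(chrom = rep_len(chrom, length(start)), start = start,
               end = end, value = value, stringsAsFactors = FALSE),
    semantics)
}

make_regions <- function(chrom, start, end, ...) {
  data.frame(chrom = rep_len(chrom, length(start)), start = start, end = end,
             ..., stringsAsFactors = FALSE)
}

# n random disjoint regions on one chromosome
random_regions <- function(n, chrom = "chr1", span = 1e6, min_len = 50,
                           max_len = 2000) {
  starts <- sort(sample.int(span - max_len, n))
  lens <- sample(min_len:max_len, n, replace = TRUE)
  ends <- pmin(starts + lens, c(starts[-1], span))
  keep <- starts < ends
  make_regions(chrom, starts[keep], ends[keep])
}

# ---- oracles ---------------------------------------------------------------

# Per-base brute-force mean of a track over a region (pad fills gaps).
oracle_track_mean <- function(track, chrom, start, end) {
  pad <- if (track$semantics == "p_value") 1 else 0
  vals <- rep(pad, end - start)
  iv <- track$intervals[track$intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    lo <- max(iv$start[i], start); hi <- min(iv$end[i], end)
    if (lo < hi) vals[(lo - start + 1):(hi - start)] <- iv$value[i]
  }
  mean(vals)
}

# Quadratic all-pairs overlap scan.
oracle_overlaps_any <- function(regions, blacklist) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(blacklist$chrom == regions$chrom[i] &
          blacklist$start < regions$end[i] &
          blacklist$end > regions$start[i])
  }, logical(1))
}

# Per-region brute-force scan of covered CpGs.
oracle_score_region <- function(m, chrom, start, end) {
  s <- m$sites
  ok <- s$chrom == chrom & s$pos >= start & s$pos < end &
    prc2index:::covered_sites(s)
  list(n = sum(ok), mean = if (any(ok)) mean(s$beta[ok]) else NA_real_)
}

# Small shared simulation for pipeline-level unit tests (cheap: 2 Mb).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      layout <- make_layout(chrom_len = 2e6, n_lmrs = 10,
                            target_fraction = 0.5, seed = 42)
      tracks <- simulate_chip_tracks(layout, 2, seed = 42)
      cache <<- list(layout = layout, tracks = tracks)
    }
    cache
  }
})
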