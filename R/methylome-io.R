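# Readers and writers for per-CpG methylation data, region BED files and
# bedGraph signal tracks. All internal coordinates are 0-based half-open;
# a CpG site is addressed by the position of the forward-strand C of the
# dyad. methcounts positions are taken as 0-based (tool convention).

new_methylome <- function(sites, sample_id, assay) {
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "strand", "meth_count", "total_count", "beta")
  stopifnot(all(need %in% names(sites)))
  sites <- sites[order(sites$chrom, sites$pos), need, drop = FALSE]
  rownames(sites) <- NULL
  structure(
    list(sample_id = sample_id, assay = assay, sites = sites),
    class = "Methylome"
  )
}

#' @export
print.Methylome <- function(x, ...) {
  cat(sprintf("Methylome '%s' (%s): %d sites on %d chromosome(s)\n",
              x$sample_id, x$assay, nrow(x$sites),
              length(unique(x$sites$chrom))))
  covered <- covered_sites(x$sites)
  if (any(covered)) {
    cat(sprintf("  mean methylation (covered sites): %.4f\n",
                mean(x$sites$beta[covered])))
  }
  invisible(x)
}

#' Number of CpG sites in a methylome
#' @param m A `Methylome`.
#' @return Integer site count.
#' @export
n_sites <- function(m) nrow(m$sites)

#' Global mean methylation of a methylome
#'
#' Unweighted mean beta over all covered CpG sites; the quantity used for
#' sample-level outlier screening.
#'
#' @param m A `Methylome`.
#' @return A number in `[0, 1]`, or `NA` if no site is covered.
#' @export
methylome_mean <- function(m) {
  covered <- covered_sites(m$sites)
  if (!any(covered)) return(NA_real_)
  mean(m$sites$beta[covered])
}

#' Read a per-CpG methylome file
#'
#' Supports the methcounts six-column text format (chrom, pos, strand,
#' context, level, coverage), bedMethyl (BED9+2: coverage in column 10,
#' percent methylated in column 11) and plain array beta tables
#' (`probe_id` plus one column per sample) with a 3-column probe manifest
#' (`probe_id`, `chrom`, `pos`). Count-based dialects reconstruct
#' `meth_count = round(beta * total_count)`; array sites carry beta only and
#' never fabricate counts.
#'
#' @param path Input file.
#' @param dialect One of `"methcounts"`, `"bedmethyl"`, `"array"`.
#' @param manifest For `dialect = "array"`: data.frame or file with columns
#'   `probe_id`, `chrom`, `pos`. Probes absent from the manifest are skipped
#'   with a message.
#' @param sample For `dialect = "array"`: which sample column to read
#'   (default: the first non-probe column).
#' @param sample_id Sample identifier stored in the result (default: file
#'   base name, or the array column name).
#' @param assay Assay label; defaults to `"wgbs"` for count dialects and
#'   `"array"` for arrays.
#' @return A `Methylome` with sites sorted by (chrom, pos).
#' @export
read_methylome <- function(path, dialect = c("methcounts", "bedmethyl", "array"),
                           manifest = NULL, sample = NULL, sample_id = NULL,
                           assay = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect != "array" && file.size(path) == 0) {
    return(new_methylome(empty_sites(), sample_id, assay %||% "wgbs"))
  }

  if (dialect == "methcounts") {
    dt <- data.table::fread(path, header = FALSE, sep = " ",
                            colClasses = list(character = c(1, 3, 4)),
                            fill = TRUE, showProgress = FALSE)
    if (nrow(dt) == 0) {
      return(new_methylome(empty_sites(), sample_id, assay %||% "wgbs"))
    }
    if (ncol(dt) < 6) stop("methcounts file needs 6 columns: ", path, call. = FALSE)
    pos <- suppressWarnings(as.integer(dt[[2]]))
    lev <- suppressWarnings(as.numeric(dt[[5]]))
    cov <- suppressWarnings(as.integer(dt[[6]]))
    bad <- which(is.na(pos) | is.na(lev) | is.na(cov) | lev < 0 | lev > 1 | cov < 0)
    if (length(bad)) {
      stop(sprintf("malformed methcounts line %d in %s", bad[1], path), call. = FALSE)
    }
    sites <- data.frame(
      chrom = dt[[1]], pos = pos, strand = dt[[3]],
      meth_count = as.integer(round(lev * cov)), total_count = cov,
      beta = ifelse(cov > 0, lev, NA_real_),
      stringsAsFactors = FALSE
    )
    return(new_methylome(dedupe_sites(sites), sample_id, assay %||% "wgbs"))
  }

  if (dialect == "bedmethyl") {
    dt <- data.table::fread(path, header = FALSE, showProgress = FALSE)
    if (nrow(dt) == 0) {
      return(new_methylome(empty_sites(), sample_id, assay %||% "wgbs"))
    }
    if (ncol(dt) < 11) stop("bedMethyl needs >= 11 columns: ", path, call. = FALSE)
    pos <- suppressWarnings(as.integer(dt[[2]]))
    cov <- suppressWarnings(as.integer(dt[[10]]))
    pct <- suppressWarnings(as.numeric(dt[[11]]))
    bad <- which(is.na(pos) | is.na(cov) | is.na(pct) | pct < 0 | pct > 100 | cov < 0)
    if (length(bad)) {
      stop(sprintf("malformed bedMethyl line %d in %s", bad[1], path), call. = FALSE)
    }
    beta <- pct / 100
    sites <- data.frame(
      chrom = dt[[1]], pos = pos, strand = as.character(dt[[6]]),
      meth_count = as.integer(round(beta * cov)), total_count = cov,
      beta = ifelse(cov > 0, beta, NA_real_),
      stringsAsFactors = FALSE
    )
    return(new_methylome(dedupe_sites(sites), sample_id, assay %||% "wgbs"))
  }

  # array dialect
  if (is.null(manifest)) {
    stop("dialect='array' requires a probe manifest", call. = FALSE)
  }
  if (is.character(manifest)) {
    manifest <- data.table::fread(manifest, header = TRUE, showProgress = FALSE)
  }
  manifest <- as.data.frame(manifest)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(manifest)))
  tab <- data.table::fread(path, header = TRUE, showProgress = FALSE)
  tab <- as.data.frame(tab)
  if (!"probe_id" %in% names(tab)) {
    stop("array table needs a 'probe_id' column: ", path, call. = FALSE)
  }
  value_cols <- setdiff(names(tab), "probe_id")
  if (length(value_cols) == 0) stop("array table has no sample columns", call. = FALSE)
  col <- sample %||% value_cols[1]
  if (!col %in% value_cols) stop("sample column not found: ", col, call. = FALSE)
  idx <- match(tab$probe_id, manifest$probe_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    message(sprintf("read_methylome: %d probe(s) absent from manifest, skipped", n_missing))
  }
  keep <- !is.na(idx)
  beta <- as.numeric(tab[[col]][keep])
  if (any(!is.na(beta) & (beta < 0 | beta > 1))) {
    stop("array beta values outside [0,1] in ", path, call. = FALSE)
  }
  sites <- data.frame(
    chrom = as.character(manifest$chrom[idx[keep]]),
    pos = as.integer(manifest$pos[idx[keep]]),
    strand = ".",
    meth_count = NA_integer_, total_count = NA_integer_,
    beta = beta, stringsAsFactors = FALSE
  )
  new_methylome(dedupe_sites(sites), sample_id = sample %||% col,
                assay = assay %||% "array")
}

empty_sites <- function() {
  data.frame(chrom = character(), pos = integer(), strand = character(),
             meth_count = integer(), total_count = integer(), beta = numeric(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dedupe_sites <- function(sites) {
  dup <- duplicated(sites[, c("chrom", "pos", "strand")])
  if (any(dup)) {
    message(sprintf("dropped %d duplicate site record(s)", sum(dup)))
    sites <- sites[!dup, , drop = FALSE]
  }
  sites
}

#' Write a methylome in methcounts format
#'
#' Six space-separated columns: chrom, pos, strand, context ("CpG"), level,
#' coverage. Array methylomes carry no counts and are rejected: the
#' methcounts format is defined by read counts.
#'
#' @param m A count-based `Methylome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(m, path) {
  stopifnot(inherits(m, "Methylome"))
  if (all(is.na(m$sites$total_count)) && nrow(m$sites) > 0) {
    stop("cannot write an array (beta-only) methylome as methcounts", call. = FALSE)
  }
  s <- m$sites
  lev <- ifelse(s$total_count > 0, s$meth_count / s$total_count, 0)
  out <- data.frame(s$chrom, s$pos, s$strand, "CpG",
                    format(lev, digits = 6, scientific = FALSE, trim = TRUE),
                    s$total_count)
  data.table::fwrite(out, path, sep = " ", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge symmetric CpG dyads
#'
#' Pools the read counts of the two strands of each CpG dyad into one
#' record anchored at the forward-strand position: a '-'-strand site at
#' position p+1 is merged into the '+'-strand site at p. Total methylated
#' and total read counts are conserved exactly. Orphan '-' sites (no '+'
#' partner) are retained, repositioned to p-1, and counted in a message.
#'
#' @param m A count-based, strand-annotated `Methylome`.
#' @return A `Methylome` with strand `"."` and strictly increasing positions
#'   per chromosome.
#' @export
merge_symmetric <- function(m) {
  stopifnot(inherits(m, "Methylome"))
  s <- m$sites
  if (nrow(s) == 0) return(m)
  if (all(is.na(s$total_count))) {
    stop("symmetric merge needs a count-based methylome", call. = FALSE)
  }
  minus <- s$strand == "-"
  # anchor every '-' site at the dyad's forward-strand position
  anchor <- ifelse(minus, s$pos - 1L, s$pos)
  key <- paste(s$chrom, anchor)
  has_plus <- key %in% paste(s$chrom, s$pos)[!minus]
  n_orphans <- sum(minus & !has_plus)
  if (n_orphans > 0) {
    message(sprintf("merge_symmetric: %d orphan '-' site(s) repositioned", n_orphans))
  }
  dt <- data.table::data.table(chrom = s$chrom, pos = anchor,
                               meth_count = s$meth_count,
                               total_count = s$total_count)
  pooled <- dt[, list(meth_count = sum(meth_count),
                      total_count = sum(total_count)),
               by = c("chrom", "pos")]
  sites <- data.frame(
    chrom = pooled$chrom, pos = pooled$pos, strand = ".",
    meth_count = pooled$meth_count, total_count = pooled$total_count,
    beta = ifelse(pooled$total_count > 0,
                  pooled$meth_count / pooled$total_count, NA_real_),
    stringsAsFactors = FALSE
  )
  out <- new_methylome(sites, m$sample_id, m$assay)
  attr(out, "n_orphans") <- n_orphans
  out
}

#' Pool several count-based methylomes into one
#'
#' Sums methylated and total counts per CpG position across samples,
#' mirroring the common practice of merging replicates before segmentation
#' or group-level delta computation. Effective coverage grows with the
#' number of samples pooled.
#'
#' @param ms List of count-based `Methylome` objects.
#' @param sample_id Identifier for the pooled methylome.
#' @return A `Methylome`.
#' @export
pool_methylomes <- function(ms, sample_id = "pooled") {
  stopifnot(length(ms) >= 1, all(vapply(ms, inherits, TRUE, "Methylome")))
  dt <- data.table::rbindlist(lapply(ms, function(m) {
    s <- m$sites
    if (all(is.na(s$total_count)) && nrow(s) > 0) {
      stop("pool_methylomes needs count-based methylomes", call. = FALSE)
    }
    data.table::data.table(chrom = s$chrom, pos = s$pos,
                           meth_count = s$meth_count,
                           total_count = s$total_count)
  }))
  pooled <- dt[, list(meth_count = sum(meth_count),
                      total_count = sum(total_count)),
               by = c("chrom", "pos")]
  sites <- data.frame(
    chrom = pooled$chrom, pos = pooled$pos, strand = ".",
    meth_count = pooled$meth_count, total_count = pooled$total_count,
    beta = ifelse(pooled$total_count > 0,
                  pooled$meth_count / pooled$total_count, NA_real_),
    stringsAsFactors = FALSE
  )
  new_methylome(sites, sample_id, ms[[1]]$assay)
}

# ---- signal tracks (bedGraph) ----------------------------------------------

new_signal_track <- function(intervals, semantics) {
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  intervals <- intervals[order(intervals$chrom, intervals$start),
                         c("chrom", "start", "end", "value")]
  rownames(intervals) <- NULL
  structure(list(semantics = semantics, intervals = intervals),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack (%s): %d interval(s), value range [%.3g, %.3g]\n",
              x$semantics, nrow(x$intervals),
              min(x$intervals$value), max(x$intervals$value)))
  invisible(x)
}

#' Read a bedGraph ChIP signal track
#'
#' Four columns: chrom, start, end, value (0-based half-open). Intervals
#' must be disjoint within each chromosome; gaps are interpreted downstream
#' as value 0 (fold-change semantics) or 1 (p-value semantics), matching
#' signal tracks that omit zero regions. Zero-valued fold-change intervals
#' are dropped on read.
#'
#' @param path bedGraph file.
#' @param semantics `"fold_change"` (higher = more bound) or `"p_value"`
#'   (lower = more bound).
#' @return A `SignalTrack`.
#' @export
read_signal_track <- function(path, semantics = c("fold_change", "p_value")) {
  semantics <- match.arg(semantics)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(new_signal_track(data.frame(chrom = character(), start = integer(),
                                       end = integer(), value = numeric()),
                            semantics))
  }
  dt <- data.table::fread(path, header = FALSE, showProgress = FALSE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(new_signal_track(data.frame(chrom = character(), start = integer(),
                                       end = integer(), value = numeric()),
                            semantics))
  }
  if (ncol(dt) < 4) stop("bedGraph needs 4 columns: ", path, call. = FALSE)
  iv <- data.frame(chrom = dt[[1]], start = as.integer(dt[[2]]),
                   end = as.integer(dt[[3]]), value = as.numeric(dt[[4]]),
                   stringsAsFactors = FALSE)
  if (any(is.na(iv$start) | is.na(iv$end) | is.na(iv$value))) {
    stop("malformed bedGraph line in ", path, call. = FALSE)
  }
  if (any(iv$start >= iv$end)) {
    bad <- which(iv$start >= iv$end)[1]
    stop(sprintf("bedGraph interval with start >= end: %s:%d-%d",
                 iv$chrom[bad], iv$start[bad], iv$end[bad]), call. = FALSE)
  }
  if (semantics == "fold_change" && any(iv$value < 0)) {
    stop("negative value with fold_change semantics in ", path, call. = FALSE)
  }
  if (semantics == "p_value" && any(iv$value <= 0 | iv$value > 1)) {
    stop("p_value semantics requires values in (0,1] in ", path, call. = FALSE)
  }
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
  olap <- which(same & iv$start[-1] < iv$end[-nrow(iv)])
  if (length(olap)) {
    i <- olap[1]
    stop(sprintf("overlapping bedGraph intervals: %s:%d-%d and %s:%d-%d",
                 iv$chrom[i], iv$start[i], iv$end[i],
                 iv$chrom[i + 1], iv$start[i + 1], iv$end[i + 1]), call. = FALSE)
  }
  if (semantics == "fold_change") iv <- iv[iv$value != 0, , drop = FALSE]
  new_signal_track(iv, semantics)
}

#' Write a SignalTrack as bedGraph
#' @param track A `SignalTrack`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  data.table::fwrite(track$intervals, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- region BED ------------------------------------------------------------

#' Read regions from a BED file
#'
#' BED3+ with native 0-based half-open coordinates. Columns 4 and 5 are
#' kept as `name` and `score` when present.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, sorted by coordinate.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(path, header = FALSE, showProgress = FALSE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(chrom = dt[[1]], start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]), stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) out$score <- suppressWarnings(as.numeric(dt[[5]]))
  assert_regions(out, path)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write regions to a BED file
#'
#' Emits chrom, start, end, name, score. The score column is `prc2_score`
#' when present, otherwise `mean_level * 1000` rounded, otherwise 0.
#'
#' @param regions Region data.frame.
#' @param path Output file.
#' @param extra_cols Optional extra column names appended after the score
#'   (e.g. `"rank"`).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, extra_cols = NULL) {
  assert_regions(regions)
  name <- if ("name" %in% names(regions)) regions$name
          else sprintf("region_%d", seq_len(nrow(regions)))
  score <- if ("prc2_score" %in% names(regions)) regions$prc2_score
           else if ("score" %in% names(regions)) regions$score
           else if ("mean_level" %in% names(regions)) round(regions$mean_level * 1000)
           else rep(0, nrow(regions))
  out <- data.frame(regions$chrom, regions$start, regions$end, name, score,
                    stringsAsFactors = FALSE)
  for (col in extra_cols) out[[col]] <- regions[[col]]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
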