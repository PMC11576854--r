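#' Build a merged region atlas from per-sample peak sets
#'
#' Peaks from all samples/stages/conditions are pooled and merged with a gap
#' tolerance (default 100 bp, i.e. `bedtools merge -d 100`), yielding the
#' single set of genomic coordinates on which the whole time-course analysis
#' operates.
#'
#' @param peak_sets named list of interval `data.frame`s (one per sample).
#' @param gap_bp merge distance in bp.
#' @return object of class `region_atlas`: list with `regions` (merged,
#'   sorted intervals carrying a `region_id`), `gap_bp` and `provenance`.
#' @export
build_atlas <- function(peak_sets, gap_bp = 100L) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  nonempty <- vapply(peak_sets, nrow, 0L) > 0
  if (!any(nonempty)) stop("all peak sets are empty")
  pooled <- do.call(rbind, lapply(peak_sets, function(p) p[, c("chrom", "start", "end")]))
  regions <- merge_intervals(pooled, gap_bp)
  regions$region_id <- sprintf("R%05d", seq_len(nrow(regions)))
  structure(list(regions = regions, gap_bp = as.integer(gap_bp),
                 provenance = names(peak_sets)),
            class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("region_atlas: %d regions on %d chromosome(s), merge gap %d bp, %d peak set(s)\n",
              nrow(x$regions), length(unique(x$regions$chrom)), x$gap_bp,
              length(x$provenance)))
  invisible(x)
}

#' Place pseudo-input background intervals
#'
#' Draws `n` background intervals whose lengths are sampled with replacement
#' from the atlas region lengths and whose positions are uniform on the
#' genome, rejecting any placement overlapping the atlas. The signal over
#' these intervals is the empirical null used to calibrate the open/closed
#' threshold.
#'
#' @param atlas `region_atlas`.
#' @param chrom_sizes named integer vector covering all atlas chromosomes.
#' @param seed integer seed; placement is deterministic given the seed.
#' @param n number of intervals (default: atlas size).
#' @param max_tries rejection-sampling budget per interval (total budget is
#'   `n * max_tries`).
#' @return interval `data.frame` of `n` background intervals.
#' @export
make_pseudo_input <- function(atlas, chrom_sizes, seed, n = nrow(atlas$regions),
                              max_tries = 1000L) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (n == 0) return(data.frame(chrom = character(), start = integer(),
                                end = integer(), stringsAsFactors = FALSE))
  miss <- setdiff(unique(atlas$regions$chrom), names(chrom_sizes))
  if (length(miss) > 0) stop("chrom_sizes missing: ", paste(miss, collapse = ", "))
  set.seed(seed)
  widths <- atlas$regions$end - atlas$regions$start
  gr_atlas <- as_gr(atlas$regions)
  chroms <- names(chrom_sizes)
  p_chrom <- chrom_sizes / sum(chrom_sizes)
  placed <- 0L; tries <- 0L; budget <- as.integer(n) * max_tries
  out_chrom <- character(n); out_start <- integer(n); out_end <- integer(n)
  while (placed < n) {
    if (tries >= budget) {
      stop(sprintf("pseudo-input placement failed: %d/%d placed after %d tries",
                   placed, n, tries))
    }
    k <- max(n - placed, 16L)  # batch proposals
    w <- sample(widths, k, replace = TRUE)
    ch <- sample(chroms, k, replace = TRUE, prob = p_chrom)
    maxs <- chrom_sizes[ch] - w
    ok <- maxs >= 0
    st <- integer(k)
    st[ok] <- as.integer(floor(stats::runif(sum(ok)) * (maxs[ok] + 1)))
    cand <- data.frame(chrom = ch[ok], start = st[ok], end = st[ok] + w[ok],
                       stringsAsFactors = FALSE)
    tries <- tries + k
    if (nrow(cand) == 0) next
    hit <- GenomicRanges::countOverlaps(as_gr(cand), gr_atlas) > 0
    cand <- cand[!hit, , drop = FALSE]
    take <- utils::head(seq_len(nrow(cand)), n - placed)
    if (length(take) > 0) {
      idx <- placed + seq_along(take)
      out_chrom[idx] <- cand$chrom[take]
      out_start[idx] <- cand$start[take]
      out_end[idx] <- cand$end[take]
      placed <- placed + length(take)
    }
  }
  data.frame(chrom = out_chrom, start = out_start, end = out_end,
             stringsAsFactors = FALSE)
}

#' Quantify normalized signal over regions
#'
#' Per-region value = overlap-weighted mean bin signal, scaled to
#' counts-per-million of the library and log-transformed:
#' `log_base(x * 1e6 / library_size + pseudocount)`. The transform is
#' invariant to jointly rescaling track values and library size.
#'
#' @param regions interval `data.frame`.
#' @param track `signal_track`.
#' @param log_base 2 (default) or 10.
#' @param pseudocount added before the log.
#' @return numeric vector, one value per region.
#' @export
quantify <- function(regions, track, log_base = 2, pseudocount = 1) {
  stopifnot(inherits(track, "signal_track"))
  validate_intervals(regions)
  gr_r <- as_gr(regions)
  gr_b <- as_gr(track$bins)
  # disjoint seqlevels are legal here; zero overlap is reported below
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_b))
  if (nrow(regions) > 0) {
    covered <- unique(S4Vectors::queryHits(hits))
    if (length(covered) < nrow(regions)) {
      stop("region(s) with no overlapping track bins: row(s) ",
           paste(utils::head(setdiff(seq_len(nrow(regions)), covered), 5), collapse = ", "))
    }
  }
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_r)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gr_b)[S4Vectors::subjectHits(hits)]))
  v <- track$bins$value[S4Vectors::subjectHits(hits)]
  num <- tapply(ov * v, S4Vectors::queryHits(hits), sum)
  den <- tapply(ov, S4Vectors::queryHits(hits), sum)
  x <- as.numeric(num / den)
  log(x * 1e6 / track$library_size + pseudocount, base = log_base)
}

#' Calibrate the open/closed threshold at a target false-positive rate
#'
#' The threshold is the empirical `1 - target_fpr` quantile (linear
#' interpolation) of the pseudo-input signal values, so that at most a
#' `target_fpr` fraction of background regions exceed it. The published
#' analysis this models used a fixed value of 4.2 at FPR 0.01 for its own
#' data set; use [fixed_threshold()] to reproduce fixed-value behaviour.
#'
#' @param pseudo_values numeric vector of pseudo-input signal values
#'   (>= 100 values required for a stable quantile).
#' @param target_fpr target false-positive rate in (0, 1).
#' @return object of class `open_threshold` (`value`, `target_fpr`, `source`).
#' @export
calibrate_threshold <- function(pseudo_values, target_fpr = 0.01) {
  stopifnot(target_fpr > 0, target_fpr < 1)
  pseudo_values <- pseudo_values[is.finite(pseudo_values)]
  if (length(pseudo_values) < 100) {
    stop("need >= 100 pseudo-input values to calibrate (got ",
         length(pseudo_values), ")")
  }
  thr <- unname(stats::quantile(pseudo_values, probs = 1 - target_fpr, type = 7))
  structure(list(value = thr, target_fpr = target_fpr, source = "calibrated"),
            class = "open_threshold")
}

#' @rdname calibrate_threshold
#' @param value fixed threshold in signal units.
#' @export
fixed_threshold <- function(value, target_fpr = 0.01) {
  structure(list(value = value, target_fpr = target_fpr, source = "fixed"),
            class = "open_threshold")
}

#' @export
print.open_threshold <- function(x, ...) {
  cat(sprintf("open_threshold: %.4g (%s, target FPR %.3g)\n",
              x$value, x$source, x$target_fpr))
  invisible(x)
}
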