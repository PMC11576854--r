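#' Genomic intervals as plain data frames
#'
#' Throughout the package a set of genomic intervals is a `data.frame` with
#' columns `chrom` (character), `start`, `end` (integer, 0-based half-open,
#' BED convention) and optionally `name` and `score`. These helpers construct
#' and validate that representation.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start >= 0`, `end > start`.
#' @param name,score optional per-interval annotation.
#' @return A `data.frame` of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval set") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$end <= df$start | df$start < 0 | is.na(df$chrom) | df$chrom == "")
  if (length(bad) > 0) {
    stop(sprintf("invalid %s: end <= start (or negative start) at row(s) %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(df)
}

# GRanges bridge: BED half-open [start, end) -> 1-based closed [start+1, end]
as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_as_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED3/BED6 file
#'
#' Lines starting with `track`, `browser` or `#` are skipped. Coordinates are
#' kept 0-based half-open. A record with `end <= start` is rejected with its
#' line number.
#'
#' @param path path to a tab-separated BED file.
#' @return `data.frame` of intervals in file order (with `name`/`score` when
#'   a 4th/5th column is present).
#' @export
parse_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("BED line %d has fewer than 3 columns", lineno[which(ncol < 3)[1]]))
  }
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                   start = as.integer(vapply(fields, `[[`, "", 2L)),
                   end = as.integer(vapply(fields, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  if (all(ncol >= 4)) df$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncol >= 5)) df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start | df$start < 0)
  if (length(bad) > 0) {
    stop(sprintf("malformed BED record at line %d: end <= start", lineno[bad[1]]))
  }
  df
}

#' Write intervals as BED
#'
#' @param df interval `data.frame`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  # BED columns are positional: score requires name
  if ("score" %in% cols && !"name" %in% cols) {
    df$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge intervals with a gap tolerance
#'
#' Reproduces `bedtools merge -d gap_bp`: two intervals on the same chromosome
#' whose separation (`start2 - end1` in half-open coordinates) is `<= gap_bp`
#' fall into one merged interval. Output is sorted and non-overlapping.
#'
#' @param df interval `data.frame`.
#' @param gap_bp non-negative merge distance in bp (0 merges only overlapping
#'   or abutting intervals).
#' @return merged, sorted interval `data.frame`.
#' @export
merge_intervals <- function(df, gap_bp = 0L) {
  stopifnot(gap_bp >= 0)
  validate_intervals(df)
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_gr(df), min.gapwidth = gap_bp + 1L)
  out <- gr_as_df(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap counts between two interval sets (Venn-style)
#'
#' Each set must be internally non-overlapping (merge first). `shared_a` is
#' the number of A intervals overlapping any B interval by at least
#' `min_overlap_bp`; `shared_b` is the symmetric count. Abutting half-open
#' intervals do not overlap.
#'
#' @param a,b interval `data.frame`s, each internally non-overlapping.
#' @param min_overlap_bp minimum overlap in bp to count (default 1).
#' @return list with `a_only`, `b_only`, `shared_a`, `shared_b`.
#' @export
intersect_counts <- function(a, b, min_overlap_bp = 1L) {
  validate_intervals(a, "set A"); validate_intervals(b, "set B")
  for (nm in c("a", "b")) {
    s <- if (nm == "a") a else b
    if (nrow(s) > 1) {
      merged <- merge_intervals(s, 0L)
      # reduce also joins abutting intervals, which are legal here
      if (sum(merged$end - merged$start) != sum(s$end - s$start))
        stop("intervals within set ", toupper(nm), " overlap; merge first")
    }
  }
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(a_only = nrow(a), b_only = nrow(b), shared_a = 0L, shared_b = 0L))
  }
  ga <- as_gr(a); gb <- as_gr(b)
  shared_a <- sum(GenomicRanges::countOverlaps(ga, gb, minoverlap = min_overlap_bp) > 0)
  shared_b <- sum(GenomicRanges::countOverlaps(gb, ga, minoverlap = min_overlap_bp) > 0)
  list(a_only = nrow(a) - shared_a, b_only = nrow(b) - shared_b,
       shared_a = shared_a, shared_b = shared_b)
}

# distance from a TSS base to a half-open interval: 0 when the base lies
# inside, otherwise bp to the nearest included base
point_interval_distance <- function(tss, start, end) {
  pmax(0L, start - tss, tss - end + 1L)
}

#' Link regions to their nearest TSS within a distance cutoff
#'
#' Each region is linked to the single nearest transcription start site, but
#' only when the distance is at most `max_dist_bp` (10 kb by default, the
#' conventional peak-to-gene annotation window). Distance is 0 when the TSS
#' lies inside the region; ties are broken by the lexicographically smaller
#' gene id.
#'
#' @param regions interval `data.frame`; row order defines `region_idx`.
#' @param annotation gene annotation `data.frame` (see
#'   [read_gene_annotation()]); needs `gene_id`, `chrom`, `tss`.
#' @param max_dist_bp maximum region-to-TSS distance in bp.
#' @return `data.frame` with `region_idx`, `gene_id`, `distance` for linked
#'   regions only.
#' @export
nearest_tss <- function(regions, annotation, max_dist_bp = 10000L) {
  validate_intervals(regions)
  stopifnot(nrow(annotation) >= 1)
  ann <- annotation[order(annotation$gene_id), , drop = FALSE]
  out_idx <- integer(0); out_gene <- character(0); out_dist <- integer(0)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    ai <- which(ann$chrom == ch)
    if (length(ai) == 0) next
    tss <- ann$tss[ai]
    for (i in ri) {
      d <- point_interval_distance(tss, regions$start[i], regions$end[i])
      j <- which.min(d)  # ann sorted by gene_id, so which.min = lexicographic tie-break
      if (d[j] <= max_dist_bp) {
        out_idx <- c(out_idx, i)
        out_gene <- c(out_gene, ann$gene_id[ai[j]])
        out_dist <- c(out_dist, d[j])
      }
    }
  }
  o <- order(out_idx)
  data.frame(region_idx = out_idx[o], gene_id = out_gene[o],
             distance = out_dist[o], stringsAsFactors = FALSE)
}

#' Annotate regions with a genomic feature label
#'
#' Labels each region by the feature overlapping its midpoint, with precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > TTS > intergenic. The promoter
#' window spans `promoter_up` bp upstream and `promoter_down` bp downstream of
#' the TSS, strand-aware; the TTS window extends `tts_window` bp on each side
#' of the transcript end. Genes without exon structure contribute their body
#' as intron.
#'
#' @param regions interval `data.frame`.
#' @param annotation gene annotation `data.frame` with `chrom`, `strand`,
#'   `tss`, `start`, `end` and optional `exons`, `utr5`, `utr3` block columns
#'   ("s1-e1;s2-e2" syntax, half-open).
#' @param promoter_up,promoter_down,tts_window window sizes in bp.
#' @return character vector of feature labels, one per region.
#' @export
annotate_feature <- function(regions, annotation,
                             promoter_up = 2000L, promoter_down = 500L,
                             tts_window = 500L) {
  validate_intervals(regions)
  mid <- (regions$start + regions$end) %/% 2L
  levels <- c("promoter", "5'UTR", "3'UTR", "exon", "intron", "TTS", "intergenic")
  best <- rep.int(7L, nrow(regions))
  blocks <- function(x) {
    if (is.null(x) || is.na(x) || !nzchar(x)) return(NULL)
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    do.call(rbind, lapply(parts, as.integer))
  }
  in_any <- function(m, b) !is.null(b) && any(m >= b[, 1] & m < b[, 2])
  for (g in seq_len(nrow(annotation))) {
    ge <- annotation[g, ]
    ri <- which(regions$chrom == ge$chrom)
    if (length(ri) == 0) next
    m <- mid[ri]
    plus <- identical(ge$strand, "+")
    prom <- if (plus) c(ge$tss - promoter_up, ge$tss + promoter_down)
            else c(ge$tss - promoter_down, ge$tss + promoter_up)
    tts_base <- if (plus) ge$end - 1L else ge$start
    tts <- c(tts_base - tts_window, tts_base + tts_window + 1L)
    ex <- blocks(ge$exons); u5 <- blocks(ge$utr5); u3 <- blocks(ge$utr3)
    for (k in seq_along(ri)) {
      i <- ri[k]; mk <- m[k]
      lab <- if (mk >= prom[1] && mk < prom[2]) 1L
        else if (in_any(mk, u5)) 2L
        else if (in_any(mk, u3)) 3L
        else if (in_any(mk, ex)) 4L
        else if (mk >= ge$start && mk < ge$end) 5L
        else if (mk >= tts[1] && mk < tts[2]) 6L
        else 7L
      if (lab < best[i]) best[i] <- lab
    }
  }
  levels[best]
}
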