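#' Read a gene annotation table
#'
#' A tab-separated table with header columns `gene_id`, `chrom`, `strand`
#' (`+`/`-`), `tss`, `start`, `end` (transcript span, 0-based half-open) and
#' optional block columns `exons`, `utr5`, `utr3` using `"s1-e1;s2-e2"`
#' half-open syntax. The TSS must lie within the span; feature blocks must lie
#' within the span.
#'
#' @param path path to the annotation TSV.
#' @return `data.frame`, one row per gene.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_gene_annotation(ann)
}

validate_gene_annotation <- function(ann) {
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(ann$strand %in% c("+", "-")),
            all(ann$end > ann$start),
            !anyDuplicated(ann$gene_id))
  bad <- which(ann$tss < ann$start | ann$tss >= ann$end)
  if (length(bad) > 0) stop("TSS outside transcript span for gene(s): ",
                            paste(utils::head(ann$gene_id[bad], 5), collapse = ", "))
  ann
}

#' @rdname read_gene_annotation
#' @param ann annotation `data.frame`.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fixed-bin signal tracks
#'
#' A signal track is a genome-wide, fixed-width-binned coverage vector
#' (25-bp bins by default, matching common ATAC-seq practice) plus the
#' library size used for normalisation.
#'
#' @param bins `data.frame` with `chrom`, `start`, `end`, `value`; all bins
#'   must share one width and values must be finite and non-negative.
#' @param library_size total fragments in the library (normalisation factor).
#' @param bin_width expected bin width in bp.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(bins, library_size, bin_width = 25L) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "value") %in% names(bins)),
            library_size > 0)
  if (nrow(bins) > 0) {
    w <- bins$end - bins$start
    if (any(w != bin_width)) stop("track bins are not all ", bin_width, " bp wide")
    if (any(!is.finite(bins$value) | bins$value < 0))
      stop("track values must be finite and >= 0")
  }
  structure(list(bins = bins, library_size = library_size,
                 bin_width = as.integer(bin_width)),
            class = "signal_track")
}

#' Read a bedGraph file into a signal track
#'
#' @param path bedGraph path (tab-separated `chrom start end value`).
#' @inheritParams signal_track
#' @export
read_bedgraph <- function(path, library_size, bin_width = 25L) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  bins <- data.frame(chrom = vapply(f, `[[`, "", 1L),
                     start = as.integer(vapply(f, `[[`, "", 2L)),
                     end = as.integer(vapply(f, `[[`, "", 3L)),
                     value = as.numeric(vapply(f, `[[`, "", 4L)),
                     stringsAsFactors = FALSE)
  signal_track(bins, library_size = library_size, bin_width = bin_width)
}

#' @rdname read_bedgraph
#' @param track `signal_track` object.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  utils::write.table(track$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file of `chrom  size`.
#' @return named integer vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), tab[[1]])
}

#' Read/write GMT gene-set files
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(f, function(x) x[-(1:2)]), vapply(f, `[[`, "", 1L))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
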