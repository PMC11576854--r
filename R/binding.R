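#' Call binding sites by the FPR-calibrated threshold
#'
#' Binding-site calling reuses the open-chromatin machinery on a single
#' "stage": candidate regions whose signal strictly exceeds the pseudo-input
#' calibrated threshold are sites (a value exactly at the threshold is not).
#'
#' @param regions candidate interval `data.frame`.
#' @param values numeric signal vector, one value per region, in threshold
#'   units.
#' @param threshold `open_threshold` (or bare number).
#' @param isoform label for the resulting site set.
#' @return object of class `binding_sites`: `sites` (intervals + `signal`),
#'   `isoform`, `threshold`.
#' @export
call_sites <- function(regions, values, threshold, isoform = "TF") {
  validate_intervals(regions)
  stopifnot(length(values) == nrow(regions))
  keep <- as.vector(binarize(matrix(values, ncol = 1), threshold))
  sites <- regions[keep, , drop = FALSE]
  sites$signal <- values[keep]
  rownames(sites) <- NULL
  thr <- if (inherits(threshold, "open_threshold")) threshold$value else threshold
  structure(list(sites = sites, isoform = isoform, threshold = thr),
            class = "binding_sites")
}

#' Overlap Venn between two binding-site sets
#'
#' @param set_a,set_b `binding_sites` objects (or bare interval data frames).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return list `a_only`, `b_only`, `shared_a`, `shared_b`.
#' @export
binding_venn <- function(set_a, set_b, min_overlap_bp = 1L) {
  sa <- if (inherits(set_a, "binding_sites")) set_a$sites else set_a
  sb <- if (inherits(set_b, "binding_sites")) set_b$sites else set_b
  intersect_counts(sa, sb, min_overlap_bp = min_overlap_bp)
}

#' Assign target genes to binding sites
#'
#' Targets are genes whose TSS lies within `max_dist` of any site, excluding
#' lowly expressed genes (overall mean FPKM below `min_fpkm`). Each target
#' appears once, annotated with its nearest site.
#'
#' @param sites `binding_sites` (or interval `data.frame`).
#' @param annotation gene annotation `data.frame`.
#' @param expr `expression_table`.
#' @param max_dist TSS-to-site distance cutoff in bp (default 10 kb).
#' @param min_fpkm expression filter (default 1).
#' @return `data.frame` with `gene_id`, `isoform`, `site`, `distance`,
#'   `mean_fpkm`.
#' @export
assign_targets <- function(sites, annotation, expr, max_dist = 10000L,
                           min_fpkm = 1) {
  iso <- if (inherits(sites, "binding_sites")) sites$isoform else NA_character_
  s <- if (inherits(sites, "binding_sites")) sites$sites else sites
  validate_intervals(s)
  mean_fpkm <- rowMeans(expr$fpkm)
  out <- list()
  for (g in seq_len(nrow(annotation))) {
    gi <- annotation$gene_id[g]
    if (!gi %in% rownames(expr$fpkm)) next
    ri <- which(s$chrom == annotation$chrom[g])
    if (length(ri) == 0) next
    d <- point_interval_distance(annotation$tss[g], s$start[ri], s$end[ri])
    j <- which.min(d)
    if (d[j] <= max_dist && mean_fpkm[gi] >= min_fpkm) {
      out[[length(out) + 1]] <- data.frame(
        gene_id = gi, isoform = iso,
        site = sprintf("%s:%d-%d", s$chrom[ri[j]], s$start[ri[j]], s$end[ri[j]]),
        distance = d[j], mean_fpkm = unname(mean_fpkm[gi]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(gene_id = character(), isoform = character(), site = character(),
               distance = integer(), mean_fpkm = numeric(), stringsAsFactors = FALSE)
  res[order(res$gene_id), , drop = FALSE]
}

#' Classify target genes by expression-correlation sign
#'
#' Correlates each target's per-stage mean log2(FPKM+1) series with the
#' binding factor's own expression series across the stages of one condition
#' (Pearson by default). Targets with r > 0 are positive, r < 0 negative;
#' r == 0 or undefined (constant series) are excluded from the reported
#' positive fraction with a logged count.
#'
#' @param targets `data.frame` from [assign_targets()] (needs `gene_id`).
#' @param isoform_series numeric vector: the factor's per-stage expression
#'   (same stages, same order).
#' @param expr `expression_table`.
#' @param condition condition label.
#' @param stages ordered stage labels (>= 3).
#' @param method correlation method (default `"pearson"`).
#' @return list with `targets` (`gene_id`, `r`, `sign`), `positive_fraction`,
#'   `n_excluded`.
#' @export
classify_correlation <- function(targets, isoform_series, expr, condition,
                                 stages, method = "pearson") {
  stopifnot(length(stages) >= 3, length(isoform_series) == length(stages))
  sm <- stage_mean_fpkm(expr, condition, stages)
  genes <- intersect(targets$gene_id, rownames(sm))
  r <- vapply(genes, function(g) {
    v <- log2(sm[g, ] + 1)
    if (stats::sd(v) == 0 || stats::sd(isoform_series) == 0) return(NA_real_)
    stats::cor(v, isoform_series, method = method)
  }, 0)
  sign <- ifelse(is.na(r) | r == 0, NA_character_,
                 ifelse(r > 0, "positive", "negative"))
  n_excl <- sum(is.na(sign))
  if (n_excl > 0) {
    warning(n_excl, " target(s) with undefined or zero correlation excluded")
  }
  usable <- !is.na(sign)
  list(targets = data.frame(gene_id = genes, r = unname(r), sign = sign,
                            stringsAsFactors = FALSE, row.names = NULL),
       positive_fraction = if (any(usable)) mean(sign[usable] == "positive") else NA_real_,
       n_excluded = n_excl)
}

#' Nominate downstream effectors by gene-set intersection
#'
#' Intersects a (sign-filtered) target-gene list with a curated gene set,
#' e.g. positively correlated targets of one isoform against an
#' epithelial-mesenchymal-transition set.
#'
#' @param target_genes character vector of target gene ids (already filtered
#'   by sign if desired).
#' @param gene_set character vector (one GMT entry's members).
#' @return sorted character vector of the intersection.
#' @export
nominate <- function(target_genes, gene_set) {
  stopifnot(length(gene_set) > 0)
  sort(intersect(target_genes, gene_set))
}
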