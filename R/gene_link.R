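#' Gene-by-replicate expression tables
#'
#' Expression is carried as FPKM in a genes x replicates matrix plus a map
#' assigning every replicate column to a (condition, stage) pair. The
#' baseline stage (starting fibroblasts, `hiF-T` by default) must be present.
#'
#' @param fpkm numeric matrix, genes x replicates, non-negative, with
#'   rownames (gene ids) and colnames (replicate ids).
#' @param map `data.frame` with `replicate`, `condition`, `stage` covering
#'   every column of `fpkm`.
#' @param baseline baseline stage label.
#' @return object of class `expression_table`.
#' @export
expression_table <- function(fpkm, map, baseline = "hiF-T") {
  fpkm <- as.matrix(fpkm)
  stopifnot(!is.null(rownames(fpkm)), !is.null(colnames(fpkm)),
            all(fpkm >= 0), all(colnames(fpkm) %in% map$replicate),
            all(c("replicate", "condition", "stage") %in% names(map)))
  if (!baseline %in% map$stage) stop("baseline stage '", baseline, "' absent from map")
  map <- map[match(colnames(fpkm), map$replicate), ]
  structure(list(fpkm = fpkm, map = map, baseline = baseline),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d replicates (%s; stages: %s)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              paste(unique(x$map$condition), collapse = "/"),
              paste(unique(x$map$stage), collapse = ", ")))
  invisible(x)
}

#' Read/write an expression table TSV
#'
#' Layout: first column `gene_id`, remaining columns one per replicate named
#' `<condition>.<stage>.<rep>`.
#'
#' @param path TSV path.
#' @inheritParams expression_table
#' @export
read_expression <- function(path, baseline = "hiF-T") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fpkm <- as.matrix(tab[, -1, drop = FALSE])
  rownames(fpkm) <- tab[[1]]
  parts <- strsplit(colnames(fpkm), ".", fixed = TRUE)
  map <- data.frame(replicate = colnames(fpkm),
                    condition = vapply(parts, `[[`, "", 1L),
                    stage = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  expression_table(fpkm, map, baseline = baseline)
}

#' @rdname read_expression
#' @param expr `expression_table`.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(gene_id = rownames(expr$fpkm), expr$fpkm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# genes x stages matrix of per-stage mean FPKM for one condition
stage_mean_fpkm <- function(expr, condition, stages) {
  out <- sapply(stages, function(s) {
    cols <- expr$map$replicate[expr$map$condition == condition & expr$map$stage == s]
    rowMeans(expr$fpkm[, cols, drop = FALSE])
  })
  matrix(out, nrow = nrow(expr$fpkm), dimnames = list(rownames(expr$fpkm), stages))
}

# vectorized Welch t-test on log2(FPKM+1); returns two-sided p per gene
welch_p_log2 <- function(a, b) {
  a <- log2(a + 1); b <- log2(b + 1)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate zero-variance pairs: identical means -> no evidence
  p[se2 == 0 & ma == mb] <- 1
  p[se2 == 0 & ma != mb] <- 0
  p
}

#' Upregulation criteria
#'
#' A gene counts as upregulated during reprogramming when, at every
#' non-baseline stage, its fold change versus the baseline exceeds
#' `min_fold`, the Welch-t p-value (on log2(FPKM+1) across replicates) is
#' below `max_p`, and its stage-mean FPKM exceeds `min_fpkm`.
#'
#' @param min_fold,max_p,min_fpkm criterion values (defaults 5, 1e-4, 5).
#' @return criteria list.
#' @export
upregulation_criteria <- function(min_fold = 5, max_p = 1e-4, min_fpkm = 5) {
  stopifnot(min_fold > 0, max_p > 0, min_fpkm > 0)
  list(min_fold = min_fold, max_p = max_p, min_fpkm = min_fpkm)
}

#' Genes upregulated at every stage of one condition
#'
#' @param expr `expression_table`.
#' @param condition condition label.
#' @param stages ordered stage labels (baseline first).
#' @param criteria from [upregulation_criteria()].
#' @return character vector of upregulated gene ids.
#' @export
upregulated_genes <- function(expr, condition, stages,
                              criteria = upregulation_criteria()) {
  stopifnot(inherits(expr, "expression_table"))
  baseline <- expr$baseline
  stopifnot(stages[1] == baseline)
  base_cols <- expr$map$replicate[expr$map$condition == condition &
                                    expr$map$stage == baseline]
  base_mean <- rowMeans(expr$fpkm[, base_cols, drop = FALSE])
  pass <- rep(TRUE, nrow(expr$fpkm))
  p_warned <- FALSE
  for (s in stages[-1]) {
    cols <- expr$map$replicate[expr$map$condition == condition & expr$map$stage == s]
    sm <- rowMeans(expr$fpkm[, cols, drop = FALSE])
    fold_ok <- sm > criteria$min_fold * base_mean
    level_ok <- sm > criteria$min_fpkm
    if (length(cols) >= 2 && length(base_cols) >= 2) {
      p <- welch_p_log2(expr$fpkm[, cols, drop = FALSE],
                        expr$fpkm[, base_cols, drop = FALSE])
      p_ok <- p < criteria$max_p
    } else {
      if (!p_warned) {
        warning("stage(s) with < 2 replicates: p-value criterion skipped")
        p_warned <- TRUE
      }
      p_ok <- TRUE
    }
    pass <- pass & fold_ok & level_ok & p_ok
  }
  rownames(expr$fpkm)[pass]
}

#' Per-class expression statistics across stages
#'
#' For each trajectory class, pools the per-gene stage-mean FPKM of the genes
#' linked to regions of that class and tests each stage against the same
#' genes' baseline values with a two-sided Mann-Whitney U test (exact for
#' pooled n <= 20, normal approximation with tie correction otherwise).
#'
#' @param links region-to-gene links from [nearest_tss()].
#' @param traj classification `data.frame` (`region_id`, `class`), rows
#'   aligned with the region indices used in `links`.
#' @param expr `expression_table`.
#' @param condition condition label.
#' @param stages ordered stage labels (baseline first).
#' @return `data.frame` with `class`, `stage`, `n_genes`, `median_log2_fpkm`,
#'   `p_vs_baseline`.
#' @export
class_expression_stats <- function(links, traj, expr, condition, stages) {
  stopifnot(inherits(expr, "expression_table"))
  sm <- stage_mean_fpkm(expr, condition, stages)
  out <- list()
  for (cls in intersect(c("PO", "CO", "OC"), unique(traj$class))) {
    ridx <- which(traj$class == cls)
    genes <- unique(links$gene_id[links$region_idx %in% ridx])
    genes <- intersect(genes, rownames(sm))
    if (length(genes) == 0) {
      warning("class ", cls, " has no linked genes; omitted")
      next
    }
    base <- sm[genes, stages[1]]
    for (s in stages) {
      v <- sm[genes, s]
      exact <- (length(v) + length(base)) <= 20
      p <- suppressWarnings(
        stats::wilcox.test(v, base, exact = exact, correct = FALSE)$p.value)
      out[[length(out) + 1]] <- data.frame(
        class = cls, stage = s, n_genes = length(genes),
        median_log2_fpkm = stats::median(log2(v + 1)),
        p_vs_baseline = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Differential expression between two replicate groups
#'
#' Welch t-test on log2(FPKM+1) per gene with Benjamini-Hochberg correction
#' across all tested genes; a gene is differential when its (two-sided) fold
#' change exceeds `min_fold` and q-value is below `max_q`.
#'
#' @param fpkm genes x replicates FPKM matrix with rownames.
#' @param group_a,group_b column names (or indices) of the two groups, each
#'   with >= 2 replicates.
#' @param min_fold,max_q criteria (defaults 2, 0.05).
#' @return `data.frame` per gene with `fold`, `p`, `q`, `de`.
#' @export
differential_genes <- function(fpkm, group_a, group_b, min_fold = 2, max_q = 0.05) {
  a <- fpkm[, group_a, drop = FALSE]
  b <- fpkm[, group_b, drop = FALSE]
  stopifnot(ncol(a) >= 2, ncol(b) >= 2)
  p <- welch_p_log2(a, b)
  q <- stats::p.adjust(p, method = "BH")
  ma <- rowMeans(a); mb <- rowMeans(b)
  fold <- pmax((ma + 1e-9) / (mb + 1e-9), (mb + 1e-9) / (ma + 1e-9))
  data.frame(gene_id = rownames(fpkm), fold = fold, p = p, q = q,
             de = fold > min_fold & q < max_q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Epigenetic-factor candidate funnel
#'
#' Reproduces the three-step candidate search: genes whose TSS lies within
#' `max_dist` of any input region (the closed-to-open regions, optionally
#' together with one transient cluster's regions), intersected with the
#' upregulated gene set, intersected with a curated epigenetic-factor list.
#'
#' @param regions interval `data.frame` of input regions; an optional
#'   `switch_stage` column is propagated into the evidence.
#' @param annotation gene annotation `data.frame`.
#' @param upregulated character vector of upregulated gene ids.
#' @param factor_list character vector of curated factor gene ids.
#' @param max_dist TSS-to-region distance cutoff in bp (default 10 kb).
#' @return list with `candidates` (`data.frame`: gene, nearest region,
#'   distance, switch stage) and `counts` (funnel stage sizes:
#'   `n_linked` >= `n_upregulated` >= `n_candidates`).
#' @export
candidate_funnel <- function(regions, annotation, upregulated, factor_list,
                             max_dist = 10000L) {
  stopifnot(length(factor_list) > 0)
  validate_intervals(regions)
  linked <- data.frame(gene_id = character(), region_idx = integer(),
                       distance = integer(), stringsAsFactors = FALSE)
  if (nrow(regions) > 0) {
    for (g in seq_len(nrow(annotation))) {
      ri <- which(regions$chrom == annotation$chrom[g])
      if (length(ri) == 0) next
      d <- point_interval_distance(annotation$tss[g], regions$start[ri], regions$end[ri])
      j <- which.min(d)
      if (d[j] <= max_dist) {
        linked <- rbind(linked, data.frame(
          gene_id = annotation$gene_id[g], region_idx = ri[j],
          distance = d[j], stringsAsFactors = FALSE))
      }
    }
  }
  up_linked <- linked[linked$gene_id %in% upregulated, , drop = FALSE]
  cand <- up_linked[up_linked$gene_id %in% factor_list, , drop = FALSE]
  cand <- cand[order(cand$gene_id), , drop = FALSE]
  cand$region <- sprintf("%s:%d-%d", regions$chrom[cand$region_idx],
                         regions$start[cand$region_idx], regions$end[cand$region_idx])
  cand$switch_stage <- if ("switch_stage" %in% names(regions))
    regions$switch_stage[cand$region_idx] else NA_character_
  list(candidates = cand[, c("gene_id", "region", "distance", "switch_stage")],
       counts = c(n_linked = nrow(linked), n_upregulated = nrow(up_linked),
                  n_candidates = nrow(cand)))
}

#' Group candidate genes by temporal expression pattern
#'
#' Classifies each gene's per-stage mean FPKM series into one of four
#' descriptive groups: `progressive-up` (monotone rise: Spearman rho vs stage
#' index >= `rho_min` and final/baseline fold >= `min_fold`), `late-surge`
#' (mean of the final two stages at least twice the earlier maximum, with all
#' earlier stages below `low_fpkm`), `low-stable` (all stage means below
#' `low_fpkm` with fold span < `min_fold`), and `constant` otherwise.
#'
#' @param genes character vector of gene ids.
#' @param expr `expression_table`.
#' @param condition condition label.
#' @param stages ordered stage labels (baseline first).
#' @param rho_min,min_fold,low_fpkm thresholds (defaults 0.7, 2, 5).
#' @return `data.frame` with `gene_id`, `group` (1-4), `group_label`.
#' @export
group_patterns <- function(genes, expr, condition, stages,
                           rho_min = 0.7, min_fold = 2, low_fpkm = 5) {
  sm <- stage_mean_fpkm(expr, condition, stages)
  genes <- intersect(genes, rownames(sm))
  labels <- c("progressive-up", "constant", "late-surge", "low-stable")
  grp <- vapply(genes, function(g) {
    v <- sm[g, ]
    k <- length(v)
    late <- mean(v[(k - 1):k]); early <- v[1:(k - 2)]
    span <- (max(v) + 1e-9) / (min(v) + 1e-9)
    rho <- suppressWarnings(stats::cor(v, seq_len(k), method = "spearman"))
    if (is.na(rho)) rho <- 0
    if (late >= 2 * max(early) && all(early < low_fpkm)) return(3L)
    if (rho >= rho_min && v[k] >= min_fold * (v[1] + 1e-9)) return(1L)
    if (all(v < low_fpkm) && span < min_fold) return(4L)
    2L
  }, 1L)
  data.frame(gene_id = genes, group = unname(grp),
             group_label = labels[grp], stringsAsFactors = FALSE, row.names = NULL)
}
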