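#' Default pipeline configuration
#'
#' A single nested list drives the full analysis; every tunable from the
#' component modules is exposed here. `threshold = NULL` calibrates the
#' open/closed cutoff from pseudo-input at `fpr`; supplying a number (e.g.
#' 4.2) reproduces fixed-threshold behaviour.
#'
#' @param seed master seed for every source of randomness.
#' @param gap_bp atlas merge gap (bp).
#' @param fpr target false-positive rate for threshold calibration.
#' @param threshold optional fixed threshold (signal units).
#' @param log_base signal log base (2 or 10).
#' @param cluster list: `enabled`, `c`, `m`, `tol`, `max_iter`,
#'   `funnel_cluster` (cluster index whose regions join the candidate
#'   funnel, or `NA`).
#' @param genes list: `condition`, `max_dist`, `upregulation` criteria.
#' @param binding list: `enabled`, `max_dist`, `min_fpkm`, `method`,
#'   `nominations` (list of `(isoform, sign, gene_set)` triples).
#' @param synthetic `study_config` used when no study is supplied.
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            gap_bp = 100L,
                            fpr = 0.01,
                            threshold = NULL,
                            log_base = 2,
                            cluster = list(),
                            genes = list(),
                            binding = list(),
                            synthetic = study_config()) {
  cl_def <- list(enabled = TRUE, c = 10L, m = 2, tol = 1e-6, max_iter = 500L,
                 funnel_cluster = NA_integer_)
  ge_def <- list(condition = "naive", max_dist = 10000L,
                 upregulation = upregulation_criteria())
  bi_def <- list(enabled = TRUE, max_dist = 10000L, min_fpkm = 1,
                 method = "pearson",
                 nominations = list(
                   list(isoform = "alpha", sign = "positive", gene_set = "EMT_LIKE"),
                   list(isoform = "beta", sign = "negative", gene_set = "PROLIF_LIKE")))
  merge_keys <- function(def, user, where) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0) {
      hint <- vapply(unknown, function(k) {
        m <- agrep(k, names(def), max.distance = 2, value = TRUE)
        if (length(m) > 0) sprintf(" (did you mean '%s'?)", m[1]) else ""
      }, "")
      stop("unknown config key(s) under ", where, ": ",
           paste0(unknown, hint, collapse = ", "))
    }
    utils::modifyList(def, user)
  }
  cfg <- list(seed = as.integer(seed), gap_bp = gap_bp, fpr = fpr,
              threshold = threshold, log_base = log_base,
              cluster = merge_keys(cl_def, cluster, "cluster"),
              genes = merge_keys(ge_def, genes, "genes"),
              binding = merge_keys(bi_def, binding, "binding"),
              synthetic = synthetic)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

#' Validate and normalize a pipeline configuration
#'
#' @param cfg `pipeline_config` (or bare list with the same shape).
#' @return the validated config, invisibly usable; errors name the offending
#'   key path.
#' @export
validate_config <- function(cfg) {
  known <- c("seed", "gap_bp", "fpr", "threshold", "log_base",
             "cluster", "genes", "binding", "synthetic")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    hint <- vapply(unknown, function(k) {
      m <- agrep(k, known, max.distance = 2, value = TRUE)
      if (length(m) > 0) sprintf(" (did you mean '%s'?)", m[1]) else ""
    }, "")
    stop("unknown config key(s): ", paste0(unknown, hint, collapse = ", "))
  }
  if (!(cfg$fpr > 0 && cfg$fpr < 1)) stop("config error at 'fpr': must be in (0, 1)")
  if (!cfg$log_base %in% c(2, 10)) stop("config error at 'log_base': must be 2 or 10")
  if (cfg$gap_bp < 0) stop("config error at 'gap_bp': must be >= 0")
  if (!inherits(cfg$synthetic, "study_config"))
    stop("config error at 'synthetic': must be a study_config()")
  if (!cfg$genes$condition %in% cfg$synthetic$conditions)
    stop("config error at 'genes.condition': not one of the study conditions")
  if (cfg$cluster$m <= 1) stop("config error at 'cluster.m': fuzzifier must be > 1")
  class(cfg) <- "pipeline_config"
  cfg
}

# stable non-cryptographic hash of the serialized config (for provenance)
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full trajectory analysis end-to-end
#'
#' Executes atlas construction, threshold calibration, trajectory
#' classification, cross-condition comparison, transient-region clustering,
#' the candidate-gene funnel and the binding-site analysis on a synthetic
#' study (generated from `config$synthetic` when `study` is `NULL`). All
#' randomness derives from `config$seed`; the returned report contains no
#' timestamps, so identical (config, seed) pairs yield identical reports.
#'
#' @param config `pipeline_config`.
#' @param study optional `synthetic_study` to analyse.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @return `run_report`: nested list of parameters, counts and results.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL, out_dir = NULL) {
  config <- validate_config(config)
  warnings_log <- character(0)
  catchw <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (is.null(study)) study <- generate_study(config$synthetic, seed = config$seed)
  cfg <- study$config
  stages <- cfg$stages
  conds <- cfg$conditions

  ## atlas
  peak_sets <- list()
  for (cond in conds) for (stg in stages) {
    p <- study$peaks[[cond]][[stg]]
    if (nrow(p) > 0) peak_sets[[paste(cond, stg, sep = ".")]] <- p
  }
  atlas <- build_atlas(peak_sets, gap_bp = config$gap_bp)
  hits <- GenomicRanges::findOverlaps(as_gr(atlas$regions), as_gr(study$regions))
  src <- rep(NA_integer_, nrow(atlas$regions))
  src[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  if (anyNA(src)) stop("atlas region without a source region (unexpected)")

  threshold <- if (is.null(config$threshold)) {
    calibrate_threshold(study$pseudo_values, target_fpr = config$fpr)
  } else fixed_threshold(config$threshold, target_fpr = config$fpr)
  exceedance <- mean(study$pseudo_values > threshold$value)

  ## trajectories per condition
  traj <- list(); counts <- list(); calls <- list()
  for (cond in conds) {
    mat <- study$signal[[cond]][src, , drop = FALSE]
    rownames(mat) <- study$regions$region_id[src]
    cl <- binarize(mat, threshold)
    calls[[cond]] <- cl
    traj[[cond]] <- classify_trajectories(cl, stages)
    counts[[cond]] <- table(factor(traj[[cond]]$class,
                                   levels = c("PO", "CO", "OC", "NEVER", "TRANSIENT")))
  }

  ## cross-condition comparison
  venn <- list(); coocc <- list()
  for (cls in c("PO", "CO", "OC")) {
    sel <- lapply(conds, function(cond) {
      idx <- which(traj[[cond]]$class == cls)
      atlas$regions[idx, c("chrom", "start", "end")]
    })
    venn[[cls]] <- intersect_counts(sel[[1]], sel[[2]])
  }
  for (cls in c("CO", "OC")) {
    coocc[[cls]] <- co_occurrence(traj[[conds[1]]], traj[[conds[2]]],
                                  class = cls, stages = stages)
  }

  ## transient clustering
  clusters <- NULL; categories <- NULL
  transient_ids <- unique(c(traj[[conds[1]]]$region_id[traj[[conds[1]]]$class == "TRANSIENT"],
                            traj[[conds[2]]]$region_id[traj[[conds[2]]]$class == "TRANSIENT"]))
  if (isTRUE(config$cluster$enabled) && length(transient_ids) >= config$cluster$c) {
    sig_list <- lapply(stats::setNames(conds, conds), function(cond) {
      m <- study$signal[[cond]][src, , drop = FALSE]
      rownames(m) <- study$regions$region_id[src]
      m[transient_ids, , drop = FALSE]
    })
    clusters <- cluster_transient(sig_list, c = config$cluster$c,
                                  m = config$cluster$m, seed = config$seed,
                                  tol = config$cluster$tol,
                                  max_iter = config$cluster$max_iter)
    categories <- categorize_clusters(clusters)
  }

  ## gene linking, class statistics, candidate funnel
  gcond <- config$genes$condition
  links <- nearest_tss(atlas$regions, study$annotation,
                       max_dist_bp = config$genes$max_dist)
  class_stats <- catchw(class_expression_stats(links, traj[[gcond]], study$expr,
                                               gcond, stages))
  upreg <- catchw(upregulated_genes(study$expr, gcond, stages,
                                    criteria = config$genes$upregulation))
  co_idx <- which(traj[[gcond]]$class == "CO")
  funnel_regions <- atlas$regions[co_idx, c("chrom", "start", "end")]
  funnel_regions$switch_stage <- traj[[gcond]]$switch_stage[co_idx]
  fc <- config$cluster$funnel_cluster
  if (!is.null(clusters) && !is.na(fc)) {
    cl_ids <- clusters$region_ids[clusters$hard == fc]
    extra_idx <- which(traj[[gcond]]$region_id %in% cl_ids)
    extra <- atlas$regions[extra_idx, c("chrom", "start", "end")]
    if (nrow(extra) > 0) {
      extra$switch_stage <- NA_character_
      funnel_regions <- rbind(funnel_regions, extra)
    }
  }
  funnel <- candidate_funnel(funnel_regions, study$annotation, upreg,
                             study$factor_list, max_dist = config$genes$max_dist)
  patterns <- group_patterns(funnel$candidates$gene_id, study$expr, gcond, stages)

  ## binding analysis
  binding_out <- NULL
  if (isTRUE(config$binding$enabled) && !is.null(study$binding)) {
    bcond <- study$binding$condition
    isoforms <- names(study$binding$candidates)
    sites <- lapply(stats::setNames(isoforms, isoforms), function(iso) {
      call_sites(study$binding$candidates[[iso]], study$binding$values[[iso]],
                 threshold, isoform = iso)
    })
    bvenn <- binding_venn(sites[[1]], sites[[2]])
    targets <- list(); corr <- list()
    for (iso in isoforms) {
      targets[[iso]] <- assign_targets(sites[[iso]], study$annotation, study$expr,
                                       max_dist = config$binding$max_dist,
                                       min_fpkm = config$binding$min_fpkm)
      corr[[iso]] <- catchw(classify_correlation(
        targets[[iso]], study$binding$isoform_series[[iso]], study$expr,
        bcond, stages, method = config$binding$method))
    }
    noms <- lapply(config$binding$nominations, function(tr) {
      if (!tr$isoform %in% isoforms || !tr$gene_set %in% names(study$gene_sets))
        return(character(0))
      tg <- corr[[tr$isoform]]$targets
      nominate(tg$gene_id[!is.na(tg$sign) & tg$sign == tr$sign],
               study$gene_sets[[tr$gene_set]])
    })
    names(noms) <- vapply(config$binding$nominations, function(tr)
      paste(tr$isoform, tr$sign, tr$gene_set, sep = "/"), "")
    binding_out <- list(
      site_counts = vapply(sites, function(x) nrow(x$sites), 0L),
      venn = bvenn,
      target_counts = vapply(targets, nrow, 0L),
      positive_fraction = vapply(corr, `[[`, 0, "positive_fraction"),
      targets = targets, correlation = corr, nominations = noms)
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("chromtraj")),
    config_hash = config_hash(config),
    seed = config$seed,
    params = list(gap_bp = config$gap_bp, fpr = config$fpr,
                  threshold = threshold$value, threshold_source = threshold$source,
                  log_base = config$log_base),
    atlas_size = nrow(atlas$regions),
    pseudo_exceedance = exceedance,
    class_counts = lapply(counts, function(x) as.list(as.integer(x)) |>
                            stats::setNames(names(x))),
    stage_counts = lapply(stats::setNames(conds, conds),
                          function(cond) stage_counts(traj[[cond]], stages)),
    venn = venn,
    co_occurrence_totals = vapply(coocc, sum, 0L),
    n_transient_clustered = if (is.null(clusters)) 0L else nrow(clusters$membership),
    cluster_sizes = if (is.null(clusters)) integer(0) else
      as.integer(table(factor(clusters$hard, levels = seq_len(clusters$c)))),
    cluster_categories = if (is.null(categories)) character(0) else categories$category,
    n_upregulated = length(upreg),
    funnel_counts = as.list(funnel$counts),
    candidates = funnel$candidates$gene_id,
    pattern_groups = patterns,
    binding = if (is.null(binding_out)) NULL else
      binding_out[c("site_counts", "venn", "target_counts",
                    "positive_fraction", "nominations")],
    warnings = warnings_log),
    class = "run_report")

  result <- list(report = report, atlas = atlas, threshold = threshold,
                 traj = traj, calls = calls, clusters = clusters,
                 categories = categories, links = links,
                 class_stats = class_stats, upregulated = upreg,
                 funnel = funnel, patterns = patterns, binding = binding_out,
                 source_idx = src, study = study)
  if (!is.null(out_dir)) write_report(result, out_dir)
  result
}

#' @export
print.run_report <- function(x, ...) {
  cat("chromtraj run report\n")
  cat(sprintf("  atlas: %d regions; threshold %.3f (%s, FPR %.3g, exceedance %.4f)\n",
              x$atlas_size, x$params$threshold, x$params$threshold_source,
              x$params$fpr, x$pseudo_exceedance))
  for (cond in names(x$class_counts)) {
    cc <- x$class_counts[[cond]]
    cat(sprintf("  %s classes: %s\n", cond,
                paste(sprintf("%s=%d", names(cc), unlist(cc)), collapse = " ")))
  }
  cat(sprintf("  upregulated genes: %d; funnel: %d linked -> %d upregulated -> %d candidates\n",
              x$n_upregulated, x$funnel_counts$n_linked,
              x$funnel_counts$n_upregulated, x$funnel_counts$n_candidates))
  if (!is.null(x$binding)) {
    cat(sprintf("  binding: sites %s; shared %d; targets %s; positive fraction %s\n",
                paste(x$binding$site_counts, collapse = "/"),
                x$binding$venn$shared_a,
                paste(x$binding$target_counts, collapse = "/"),
                paste(sprintf("%.3f", x$binding$positive_fraction), collapse = "/")))
  }
  if (length(x$warnings) > 0) cat(sprintf("  warnings: %d\n", length(x$warnings)))
  invisible(x)
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", force = TRUE)
  for (cond in names(result$traj)) {
    utils::write.table(result$traj[[cond]],
                       file.path(out_dir, sprintf("trajectories_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_bed(result$atlas$regions[, c("chrom", "start", "end", "region_id")],
            file.path(out_dir, "atlas.bed"))
  invisible(out_dir)
}
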