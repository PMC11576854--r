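#' Configuration for a synthetic reprogramming study
#'
#' Describes the simulated world: a 7-stage time course (fibroblast baseline
#' `hiF-T`, days 6-24, final iPSC) in two conditions (naive, primed), regions
#' planted with one of five accessibility trajectories, log2-scale Gaussian
#' signal (open and closed states cleanly separated), replicate-level FPKM
#' expression coupled to linked-region accessibility, a curated factor list
#' with planted funnel candidates and single-criterion decoys, and two
#' binding-site sets with planted correlation-sign targets.
#'
#' @param stages ordered stage labels (baseline first).
#' @param conditions two condition labels.
#' @param n_per_class named region counts for PO, CO, OC, NEVER, TRANSIENT.
#' @param open_mean,open_sd,closed_mean,closed_sd log2 signal model
#'   (defaults 6.0/0.7 open, 2.0/0.7 closed: clean separation around a
#'   4.2-like threshold).
#' @param n_pseudo pseudo-input sample size.
#' @param replicates replicates per (condition, stage); default 2, matching
#'   typical bulk ATAC/RNA designs.
#' @param region_width min/max region width in bp.
#' @param peak_jitter max bp of peak-boundary jitter per sample.
#' @param base_log2_mean,base_log2_sd gene baseline log2 FPKM distribution.
#' @param coupling log2-FPKM shift per unit of standardized linked-region
#'   accessibility.
#' @param expr_noise_sd replicate-level log2 FPKM noise.
#' @param n_extra_genes unlinked genes (placed > 10 kb from all regions).
#' @param n_factor_genes planted funnel candidates (factor-listed, forced
#'   upregulated, linked to CO regions).
#' @param n_decoys_no_factor,n_decoys_not_up,n_decoys_far funnel decoys, each
#'   failing exactly one funnel criterion (list membership, upregulation,
#'   proximity).
#' @param n_targets named per-isoform planted binding-target counts.
#' @param shared_sites binding sites common to both isoforms (placed in a
#'   gene-free zone so target rosters stay per-isoform).
#' @param positive_fraction named per-isoform fraction of positively
#'   correlated targets.
#' @param n_low_fpkm named per-isoform count of targets planted at FPKM < 1
#'   (exercising the expression filter).
#' @param n_site_decoys per-isoform below-threshold candidate regions.
#' @param seed integer seed fixing every generated byte.
#' @return config list of class `study_config`.
#' @export
study_config <- function(stages = c("hiF-T", "d6", "d8", "d14", "d20", "d24", "iPSC"),
                         conditions = c("naive", "primed"),
                         n_per_class = c(PO = 400, CO = 400, OC = 400,
                                         NEVER = 400, TRANSIENT = 400),
                         open_mean = 6.0, open_sd = 0.7,
                         closed_mean = 2.0, closed_sd = 0.7,
                         n_pseudo = 10000L,
                         replicates = 2L,
                         region_width = c(200L, 800L),
                         peak_jitter = 30L,
                         base_log2_mean = 3, base_log2_sd = 1.2,
                         coupling = 1.0,
                         expr_noise_sd = 0.25,
                         n_extra_genes = 100L,
                         n_factor_genes = 10L,
                         n_decoys_no_factor = 30L,
                         n_decoys_not_up = 30L,
                         n_decoys_far = 30L,
                         n_targets = c(alpha = 400L, beta = 100L),
                         shared_sites = 10L,
                         positive_fraction = c(alpha = 0.8, beta = 0.2),
                         n_low_fpkm = c(alpha = 20L, beta = 5L),
                         n_site_decoys = 50L,
                         seed = 42L) {
  stopifnot(length(stages) >= 3, length(conditions) == 2,
            all(names(n_per_class) == c("PO", "CO", "OC", "NEVER", "TRANSIENT")),
            all(n_per_class >= 0), open_mean > closed_mean,
            all(positive_fraction >= 0 & positive_fraction <= 1),
            replicates >= 1)
  if (sum(n_per_class) == 0) stop("all region class counts are zero")
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

# one planted open/closed state vector per trajectory class
plant_states <- function(class, s) {
  switch(class,
    PO = rep(TRUE, s),
    NEVER = rep(FALSE, s),
    CO = { k <- sample(2:s, 1); c(rep(FALSE, k - 1), rep(TRUE, s - k + 1)) },
    OC = { k <- sample(2:s, 1); c(rep(TRUE, k - 1), rep(FALSE, s - k + 1)) },
    TRANSIENT = {
      # one interior excursion: open-closed-open or closed-open-closed
      ab <- sort(sample(2:s, 2))
      base <- sample(c(TRUE, FALSE), 1)
      st <- rep(base, s)
      st[ab[1]:(ab[2] - 1)] <- !base
      st
    })
}

#' Generate the region atlas, per-condition signal matrices and pseudo-input
#'
#' Regions are laid out with generous spacing on two synthetic chromosomes;
#' each region draws its per-stage log2 signal from the open or closed
#' Gaussian according to its planted trajectory (planted independently per
#' condition for switch stages, with the same class in both conditions).
#' Per-sample peak files are emitted for stages at which a region is open,
#' with small boundary jitter. Pseudo-input values are drawn from the closed
#' distribution.
#'
#' @param config `study_config`.
#' @param reseed set the RNG from `config$seed` (disable when composing).
#' @return list with `regions`, `signal` (per condition regions x stages
#'   matrix), `peaks` (per condition, per stage interval sets),
#'   `pseudo_values`, `chrom_sizes`, `truth` (per-region planted class and
#'   switch stages).
#' @export
generate_atlas_signals <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "study_config"))
  if (reseed) set.seed(config$seed)
  s <- length(config$stages)
  n <- sum(config$n_per_class)
  classes <- sample(rep(names(config$n_per_class), config$n_per_class))
  widths <- sample(config$region_width[1]:config$region_width[2], n, replace = TRUE)
  half <- ceiling(n / 2)
  chrom <- rep(c("chr1", "chr2"), c(half, n - half))
  start <- integer(n)
  pos <- c(chr1 = 10000L, chr2 = 10000L)
  gaps <- sample(2000:4000, n, replace = TRUE)
  for (i in seq_len(n)) {
    start[i] <- pos[chrom[i]]
    pos[chrom[i]] <- pos[chrom[i]] + widths[i] + gaps[i]
  }
  regions <- data.frame(chrom = chrom, start = start, end = start + widths,
                        stringsAsFactors = FALSE)
  regions$region_id <- sprintf("R%05d", seq_len(n))
  chrom_sizes <- c(chr1 = unname(pos["chr1"]) + 500000L,
                   chr2 = unname(pos["chr2"]) + 500000L)

  truth <- data.frame(region_id = regions$region_id, class = classes,
                      stringsAsFactors = FALSE)
  signal <- list(); states <- list()
  for (cond in config$conditions) {
    st <- t(vapply(classes, plant_states, logical(s), s = s))
    vals <- matrix(0, n, s, dimnames = list(regions$region_id, config$stages))
    n_open <- sum(st)
    vals[st] <- stats::rnorm(n_open, config$open_mean, config$open_sd)
    vals[!st] <- stats::rnorm(n * s - n_open, config$closed_mean, config$closed_sd)
    signal[[cond]] <- vals
    states[[cond]] <- st
    sw <- apply(st, 1, function(z) {
      d <- diff(z)
      if (sum(d != 0) == 1) which(d != 0) + 1L else NA_integer_
    })
    truth[[paste0("switch_idx_", cond)]] <- ifelse(classes %in% c("CO", "OC"),
                                                   sw, NA_integer_)
  }

  peaks <- lapply(stats::setNames(config$conditions, config$conditions), function(cond) {
    lapply(stats::setNames(config$stages, config$stages), function(stg) {
      open <- states[[cond]][, match(stg, config$stages)]
      idx <- which(open)
      if (length(idx) == 0) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
      }
      j1 <- sample(0:config$peak_jitter, length(idx), replace = TRUE)
      j2 <- sample(0:config$peak_jitter, length(idx), replace = TRUE)
      data.frame(chrom = regions$chrom[idx],
                 start = pmax(0L, regions$start[idx] - j1),
                 end = regions$end[idx] + j2, stringsAsFactors = FALSE)
    })
  })

  pseudo_values <- stats::rnorm(config$n_pseudo, config$closed_mean, config$closed_sd)
  list(regions = regions, signal = signal, peaks = peaks, states = states,
       pseudo_values = pseudo_values, chrom_sizes = chrom_sizes, truth = truth)
}

make_gene_rows <- function(gene_id, chrom, tss, strand, span = 2000L) {
  start <- ifelse(strand == "+", tss, tss - span + 1L)
  end <- start + span
  ex1 <- c(start, start + 300L)
  ex2 <- c(start + 1200L, start + 1700L)
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
             start = start, end = end,
             exons = sprintf("%d-%d;%d-%d", ex1[1], ex1[2], ex2[1], ex2[2]),
             stringsAsFactors = FALSE)
}

#' Generate annotation, expression and the factor-list planting
#'
#' Every region gets one linked gene with its TSS within 10 kb; a gene's
#' log2 FPKM per replicate is baseline + coupling x (standardized planted
#' region trajectory) + Gaussian noise. Funnel planting: `n_factor_genes`
#' genes linked to CO regions are factor-listed and forced to satisfy the
#' upregulation criterion (near-deterministic strong induction, so the
#' p-value criterion is attainable at 2 replicates); three decoy groups each
#' fail exactly one funnel criterion.
#'
#' @param config `study_config`.
#' @param atlas output of [generate_atlas_signals()].
#' @param reseed set the RNG from `config$seed` (disable when composing).
#' @return list with `annotation`, `expr` (`expression_table`),
#'   `factor_list`, `truth` (per-gene role and upregulation flag),
#'   `chrom_sizes` (extended).
#' @export
generate_expression <- function(config, atlas, reseed = TRUE) {
  if (reseed) set.seed(config$seed + 1L)
  regions <- atlas$regions
  n <- nrow(regions)
  s <- length(config$stages)
  mid <- (regions$start + regions$end) %/% 2L
  offset <- sample(seq(-3000L, 3000L), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- pmax(2000L, mid + offset)
  linked <- make_gene_rows(sprintf("G%05d", seq_len(n)), regions$chrom, tss, strand)

  # unlinked genes live > 10 kb beyond the last region of chr2
  n_extra <- config$n_extra_genes + config$n_decoys_far
  tail0 <- max(regions$end[regions$chrom == "chr2"]) + 50000L
  extra <- make_gene_rows(sprintf("X%04d", seq_len(n_extra)), "chr2",
                          tss = tail0 + seq_len(n_extra) * 25000L,
                          strand = sample(c("+", "-"), n_extra, replace = TRUE))
  annotation <- rbind(linked, extra)
  chrom_sizes <- atlas$chrom_sizes
  chrom_sizes["chr2"] <- max(chrom_sizes["chr2"], max(extra$end) + 500000L)

  # funnel planting over CO regions (class is shared across conditions)
  co_idx <- which(atlas$truth$class == "CO")
  need <- config$n_factor_genes + config$n_decoys_no_factor + config$n_decoys_not_up
  if (length(co_idx) < need) stop("not enough CO regions for funnel planting")
  picks <- sample(co_idx, need)
  g_factor <- linked$gene_id[picks[seq_len(config$n_factor_genes)]]
  g_decoyA <- linked$gene_id[picks[config$n_factor_genes + seq_len(config$n_decoys_no_factor)]]
  g_decoyB <- linked$gene_id[picks[config$n_factor_genes + config$n_decoys_no_factor +
                                     seq_len(config$n_decoys_not_up)]]
  g_decoyC <- extra$gene_id[seq_len(config$n_decoys_far)]
  factor_list <- sort(c(g_factor, g_decoyB, g_decoyC))
  forced_up <- c(g_factor, g_decoyA, g_decoyC)

  genes <- annotation$gene_id
  base <- stats::rnorm(length(genes), config$base_log2_mean, config$base_log2_sd)
  names(base) <- genes

  # standardized planted mean trajectory per region/condition
  zshape <- lapply(atlas$states, function(st) {
    mu <- ifelse(st, config$open_mean, config$closed_mean)
    t(apply(mu, 1, function(v) {
      sd <- stats::sd(v)
      if (sd == 0) rep(0, length(v)) else (v - mean(v)) / sd
    }))
  })

  reps <- config$replicates
  cols <- character(0); map <- NULL
  for (cond in config$conditions) for (stg in config$stages) for (r in seq_len(reps)) {
    cols <- c(cols, paste(cond, stg, paste0("r", r), sep = "."))
  }
  map <- data.frame(replicate = cols,
                    condition = vapply(strsplit(cols, ".", fixed = TRUE), `[[`, "", 1L),
                    stage = vapply(strsplit(cols, ".", fixed = TRUE), `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  log2fpkm <- matrix(0, length(genes), length(cols), dimnames = list(genes, cols))
  for (cond in config$conditions) {
    z <- zshape[[cond]]
    for (si in seq_len(s)) {
      mu <- base
      mu[linked$gene_id] <- base[linked$gene_id] + config$coupling * z[, si]
      for (r in seq_len(reps)) {
        cn <- paste(cond, config$stages[si], paste0("r", r), sep = ".")
        log2fpkm[, cn] <- mu + stats::rnorm(length(genes), 0, config$expr_noise_sd)
      }
    }
  }
  # forced upregulation: baseline FPKM 2, every later stage FPKM 40.
  # Replicate sd must be ~1e-4: the Welch df with 2 replicates can approach 1
  # (near-Cauchy tail), so p < 1e-4 needs t in the thousands. "Forcing" means
  # induction strong and reproducible enough to satisfy all three criteria.
  for (g in forced_up) {
    for (cond in config$conditions) {
      for (si in seq_len(s)) {
        lv <- if (si == 1) 1 else log2(40)
        for (r in seq_len(reps)) {
          cn <- paste(cond, config$stages[si], paste0("r", r), sep = ".")
          log2fpkm[g, cn] <- lv + stats::rnorm(1, 0, 1e-4)
        }
      }
    }
  }
  # decoy B: flat, well expressed -> fails only the fold criterion
  for (g in g_decoyB) log2fpkm[g, ] <- log2(20) + stats::rnorm(ncol(log2fpkm), 0, 0.01)

  fpkm <- 2^log2fpkm
  expr <- expression_table(fpkm, map, baseline = config$stages[1])

  role <- rep("background", length(genes)); names(role) <- genes
  role[linked$gene_id] <- "linked"
  role[g_factor] <- "factor"; role[g_decoyA] <- "decoy_no_factor"
  role[g_decoyB] <- "decoy_not_up"; role[g_decoyC] <- "decoy_far"
  truth <- data.frame(gene_id = genes, role = unname(role),
                      linked_region = c(regions$region_id, rep(NA, n_extra)),
                      forced_upregulated = genes %in% forced_up,
                      stringsAsFactors = FALSE)
  list(annotation = annotation, expr = expr, factor_list = factor_list,
       truth = truth, chrom_sizes = chrom_sizes)
}

#' Generate two binding-site sets with planted correlation-sign targets
#'
#' Places per-isoform target genes on a dedicated chromosome, one binding
#' site within 10 kb of each target TSS, plus a configured number of shared
#' sites (in a gene-free zone) and below-threshold decoy candidates. Target
#' expression series are regenerated as linear responses to the isoform's
#' own expression series with the planted sign (|r| >= 0.9 by construction);
#' a planted subset is set to FPKM < 1 to exercise the exclusion filter.
#'
#' @param config `study_config`.
#' @param exprgen output of [generate_expression()] (extended in place).
#' @param reseed set the RNG from `config$seed` (disable when composing).
#' @return list with `candidates`/`values` per isoform, `sites`,
#'   `isoform_series` (per-stage log2 expression of each isoform, first
#'   condition), `annotation` and `expr` (extended), `gene_sets`,
#'   `truth` (per-target isoform, planted sign, low-FPKM flag),
#'   `chrom_sizes` (extended).
#' @export
generate_binding <- function(config, exprgen, reseed = TRUE) {
  if (reseed) set.seed(config$seed + 2L)
  s <- length(config$stages)
  isoforms <- names(config$n_targets)
  cond1 <- config$conditions[1]
  rising <- seq(0.5, 4.6, length.out = s)
  isoform_series <- list()
  isoform_series[[isoforms[1]]] <- rising
  isoform_series[[isoforms[2]]] <- rev(rising)

  ann_new <- NULL; truth <- NULL
  site_sets <- list(); cand_sets <- list(); val_sets <- list()
  pos <- 50000L
  n_total <- sum(config$n_targets)
  if (any(config$n_low_fpkm >= config$n_targets))
    stop("more low-FPKM targets requested than targets")
  expr <- exprgen$expr
  fpkm <- expr$fpkm
  reps <- config$replicates
  shared <- NULL
  for (iso in isoforms) {
    k <- config$n_targets[[iso]]
    ids <- sprintf("T%s%04d", toupper(substr(iso, 1, 1)), seq_len(k))
    tss <- pos + seq_len(k) * 25000L
    pos <- max(tss) + 50000L
    strand <- sample(c("+", "-"), k, replace = TRUE)
    ann_new <- rbind(ann_new, make_gene_rows(ids, "chr3", tss, strand))
    off <- sample(seq(-5000L, 5000L), k, replace = TRUE)
    sites <- data.frame(chrom = "chr3", start = tss + off,
                        end = tss + off + 300L, stringsAsFactors = FALSE)
    low <- seq_len(k) > (k - config$n_low_fpkm[[iso]])
    n_hi <- sum(!low)
    n_pos <- round(config$positive_fraction[[iso]] * n_hi)
    sign <- rep(NA_character_, k)
    sign[!low] <- sample(rep(c("positive", "negative"), c(n_pos, n_hi - n_pos)))
    series <- isoform_series[[iso]]
    zs <- (series - mean(series)) / stats::sd(series)
    new_rows <- matrix(2^config$base_log2_mean, k, ncol(fpkm),
                       dimnames = list(ids, colnames(fpkm)))
    for (i in seq_len(k)) {
      if (low[i]) { new_rows[i, ] <- 0.5; next }
      sgn <- if (sign[i] == "positive") 1 else -1
      for (si in seq_len(s)) {
        mu <- 2 + sgn * 1.5 * zs[si] + stats::rnorm(1, 0, 0.05)
        for (cond in config$conditions) for (r in seq_len(reps)) {
          cn <- paste(cond, config$stages[si], paste0("r", r), sep = ".")
          new_rows[i, cn] <- 2^(mu + stats::rnorm(1, 0, 0.05))
        }
      }
    }
    fpkm <- rbind(fpkm, new_rows)
    truth <- rbind(truth, data.frame(gene_id = ids, isoform = iso,
                                     planted_sign = sign, low_fpkm = low,
                                     stringsAsFactors = FALSE))
    site_sets[[iso]] <- sites
  }
  # shared sites in a gene-free zone (> 10 kb from every gene)
  if (config$shared_sites > 0) {
    sh_start <- pos + 100000L + seq_len(config$shared_sites) * 25000L
    shared <- data.frame(chrom = "chr3", start = sh_start,
                         end = sh_start + 300L, stringsAsFactors = FALSE)
    for (iso in isoforms) site_sets[[iso]] <- rbind(site_sets[[iso]], shared)
  }
  chr3_size <- pos + 100000L + (config$shared_sites + 10L) * 25000L + 500000L
  for (iso in isoforms) {
    sites <- site_sets[[iso]]
    nd <- config$n_site_decoys
    dec_start <- chr3_size + seq_len(nd) * 5000L
    decoys <- data.frame(chrom = "chr3", start = dec_start,
                         end = dec_start + 300L, stringsAsFactors = FALSE)
    cand <- rbind(sites, decoys)
    vals <- c(stats::rnorm(nrow(sites), config$open_mean, config$open_sd),
              stats::rnorm(nd, config$closed_mean, config$closed_sd))
    cand_sets[[iso]] <- cand
    val_sets[[iso]] <- vals
    chr3_size <- max(chr3_size, max(cand$end))
  }
  chrom_sizes <- exprgen$chrom_sizes
  chrom_sizes["chr3"] <- chr3_size + 500000L

  annotation <- rbind(exprgen$annotation, ann_new)
  expr <- expression_table(fpkm, expr$map, baseline = expr$baseline)

  # curated gene sets with planted single/multi-member intersections
  pos_a <- truth$gene_id[truth$isoform == isoforms[1] &
                           !truth$low_fpkm & truth$planted_sign == "positive"]
  neg_b <- truth$gene_id[truth$isoform == isoforms[2] &
                           !truth$low_fpkm & truth$planted_sign == "negative"]
  bg <- grep("^X", exprgen$annotation$gene_id, value = TRUE)
  gene_sets <- list(
    EMT_LIKE = sort(c(pos_a[1], utils::head(bg, 20))),
    PROLIF_LIKE = sort(c(utils::head(neg_b, 6), utils::tail(bg, 20))))

  list(candidates = cand_sets, values = val_sets, sites = site_sets,
       isoform_series = isoform_series, annotation = annotation, expr = expr,
       gene_sets = gene_sets, truth = truth, chrom_sizes = chrom_sizes,
       condition = cond1)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Composes [generate_atlas_signals()], [generate_expression()] and
#' [generate_binding()] under a single seed. The returned object carries
#' everything the pipeline consumes plus machine-readable ground truth.
#'
#' @param config `study_config`.
#' @param seed overrides `config$seed` when given.
#' @return object of class `synthetic_study`.
#' @export
generate_study <- function(config = study_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  atlas <- generate_atlas_signals(config, reseed = FALSE)
  exprgen <- generate_expression(config, atlas, reseed = FALSE)
  binding <- generate_binding(config, exprgen, reseed = FALSE)
  structure(list(
    config = config,
    regions = atlas$regions,
    signal = atlas$signal,
    peaks = atlas$peaks,
    pseudo_values = atlas$pseudo_values,
    chrom_sizes = binding$chrom_sizes,
    annotation = binding$annotation,
    expr = binding$expr,
    factor_list = exprgen$factor_list,
    gene_sets = binding$gene_sets,
    binding = binding[c("candidates", "values", "sites", "isoform_series", "condition")],
    ground_truth = list(regions = atlas$truth, genes = exprgen$truth,
                        targets = binding$truth)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d regions x %d stages x %d conditions, ",
                     "%d genes, %d + %d binding candidates (seed %d)\n"),
              nrow(x$regions), length(x$config$stages), length(x$config$conditions),
              nrow(x$expr$fpkm), nrow(x$binding$candidates[[1]]),
              nrow(x$binding$candidates[[2]]), x$config$seed))
  invisible(x)
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits per-(condition, stage) peak BED files and 25-bp bedGraph tracks
#' (covering region and pseudo-input footprints; zero background bins are
#' omitted as in real sparse bedGraphs), the expression TSV, annotation TSV,
#' chrom.sizes, factor list, GMT gene sets, binding-candidate BEDs and the
#' ground-truth JSON. Everything re-parses through the package readers.
#'
#' @param study `synthetic_study`.
#' @param dir output directory (created if needed).
#' @param library_size nominal library size used to invert the log transform
#'   when writing raw-scale tracks.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, library_size = 2e7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- study$config
  for (cond in cfg$conditions) {
    for (stg in cfg$stages) {
      safe <- gsub("[^A-Za-z0-9]", "", stg)
      write_bed(study$peaks[[cond]][[stg]],
                file.path(dir, sprintf("peaks_%s_%s.bed", cond, safe)))
      si <- match(stg, cfg$stages)
      vals <- study$signal[[cond]][, si]
      bins <- do.call(rbind, lapply(seq_len(nrow(study$regions)), function(i) {
        st <- (study$regions$start[i] %/% 25L) * 25L
        en <- ((study$regions$end[i] + 24L) %/% 25L) * 25L
        bs <- seq(st, en - 25L, by = 25L)
        # log2 signals below 0 have no raw-scale counterpart; clamp at 0
        raw <- max(0, (2^vals[i] - 1) * library_size / 1e6)
        data.frame(chrom = study$regions$chrom[i], start = bs, end = bs + 25L,
                   value = raw, stringsAsFactors = FALSE)
      }))
      write_bedgraph(signal_track(bins, library_size),
                     file.path(dir, sprintf("signal_%s_%s.bedgraph", cond, safe)))
    }
  }
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_gene_annotation(study$annotation, file.path(dir, "annotation.tsv"))
  writeLines(sprintf("%s\t%d", names(study$chrom_sizes), study$chrom_sizes),
             file.path(dir, "chrom.sizes"))
  writeLines(study$factor_list, file.path(dir, "factor_list.txt"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  for (iso in names(study$binding$candidates)) {
    cand <- study$binding$candidates[[iso]]
    cand$name <- sprintf("%s_cand%04d", iso, seq_len(nrow(cand)))
    cand$score <- study$binding$values[[iso]]
    write_bed(cand, file.path(dir, sprintf("binding_candidates_%s.bed", iso)))
  }
  jsonlite::write_json(study$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", na = "null", digits = NA)
  invisible(dir)
}
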