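stages7 <- c("hiF-T", "d6", "d8", "d14", "d20", "d24", "iPSC")

# a tiny deterministic expression table: n genes, all conditions/stages, 2 reps
toy_expr <- function(fpkm_by_stage, n = 1, conditions = "naive", reps = 2) {
  cols <- character(0)
  for (cond in conditions) for (s in stages7) for (r in seq_len(reps))
    cols <- c(cols, paste(cond, s, paste0("r", r), sep = "."))
  m <- matrix(0, n, length(cols), dimnames = list(sprintf("g%03d", seq_len(n)), cols))
  for (cond in conditions) for (si in seq_along(stages7)) for (r in seq_len(reps)) {
    cn <- paste(cond, stages7[si], paste0("r", r), sep = ".")
    m[, cn] <- fpkm_by_stage[, si]
  }
  map <- data.frame(replicate = cols,
                    condition = vapply(strsplit(cols, ".", fixed = TRUE), `[[`, "", 1),
                    stage = vapply(strsplit(cols, ".", fixed = TRUE), `[[`, "", 2),
                    stringsAsFactors = FALSE)
  expression_table(m, map)
}

test_that("class_expression_stats matches the Mann-Whitney oracle", {
  n <- 50
  set.seed(41)
  base <- matrix(rep(runif(n, 5, 50), 7), n)
  expr <- toy_expr(base, n = n)
  links <- data.frame(region_idx = 1:n, gene_id = sprintf("g%03d", 1:n),
                      distance = 0L, stringsAsFactors = FALSE)
  traj <- data.frame(region_id = sprintf("R%05d", 1:n), class = "PO",
                     stringsAsFactors = FALSE)
  st <- class_expression_stats(links, traj, expr, "naive", stages7)
  # stage values identical to baseline: p ~ 1, median ratio 1
  expect_true(all(st$p_vs_baseline[st$stage != "hiF-T"] > 0.9))
  expect_equal(st$median_log2_fpkm[st$stage == "iPSC"],
               st$median_log2_fpkm[st$stage == "hiF-T"])

  # a +10 FPKM shift at n=50 is decisively significant, and the p-value
  # equals wilcox.test on the same pooled per-gene stage means
  shifted <- base; shifted[, 7] <- base[, 7] + 10
  expr2 <- toy_expr(shifted, n = n)
  st2 <- class_expression_stats(links, traj, expr2, "naive", stages7)
  p_ipsc <- st2$p_vs_baseline[st2$stage == "iPSC"]
  expect_lt(p_ipsc, 0.001)
  oracle <- suppressWarnings(stats::wilcox.test(shifted[, 7], shifted[, 1],
                                                exact = FALSE, correct = FALSE)$p.value)
  expect_equal(p_ipsc, oracle)
  expect_warning(
    class_expression_stats(links[0, ], traj, expr, "naive", stages7),
    "no linked genes")
})

test_that("directional class expression trends follow accessibility coupling", {
  study <- generate_study(quick_config(seed = 8L, coupling = 1.5))
  stg <- study$config$stages
  thr <- calibrate_threshold(study$pseudo_values)
  traj <- classify_trajectories(binarize(study$signal$naive, thr), stg)
  links <- nearest_tss(study$regions, study$annotation)
  st <- class_expression_stats(links, traj, study$expr, "naive", stg)
  co <- st[st$class == "CO", ]
  expect_gt(co$median_log2_fpkm[co$stage == "iPSC"],
            co$median_log2_fpkm[co$stage == "hiF-T"])
  oc <- st[st$class == "OC", ]
  expect_lt(oc$median_log2_fpkm[oc$stage == "iPSC"],
            oc$median_log2_fpkm[oc$stage == "hiF-T"])
})

test_that("upregulated_genes enforces all three criteria at every stage", {
  # constant high expression: fold = 1 -> excluded
  flat <- matrix(rep(100, 7), 1)
  expect_length(upregulated_genes(toy_expr(flat), "naive", stages7), 0)
  # fold 6 everywhere but FPKM 3 at one stage -> excluded
  low_mid <- matrix(c(0.5, 6, 6, 3, 6, 6, 6), 1)
  expect_length(upregulated_genes(toy_expr(low_mid), "naive", stages7), 0)
  # planted forced-upregulated genes are all recovered
  study <- generate_study(quick_config())
  up <- upregulated_genes(study$expr, "naive", study$config$stages)
  gt <- study$ground_truth$genes
  expect_true(all(gt$gene_id[gt$forced_upregulated] %in% up))
  # single-replicate table: p-criterion skipped with a warning
  one_rep <- toy_expr(matrix(c(1, rep(40, 6)), 1), reps = 1)
  expect_warning(up1 <- upregulated_genes(one_rep, "naive", stages7),
                 "p-value criterion skipped")
  expect_length(up1, 1)
})

test_that("differential_genes recovers a planted shift and controls BH order", {
  set.seed(42)
  n <- 1000
  fpkm <- matrix(2^rnorm(n * 6, 3, 0.5), n, 6,
                 dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:6)))
  # identical groups: empty DE set
  de0 <- differential_genes(cbind(fpkm[, 1:3], fpkm[, 1:3]),
                            group_a = 1:3, group_b = 4:6)
  expect_equal(sum(de0$de), 0)
  # one gene shifted 8-fold with tiny variance among nulls
  fpkm["g0001", 1:3] <- 2^rnorm(3, 2, 0.01)
  fpkm["g0001", 4:6] <- 2^rnorm(3, 5, 0.01)
  de <- differential_genes(fpkm, group_a = 1:3, group_b = 4:6)
  expect_equal(de$gene_id[de$de], "g0001")
  # BH preserves the p-value order
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-12))
  # zero variance with equal means -> p = 1
  degen <- matrix(5, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  expect_equal(differential_genes(degen, 1:3, 4:6)$p, c(1, 1))
})

test_that("candidate_funnel is a pure intersection with a strict 10-kb boundary", {
  ann <- data.frame(gene_id = c("gNear", "gEdge"), chrom = "c", strand = "+",
                    tss = c(5000L, 30001L), start = c(5000L, 30001L),
                    end = c(7000L, 32001L), stringsAsFactors = FALSE)
  regions <- data.frame(chrom = "c", start = 10000L, end = 20000L,
                        switch_stage = "d8", stringsAsFactors = FALSE)
  # gEdge sits 10,001 bp past the region end: linked set excludes it
  fn <- candidate_funnel(regions, ann, upregulated = c("gNear", "gEdge"),
                         factor_list = c("gNear", "gEdge"))
  expect_equal(fn$candidates$gene_id, "gNear")
  expect_equal(fn$counts[["n_linked"]], 1)
  # factor list disjoint from the annotation -> empty
  fn2 <- candidate_funnel(regions, ann, upregulated = "gNear", factor_list = "zzz")
  expect_equal(nrow(fn2$candidates), 0)
  # funnel counts are monotone non-increasing
  expect_true(all(diff(unname(fn$counts)) <= 0))
})

test_that("the planted funnel design is recovered exactly", {
  study <- generate_study(quick_config())
  stg <- study$config$stages
  thr <- calibrate_threshold(study$pseudo_values)
  traj <- classify_trajectories(binarize(study$signal$naive, thr), stg)
  up <- upregulated_genes(study$expr, "naive", stg)
  co <- which(traj$class == "CO")
  regions <- study$regions[co, c("chrom", "start", "end")]
  regions$switch_stage <- traj$switch_stage[co]
  fn <- candidate_funnel(regions, study$annotation, up, study$factor_list)
  gt <- study$ground_truth$genes
  expect_equal(fn$candidates$gene_id, sort(gt$gene_id[gt$role == "factor"]))
})

test_that("group_patterns distinguishes the four expression archetypes", {
  m <- rbind(c(1, 2, 4, 8, 16, 32, 64),   # progressive-up
             rep(20, 7),                  # constant
             c(1, 1, 1, 1, 1, 30, 40),    # late-surge
             c(1, 1.2, 0.9, 1, 1.1, 1, 1.05))  # low-stable
  expr <- toy_expr(m, n = 4)
  got <- group_patterns(sprintf("g%03d", 1:4), expr, "naive", stages7)
  expect_equal(got$group, c(1L, 2L, 3L, 4L))
})
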