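stages7 <- c("hiF-T", "d6", "d8", "d14", "d20", "d24", "iPSC")

test_that("binarize is strict at the threshold", {
  thr <- fixed_threshold(4.2)
  m <- matrix(c(4.2, 4.2000001, 0, 10), 2, 2)
  expect_equal(binarize(m, thr), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_true(all(binarize(matrix(5, 3, 3), thr)))
  set.seed(31)
  x <- matrix(rnorm(100, 4.2, 1), 10, 10)
  expect_equal(binarize(x, thr), x > 4.2)
  expect_error(binarize(matrix(c(1, NA), 1, 2), thr), "non-finite")
})

test_that("classify_trajectories matches the definitions and the truth-table oracle", {
  mk <- function(...) matrix(as.logical(c(...)), nrow = 1)
  expect_equal(classify_trajectories(mk(1, 1, 1, 1, 1, 1, 1), stages7)$class, "PO")
  co <- classify_trajectories(mk(0, 0, 1, 1, 1, 1, 1), stages7)
  expect_equal(co$class, "CO")
  expect_equal(co$switch_stage, "d8")
  oc <- classify_trajectories(mk(1, 1, 1, 0, 0, 0, 0), stages7)
  expect_equal(oc$class, "OC")
  expect_equal(oc$switch_stage, "d14")
  expect_equal(classify_trajectories(mk(1, 0, 1, 1, 1, 1, 1), stages7)$class, "TRANSIENT")
  expect_equal(classify_trajectories(mk(0, 0, 0, 0, 0, 0, 0), stages7)$class, "NEVER")

  # exhaustive 2^7 truth table
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 7)))
  colnames(patterns) <- stages7
  got <- classify_trajectories(patterns, stages7)
  want <- apply(patterns, 1, oracle_classify)
  expect_equal(got$class, unname(want))
  # switch stage defined exactly for CO/OC
  expect_equal(is.na(got$switch_stage), !got$class %in% c("CO", "OC"))
})

test_that("stage_counts are cumulative by switch stage", {
  calls <- matrix(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE), 1)
  tr <- classify_trajectories(calls, stages7)
  sc <- stage_counts(tr, stages7)
  expect_equal(sc$CO, c(0L, 0L, 0L, 1L, 1L, 1L, 1L))
  all_po <- classify_trajectories(matrix(TRUE, 5, 7), stages7)
  sc2 <- stage_counts(all_po, stages7)
  expect_equal(sc2$PO, rep(5L, 7))
  expect_equal(sc2$CO, rep(0L, 7))

  # synthetic world: counts equal cumulative tallies of the planted truth
  study <- generate_study(quick_config())
  thr <- calibrate_threshold(study$pseudo_values)
  tr3 <- classify_trajectories(binarize(study$signal$naive, thr), stages7)
  sc3 <- stage_counts(tr3, stages7)
  for (s in seq_along(stages7)) {
    expect_equal(sc3$CO[s], sum(tr3$class == "CO" & tr3$switch_idx <= s, na.rm = TRUE))
  }
  expect_true(all(diff(sc3$CO) >= 0) && all(diff(sc3$OC) >= 0))
})

test_that("co_occurrence tallies joint switch stages", {
  one <- classify_trajectories(matrix(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE), 1,
                                      dimnames = list("r1", NULL)), stages7)
  m <- co_occurrence(one, one, "CO", stages7)
  expect_equal(sum(m), 1)
  expect_equal(m["d8", "d8"], 1L)
  # disjoint class memberships give an empty matrix
  other <- classify_trajectories(matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 1,
                                        dimnames = list("r1", NULL)), stages7)
  expect_equal(sum(co_occurrence(one, other, "CO", stages7)), 0)

  # planted joint histogram on synthetic data (threshold below every open draw
  # and above every closed draw recovers the planted states exactly)
  study <- generate_study(quick_config())
  gt <- study$ground_truth$regions
  mid <- (study$config$open_mean + study$config$closed_mean) / 2
  tn <- classify_trajectories(study$signal$naive > mid, stages7)
  tp <- classify_trajectories(study$signal$primed > mid, stages7)
  mm <- co_occurrence(tn, tp, "CO", stages7)
  both <- gt$class == "CO" & tn$class == "CO" & tp$class == "CO"
  planted <- table(factor(gt$switch_idx_naive[both], levels = 1:7),
                   factor(gt$switch_idx_primed[both], levels = 1:7))
  expect_equal(as.vector(mm), as.vector(planted))
  expect_equal(sum(mm), sum(both))
})

test_that("class conservation holds for arbitrary call matrices", {
  set.seed(32)
  calls <- matrix(runif(400 * 7) > 0.5, 400, 7)
  tr <- classify_trajectories(calls, stages7)
  expect_equal(sum(table(tr$class)), 400)
  expect_setequal(unique(tr$class),
                  intersect(c("PO", "CO", "OC", "NEVER", "TRANSIENT"), tr$class))
})

test_that("fuzzy memberships are a proper partition and c=1 is degenerate", {
  set.seed(33)
  x <- matrix(rnorm(60 * 7), 60, 7, dimnames = list(sprintf("r%02d", 1:60), stages7))
  cl <- cluster_transient(list(naive = x), c = 4, seed = 2)
  expect_equal(unname(rowSums(cl$membership)), rep(1, 60), tolerance = 1e-9)
  expect_true(all(cl$membership >= 0 & cl$membership <= 1))
  cl1 <- cluster_transient(list(naive = x), c = 1, seed = 2)
  expect_true(all(cl1$membership == 1))
  expect_error(cluster_transient(list(naive = x[1:3, ]), c = 10), "fewer regions")
  # determinism under a fixed seed
  cl2 <- cluster_transient(list(naive = x), c = 4, seed = 2)
  expect_identical(cl$membership, cl2$membership)
})

test_that("fuzzy clustering separates two planted shapes", {
  set.seed(34)
  n <- 100
  up <- seq(-1.2, 1.2, length.out = 7)
  bump <- c(-1, 0.2, 1.4, 1.4, 0.2, -1, -1.2)
  truth <- rep(1:2, each = n)
  x <- rbind(matrix(rep(up, n), n, byrow = TRUE),
             matrix(rep(bump, n), n, byrow = TRUE)) + rnorm(2 * n * 7, 0, 0.3)
  rownames(x) <- sprintf("r%03d", seq_len(2 * n))
  cl <- cluster_transient(list(naive = x), c = 2, seed = 5)
  expect_gte(adjusted_rand_index(cl$hard, truth), 0.95)
})

test_that("cluster categories follow the shape rules", {
  mk_clusters <- function(naive, primed) {
    structure(list(membership = diag(nrow(naive)), hard = seq_len(nrow(naive)),
                   centers = list(naive = naive, primed = primed),
                   c = nrow(naive), m = 2, iterations = 1L, converged = TRUE,
                   region_ids = NULL),
              class = "fuzzy_clusters")
  }
  rise <- seq(0, 1.5, length.out = 7)
  flat <- rep(0, 7)
  peak <- c(0, 0.2, 1.2, 0.3, 0.1, 0, 0)
  fall <- seq(0.5, -1.5, length.out = 7)
  cats <- categorize_clusters(mk_clusters(rbind(rise, peak, rise, fall),
                                          rbind(rise, flat, flat, fall)))
  expect_equal(cats$category,
               c("shared up", "naive transient", "naive up", "shared loss"))
})
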