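#' Binarize a signal matrix into open/closed calls
#'
#' A region is called open at a stage when its signal strictly exceeds the
#' threshold; a value exactly at the threshold is closed ("above" is strict).
#'
#' @param mat numeric matrix, regions x stages, in the same log base and
#'   units the threshold was calibrated in.
#' @param threshold `open_threshold` object (or a bare number).
#' @return logical matrix of the same shape (`TRUE` = open).
#' @export
binarize <- function(mat, threshold) {
  thr <- if (inherits(threshold, "open_threshold")) threshold$value else threshold
  stopifnot(is.numeric(thr), length(thr) == 1, is.finite(thr))
  if (!all(is.finite(mat))) stop("signal matrix contains non-finite values")
  mat > thr
}

#' Classify per-region temporal trajectories
#'
#' Given ordered per-stage open/closed calls, each region is assigned one of
#' five classes: `PO` (open at every stage), `NEVER` (closed at every stage),
#' `CO` (a single closed-to-open switch, open thereafter), `OC` (the
#' converse), or `TRANSIENT` (any trajectory with more than one switch).
#' `switch_stage` is the first stage in the new state, defined only for
#' CO/OC.
#'
#' @param calls logical matrix, regions x stages (>= 3 stages), columns in
#'   time order; rownames used as region ids if present.
#' @param stages stage labels (default: column names).
#' @return `data.frame` with `region_id`, `class`, `switch_stage`.
#' @export
classify_trajectories <- function(calls, stages = colnames(calls)) {
  calls <- as.matrix(calls)
  stopifnot(is.logical(calls), ncol(calls) >= 3)
  if (is.null(stages)) stages <- paste0("s", seq_len(ncol(calls)))
  n <- nrow(calls); s <- ncol(calls)
  d <- calls[, -1, drop = FALSE] - calls[, -s, drop = FALSE]
  n01 <- rowSums(d == 1)   # closed -> open transitions
  n10 <- rowSums(d == -1)  # open -> closed
  open_n <- rowSums(calls)
  cls <- rep("TRANSIENT", n)
  cls[open_n == s] <- "PO"
  cls[open_n == 0] <- "NEVER"
  cls[n01 == 1 & n10 == 0] <- "CO"
  cls[n10 == 1 & n01 == 0] <- "OC"
  switch_idx <- rep(NA_integer_, n)
  co <- which(cls == "CO"); oc <- which(cls == "OC")
  if (length(co) > 0)
    switch_idx[co] <- apply(d[co, , drop = FALSE], 1, function(z) which(z == 1)) + 1L
  if (length(oc) > 0)
    switch_idx[oc] <- apply(d[oc, , drop = FALSE], 1, function(z) which(z == -1)) + 1L
  ids <- rownames(calls)
  if (is.null(ids)) ids <- sprintf("R%05d", seq_len(n))
  data.frame(region_id = ids, class = cls,
             switch_stage = ifelse(is.na(switch_idx), NA_character_, stages[switch_idx]),
             switch_idx = switch_idx, stringsAsFactors = FALSE)
}

#' Count PO/CO/OC regions at each stage
#'
#' The PO count is constant across stages; CO (OC) counts are cumulative:
#' a CO region is counted at every stage at or after its switch stage, so
#' counts increase monotonically through the course.
#'
#' @param traj classification `data.frame` from [classify_trajectories()].
#' @param stages ordered stage labels.
#' @return `data.frame` with `stage`, `PO`, `CO`, `OC`.
#' @export
stage_counts <- function(traj, stages) {
  po <- sum(traj$class == "PO")
  out <- data.frame(stage = stages, PO = po, CO = 0L, OC = 0L,
                    stringsAsFactors = FALSE)
  for (s in seq_along(stages)) {
    out$CO[s] <- sum(traj$class == "CO" & traj$switch_idx <= s, na.rm = TRUE)
    out$OC[s] <- sum(traj$class == "OC" & traj$switch_idx <= s, na.rm = TRUE)
  }
  out
}

#' Cross-condition switch-time co-occurrence matrix
#'
#' For regions carrying the same class (CO or OC) in both conditions, tallies
#' the joint distribution of switch stages: entry (i, j) counts regions that
#' switch at stage i in the first condition and stage j in the second. The
#' matrix total equals the number of shared-class regions with a defined
#' switch stage in both conditions; regions lacking one are dropped and their
#' count reported via the `"excluded"` attribute.
#'
#' @param traj_a,traj_b classification `data.frame`s for the two conditions,
#'   matched on `region_id`.
#' @param class `"CO"` or `"OC"`.
#' @param stages ordered stage labels.
#' @return integer matrix stages x stages with an `excluded` attribute.
#' @export
co_occurrence <- function(traj_a, traj_b, class = c("CO", "OC"), stages) {
  class <- match.arg(class)
  shared <- intersect(traj_a$region_id[traj_a$class == class],
                      traj_b$region_id[traj_b$class == class])
  a <- traj_a[match(shared, traj_a$region_id), ]
  b <- traj_b[match(shared, traj_b$region_id), ]
  ok <- !is.na(a$switch_idx) & !is.na(b$switch_idx)
  m <- matrix(0L, length(stages), length(stages), dimnames = list(stages, stages))
  for (i in which(ok)) {
    m[a$switch_idx[i], b$switch_idx[i]] <- m[a$switch_idx[i], b$switch_idx[i]] + 1L
  }
  attr(m, "excluded") <- sum(!ok)
  m
}
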