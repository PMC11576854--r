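# Fuzzy c-means (Bezdek): standard alternating update of memberships and
# centroids under squared Euclidean distance. Implemented here because no
# fuzzy-clustering package ships with the target environment.
fcm <- function(x, c, m = 2, seed = 1, tol = 1e-6, max_iter = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(c >= 1, n >= c, m > 1)
  if (c == 1) {
    u <- matrix(1, n, 1)
    return(list(membership = u, centers = matrix(colMeans(x), 1),
                iterations = 0L, converged = TRUE))
  }
  set.seed(seed)
  u <- matrix(stats::runif(n * c), n, c)
  u <- u / rowSums(u)
  xsq <- rowSums(x^2)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    d2 <- outer(xsq, rowSums(centers^2), "+") - 2 * x %*% t(centers)
    d2[d2 < 1e-300] <- 1e-300
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    # exact hits on a centroid get full membership there
    zero <- which(d2 <= 1e-300, arr.ind = TRUE)
    if (nrow(zero) > 0) {
      for (r in unique(zero[, 1])) {
        u_new[r, ] <- 0
        u_new[r, zero[zero[, 1] == r, 2][1]] <- 1
      }
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  um <- u^m
  centers <- (t(um) %*% x) / colSums(um)
  list(membership = u, centers = centers, iterations = iter, converged = converged)
}

#' Cluster transient-region trajectories with fuzzy c-means
#'
#' Transient regions (more than one open/closed switch) are soft-clustered on
#' their temporal signal shapes, in the spirit of Mfuzz: each region's
#' per-condition signal series is z-standardized (so shape, not level, drives
#' the clustering), the standardized series of all conditions are
#' concatenated, and fuzzy c-means with fuzzifier `m` is run on the result.
#'
#' @param signal_list named list (one element per condition) of numeric
#'   matrices, regions x stages, all with identical rows.
#' @param c number of clusters (default 10).
#' @param m fuzzifier (> 1; default 2).
#' @param seed integer seed (initial memberships are random).
#' @param tol,max_iter convergence control.
#' @return object of class `fuzzy_clusters`: `membership` (rows sum to 1),
#'   `hard` (argmax cluster per region), `centers` (per condition, cluster
#'   mean trajectories in z units), `c`, `m`, `iterations`, `converged`.
#' @export
cluster_transient <- function(signal_list, c = 10L, m = 2, seed = 1,
                              tol = 1e-6, max_iter = 500L) {
  stopifnot(is.list(signal_list), length(signal_list) >= 1)
  n <- nrow(signal_list[[1]])
  if (n < c) stop("fewer regions (", n, ") than clusters (", c, ")")
  zstd <- lapply(signal_list, function(mat) {
    mu <- rowMeans(mat)
    sd <- apply(mat, 1, stats::sd)
    z <- (mat - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0
    z
  })
  x <- do.call(cbind, zstd)
  fit <- fcm(x, c = c, m = m, seed = seed, tol = tol, max_iter = max_iter)
  ncol_per <- vapply(signal_list, ncol, 0L)
  splits <- rep(names(signal_list), ncol_per)
  centers <- lapply(stats::setNames(names(signal_list), names(signal_list)),
                    function(cond) fit$centers[, splits == cond, drop = FALSE])
  structure(list(membership = fit$membership,
                 hard = max.col(fit$membership, ties.method = "first"),
                 centers = centers, c = c, m = m,
                 iterations = fit$iterations, converged = fit$converged,
                 region_ids = rownames(signal_list[[1]])),
            class = "fuzzy_clusters")
}

#' @export
print.fuzzy_clusters <- function(x, ...) {
  cat(sprintf("fuzzy_clusters: %d regions, c = %d, m = %.2g, %d iteration(s)%s\n",
              nrow(x$membership), x$c, x$m, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

label_center <- function(z, up_z, rho_min, margin, flat_span) {
  idx <- seq_along(z)
  rho <- suppressWarnings(stats::cor(z, idx, method = "spearman"))
  if (is.na(rho)) rho <- 0
  span <- max(z) - min(z)
  interior <- if (length(z) > 2) max(z[-c(1, length(z))]) else -Inf
  if (z[length(z)] >= up_z && rho >= rho_min) return("up")
  if (z[length(z)] <= -up_z && rho <= -rho_min) return("loss")
  if (interior >= z[1] + margin && interior >= z[length(z)] + margin) return("transient")
  if (span < flat_span) return("flat")
  "none"
}

#' Categorize fuzzy clusters by cross-condition trajectory shape
#'
#' Each cluster's mean z-trajectory is labelled per condition as `up`
#' (final-stage z at least `up_z` with a positive monotone trend), `loss`
#' (the mirrored rule), `transient` (an interior maximum exceeding both
#' endpoints by `margin`), or `flat` (total z span below `flat_span`).
#' Clusters labelled the same way in both conditions become `shared <label>`;
#' a label in one condition with a flat profile in the other becomes
#' `<condition> <label>`; anything else is `unclassified`.
#'
#' @param clusters `fuzzy_clusters` with exactly two conditions.
#' @param up_z,rho_min,margin,flat_span shape thresholds (z units /
#'   Spearman rho); defaults 0.5, 0.6, 0.5, 0.5.
#' @return `data.frame` with `cluster`, per-condition labels, `category`.
#' @export
categorize_clusters <- function(clusters, up_z = 0.5, rho_min = 0.6,
                                margin = 0.5, flat_span = 0.5) {
  stopifnot(inherits(clusters, "fuzzy_clusters"), length(clusters$centers) == 2)
  conds <- names(clusters$centers)
  labs <- sapply(conds, function(cond) {
    apply(clusters$centers[[cond]], 1, label_center,
          up_z = up_z, rho_min = rho_min, margin = margin, flat_span = flat_span)
  })
  labs <- matrix(labs, ncol = 2, dimnames = list(NULL, conds))
  category <- vapply(seq_len(clusters$c), function(k) {
    a <- labs[k, 1]; b <- labs[k, 2]
    if (a == b && a %in% c("up", "loss", "transient")) return(paste("shared", a))
    if (a %in% c("up", "loss", "transient") && b == "flat")
      return(paste(conds[1], a))
    if (b %in% c("up", "loss", "transient") && a == "flat")
      return(paste(conds[2], b))
    "unclassified"
  }, "")
  out <- data.frame(cluster = seq_len(clusters$c), stringsAsFactors = FALSE)
  out[[paste0("label_", conds[1])]] <- labs[, 1]
  out[[paste0("label_", conds[2])]] <- labs[, 2]
  out$category <- category
  out
}
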