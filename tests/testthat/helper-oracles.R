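# Independent brute-force oracles used to pin down interval-algebra and
# classification semantics. Deliberately naive implementations: graph
# closure for merging, pairwise scans for overlap/nearest, literal pattern
# matching for trajectory classes.

oracle_merge <- function(df, gap) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- NULL
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    n <- nrow(d)
    # adjacency: separation (start_j - end_i) <= gap in either direction
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- d$start[j] - d$end[i] <= gap && d$start[i] - d$end[j] <= gap
    }
    comp <- rep(0L, n); cur <- 0L
    for (i in seq_len(n)) {
      if (comp[i] > 0) next
      cur <- cur + 1L
      queue <- i
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] > 0) next
        comp[v] <- cur
        queue <- c(queue, which(adj[v, ] & comp == 0))
      }
    }
    for (k in seq_len(cur)) {
      idx <- which(comp == k)
      out <- rbind(out, data.frame(chrom = ch, start = min(d$start[idx]),
                                   end = max(d$end[idx]), stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_overlap_count <- function(a, b, minov = 1) {
  hit <- function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >= minov)
  }
  sum(vapply(seq_len(nrow(a)), hit, TRUE))
}

oracle_nearest <- function(regions, ann, maxd) {
  out <- NULL
  for (i in seq_len(nrow(regions))) {
    best_d <- Inf; best_g <- NA_character_
    for (g in seq_len(nrow(ann))) {
      if (ann$chrom[g] != regions$chrom[i]) next
      tss <- ann$tss[g]
      d <- if (tss >= regions$start[i] && tss < regions$end[i]) 0L else
        min(abs(regions$start[i] - tss), abs(tss - (regions$end[i] - 1L)))
      if (d < best_d || (d == best_d && ann$gene_id[g] < best_g)) {
        best_d <- d; best_g <- ann$gene_id[g]
      }
    }
    if (is.finite(best_d) && best_d <= maxd) {
      out <- rbind(out, data.frame(region_idx = i, gene_id = best_g,
                                   distance = best_d, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(region_idx = integer(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  }
  out
}

# literal pattern definitions: CO = closed prefix then open suffix, etc.
oracle_classify <- function(calls) {
  s <- length(calls)
  if (all(calls)) return("PO")
  if (!any(calls)) return("NEVER")
  for (k in 2:s) {
    if (all(!calls[1:(k - 1)]) && all(calls[k:s])) return("CO")
    if (all(calls[1:(k - 1)]) && all(!calls[k:s])) return("OC")
  }
  "TRANSIENT"
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

random_intervals <- function(n, max_coord = 50000, max_len = 400,
                             chroms = c("chrA", "chrB")) {
  start <- sample.int(max_coord, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# a small, quick study used by non-acceptance tests; ... overrides defaults
quick_config <- function(seed = 7L, ...) {
  args <- list(n_per_class = c(PO = 30, CO = 30, OC = 30, NEVER = 30, TRANSIENT = 30),
               n_pseudo = 500L, n_extra_genes = 20L,
               n_factor_genes = 5L, n_decoys_no_factor = 5L,
               n_decoys_not_up = 5L, n_decoys_far = 5L,
               n_targets = c(alpha = 40L, beta = 20L), shared_sites = 4L,
               n_low_fpkm = c(alpha = 4L, beta = 2L), n_site_decoys = 10L,
               seed = seed)
  do.call(study_config, utils::modifyList(args, list(...)))
}
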