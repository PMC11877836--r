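# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths of the implementation (choose()-based enumeration
# instead of dhyper, quadratic scans instead of interval trees).

# two-sided Fisher's exact p by direct enumeration of the hypergeometric
# support with binomial-coefficient probabilities
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || k1 == 0 || k1 == n) return(1)
  supp <- max(0, k1 - r2):min(r1, k1)
  logp <- lchoose(r1, supp) + lchoose(r2, k1 - supp) - lchoose(n, k1)
  p <- exp(logp)
  p_obs <- p[supp == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up by definition: q_(i) = min_{j >= i} p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# quadratic interval merge: connected components under gap <= merge_gap
oracle_merge <- function(windows, merge_gap) {
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    w <- w[order(w$start), ]
    n <- nrow(w)
    comp <- seq_len(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        gap <- max(w$start[j] - w$end[i], w$start[i] - w$end[j], 0)
        if (gap <= merge_gap) {
          ci <- comp[i]; cj <- comp[j]
          comp[comp == cj] <- ci
        }
      }
    }
    for (cc in unique(comp)) {
      m <- w[comp == cc, ]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = min(m$start), end = max(m$end))
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# edge-to-edge distance of two half-open intervals (0 if they share a base
# or are adjacent)
oracle_distance <- function(s1, e1, s2, e2) {
  max(s2 - e1, s1 - e2, 0)
}

oracle_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# per-interval brute-force pooled counts
oracle_quantify <- function(methylome, intervals, contexts = c("CG", "CHG", "CHH")) {
  purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    m <- methylome[methylome$chrom == iv$chrom &
                     methylome$pos - 1 >= iv$start &
                     methylome$pos - 1 < iv$end, ]
    purrr::map_dfr(contexts, function(ctx) {
      mc <- m[m$context == ctx, ]
      tibble::tibble(row = i, context = ctx, n_sites = nrow(mc),
                     count_methylated = sum(mc$count_methylated),
                     count_total = sum(mc$count_total))
    })
  })
}
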