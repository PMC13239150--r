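# Independent brute-force oracles. Deliberately coded without reusing the
# package's routines (or the stats shortcuts they call) so that agreement is
# a genuine cross-check.

# Greedy clumping, restated from scratch over plain data structures.
# cand: data.frame(snp_id, chrom, pos, n_hits, max_abs_z); ld_pairs:
# data.frame(snp_a, snp_b, r2). Returns the selected snp_ids (any order).
oracle_clump <- function(cand, ld_pairs, window_bp, r2_max) {
  remaining <- cand
  selected <- character(0)
  lookup_r2 <- function(x, y) {
    hit <- (ld_pairs$snp_a == x & ld_pairs$snp_b == y) |
      (ld_pairs$snp_a == y & ld_pairs$snp_b == x)
    if (any(hit)) ld_pairs$r2[which(hit)[1]] else 0
  }
  while (nrow(remaining) > 0) {
    ord <- order(-remaining$n_hits, -remaining$max_abs_z, remaining$snp_id)
    top <- remaining[ord[1], ]
    selected <- c(selected, top$snp_id)
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      row <- remaining[i, ]
      if (row$snp_id == top$snp_id) {
        drop[i] <- TRUE
      } else if (row$chrom == top$chrom &&
                 abs(row$pos - top$pos) <= window_bp &&
                 lookup_r2(row$snp_id, top$snp_id) > r2_max) {
        drop[i] <- TRUE
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  selected
}

# Upper-tail hypergeometric probability P[X >= k] from factorial identities.
oracle_hyper_tail <- function(k, n_set, n_background, n_query) {
  js <- seq(from = k, to = min(n_set, n_query))
  if (k > min(n_set, n_query)) return(0)
  total <- choose(n_background, n_query)
  sum(choose(n_set, js) * choose(n_background - n_set, n_query - js)) / total
}

# Benjamini-Hochberg step-up, restated directly: sort, p * m / rank,
# cumulative minimum from the bottom, clamp at 1, unsort.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    adj_sorted[i] <- min(adj_sorted[i], adj_sorted[i + 1])
  }
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Fixed-effect inverse-variance meta of k cohorts' (beta, se) vectors.
oracle_ivw <- function(betas, ses) {
  w <- lapply(ses, function(s) 1 / s^2)
  w_sum <- Reduce(`+`, w)
  num <- Reduce(`+`, Map(function(wi, bi) wi * bi, w, betas))
  list(beta = num / w_sum, se = 1 / sqrt(w_sum))
}
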