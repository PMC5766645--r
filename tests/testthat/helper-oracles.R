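# Independent oracles: deliberately naive implementations used only to
# check the production path.

# exhaustive double-loop contact finder over all residue pairs
brute_contacts <- function(model, threshold = 3.3) {
  res <- complex_residues(model)
  trna_chain <- model$trna_chains[1]
  rib <- res[res$chain == trna_chain & res$kind == "ribonucleotide", ]
  aa <- res[res$chain %in% model$protein_chains & res$kind == "amino_acid", ]
  out <- list()
  for (i in seq_len(nrow(rib))) {
    xi <- model$atoms[model$atoms$chain == rib$chain[i] &
                        model$atoms$seq_id == rib$seq_id[i] &
                        model$atoms$kind == "ribonucleotide", ]
    for (j in seq_len(nrow(aa))) {
      yj <- model$atoms[model$atoms$chain == aa$chain[j] &
                          model$atoms$seq_id == aa$seq_id[j] &
                          model$atoms$kind == "amino_acid", ]
      dmin <- Inf
      for (k in seq_len(nrow(xi))) {
        d <- sqrt((xi$x[k] - yj$x)^2 + (xi$y[k] - yj$y)^2 +
                    (xi$z[k] - yj$z)^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= threshold + 1e-9) {
        out[[length(out) + 1]] <- tibble::tibble(
          rib_seq = rib$seq_id[i], aa_chain = aa$chain[j],
          aa_seq = aa$seq_id[j], distance = dmin)
      }
    }
  }
  empty <- tibble::tibble(rib_seq = integer(), aa_chain = character(),
                          aa_seq = integer(), distance = numeric())
  dplyr::bind_rows(empty, out)
}

# affine-gap global alignment score (Gotoh), gap of length k costs open + k*ext
nw_score <- function(a, b, match = 1, mismatch = -1, open = 4, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a aligned to -)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# pairwise-complete correlation distance, written out longhand
pearson_dist_oracle <- function(X) {
  # X: complexes x regions with NA
  n <- nrow(X)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(X), rownames(X)))
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (sum(ok) < 3) next
    xi <- X[i, ok]; xj <- X[j, ok]
    sx <- sd(xi); sy <- sd(xj)
    if (sx == 0 || sy == 0) next
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) / ((sum(ok) - 1) * sx * sy)
    d[i, j] <- 1 - r
  }
  d
}

# naive agglomerative complete linkage: returns merge heights and the sets
# merged at each step (sorted label vectors)
complete_linkage_oracle <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  heights <- numeric()
  merged_sets <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
    }
    newc <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_h)
    merged_sets[[length(merged_sets) + 1]] <- newc
    clusters <- c(clusters[-best], list(newc))
  }
  list(heights = heights, sets = merged_sets)
}

# reconstruct the merged set at each hclust step
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    members <- function(k) {
      if (k < 0) hc$labels[-k] else sets[[k]]
    }
    sets[[s]] <- sort(c(members(hc$merge[s, 1]), members(hc$merge[s, 2])))
  }
  sets
}

# asymptotic standard error of the plug-in entropy estimator
entropy_se <- function(p, n) {
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  v <- sum(p * log2(p)^2) - h^2
  sqrt(max(v, 0) / n)
}
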