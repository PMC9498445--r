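# Independent oracles and fixture builders used across the suite.
# Each oracle re-derives the quantity with different machinery than the
# implementation path it checks.

rand_rna <- function(len, au_rich = FALSE) {
  p <- if (au_rich) c(0.35, 0.15, 0.15, 0.35) else rep(0.25, 4)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = p),
        collapse = "")
}

# Textbook Needleman-Wunsch score by explicit DP over the full matrix
# (independent of Biostrings).
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- strsplit(a, "")[[1L]]
  b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- gap * (0:n)
  D[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (a[i] == b[j]) match else mismatch
      D[i + 1L, j + 1L] <- max(D[i, j] + sub,
                               D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
    }
  }
  D[n + 1L, m + 1L]
}

# Literal double-loop evaluation of the Gaussian profile kernel.
gp_kernel_oracle <- function(V, phi_prime = 1) {
  phi <- phi_prime / mean(rowSums(V^2))
  n <- nrow(V)
  K <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-phi * sum((V[i, ] - V[j, ])^2))
    }
  }
  K
}

# Interval-recursion minimum pairing energy: j either unpaired or paired
# with some t; a different decomposition than the package DP.
fold_energy_oracle <- function(seq, min_loop = 3L) {
  s <- strsplit(seq, "")[[1L]]
  e <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1, NA)
  }
  memo <- new.env()
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- best(i, j - 1L)
    for (t in i:(j - min_loop - 1L)) {
      pe <- e(s[t], s[j])
      if (!is.na(pe)) {
        left <- if (t > i) best(i, t - 1L) else 0
        v <- min(v, left + best(t + 1L, j - 1L) + pe)
      }
    }
    memo[[key]] <- v
    v
  }
  best(1L, length(s))
}

# Regex-engine tandem-run scanner: an independent route to SSR counts.
ssr_oracle <- function(seq, min_repeats = 3L, motif_lengths = 2:4) {
  counts <- integer(0)
  for (L in sort(motif_lengths)) {
    pat <- paste0("(.{", L, "})\\1{", min_repeats - 1L, ",}")
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (r in seq_along(m)) {
      run <- substr(seq, m[r], m[r] + lens[r] - 1L)
      motif <- substr(run, 1L, L)
      if (length(unique(strsplit(motif, "")[[1L]])) == 1L) next
      cnt <- nchar(run) %/% L
      counts[motif] <- if (motif %in% names(counts))
        counts[[motif]] + cnt else cnt
    }
  }
  counts
}

# Random symmetric PSD similarity-like matrix with unit diagonal.
random_psd_kernel <- function(n, ids = sprintf("e%02d", seq_len(n))) {
  A <- matrix(runif(n * n), n)
  K <- crossprod(A)
  K <- K / sqrt(outer(diag(K), diag(K)))
  dimnames(K) <- list(ids, ids)
  K
}

# Small handcrafted dataset with planted structure, built in code.
tiny_dataset <- function(n_mirna = 4L, n_site = 6L, positives = NULL,
                         seed = 42L) {
  withr::with_seed(seed, {
    m <- sequence_records(sprintf("m%02d", seq_len(n_mirna)), "miRNA",
                          replicate(n_mirna, rand_rna(22L)))
    s <- sequence_records(sprintf("t%02d", seq_len(n_site)), "target_site",
                          replicate(n_site, rand_rna(40L, au_rich = TRUE)))
    A <- matrix(0, n_mirna, n_site, dimnames = list(m$id, s$id))
    if (is.null(positives)) {
      positives <- cbind(sample.int(n_mirna, 3L, replace = TRUE),
                         sample.int(n_site, 3L, replace = TRUE))
    }
    A[positives] <- 1
    mirna_dataset(m, s, A)
  })
}
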