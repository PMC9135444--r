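# Independent brute-force oracles. These follow the scoring definitions
# literally (plain recursion / direct enumeration) and never call the
# package's dynamic-programming kernels.

WC_PAIRS <- c("AT", "TA", "CG", "GC")
GU_PAIRS <- c("GT", "TG")

oracle_pair_class <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% WC_PAIRS) "wc" else if (p %in% GU_PAIRS) "gu" else "none"
}

# Exhaustive minimal target-site score over all global alignments with at
# most `max_gaps` gaps (depth-first over alignment columns).
oracle_target_score <- function(mirna, site, config = run_config()) {
  mir <- strsplit(mirna, "")[[1]]
  rs <- rev(strsplit(site, "")[[1]])
  n <- length(mir); m <- length(rs)
  zone <- function(i)
    if (i >= config$strict_zone[1] && i <= config$strict_zone[2])
      "strict" else "nonstrict"
  mm <- config$mismatch_penalty; gu <- config$gu_penalty
  best <- Inf
  rec <- function(i, j, g, acc) {
    if (acc >= best) return(invisible())
    if (i > n && j > m) { best <<- acc; return(invisible()) }
    if (i <= n && j <= m) {
      pc <- oracle_pair_class(mir[i], rs[j])
      pen <- if (pc == "wc") 0 else if (pc == "gu") gu[[zone(i)]]
             else mm[[zone(i)]]
      rec(i + 1, j + 1, g, acc + pen)
    }
    if (g < config$max_gaps) {
      if (i <= n) rec(i + 1, j, g + 1, acc + mm[[zone(i)]])
      if (j <= m) rec(i, j + 1, g + 1, acc + mm[[zone(min(i, n))]])
    }
  }
  rec(1L, 1L, 0L, 0)
  best
}

# Exhaustive duplex minimum over all helix / helix-loop-helix structures.
oracle_duplex_energy <- function(a, b, stacks = nn_stack_table(),
                                 loop_open = 3, loop_ext = 0.5,
                                 max_loop = 8) {
  A <- strsplit(a, "")[[1]]
  B <- rev(strsplit(b, "")[[1]])
  n <- length(A); m <- length(B)
  ptype <- function(x, y) {
    i <- match(paste0(x, y), c("AT", "TA", "CG", "GC", "GT", "TG"))
    if (is.na(i)) 0L else i
  }
  P <- matrix(0L, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) P[i, j] <- ptype(A[i], B[j])
  helices <- function(i, j) {   # cumulative energies of helix prefixes
    if (P[i, j] == 0L) return(NULL)
    res <- list(c(i, j, 0))
    e <- 0; ii <- i; jj <- j
    while (ii < n && jj < m && P[ii + 1, jj + 1] > 0L) {
      e <- e + stacks[P[ii, jj], P[ii + 1, jj + 1]]
      ii <- ii + 1; jj <- jj + 1
      res[[length(res) + 1]] <- c(ii, jj, e)
    }
    do.call(rbind, res)
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    h1 <- helices(i, j)
    if (is.null(h1)) next
    for (r in seq_len(nrow(h1))) {
      best <- min(best, h1[r, 3])
      for (ga in 0:max_loop) for (gb in 0:(max_loop - ga)) {
        if (ga == 0 && gb == 0) next
        si <- h1[r, 1] + 1 + ga; sj <- h1[r, 2] + 1 + gb
        if (si > n || sj > m) next
        h2 <- helices(si, sj)
        if (is.null(h2)) next
        best <- min(best, h1[r, 3] + loop_open + loop_ext * (ga + gb) +
                      min(h2[, 3]))
      }
    }
  }
  best
}

# Exhaustive nested base-pair maximum (no memoization).
oracle_nussinov_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (oracle_pair_class(s[i], s[k]) == "none") next
      v <- 1L + rec(i + 1, k - 1) + if (k < j) rec(k + 1, j) else 0L
      if (v > best) best <- v
    }
    best
  }
  if (length(s) == 0) 0L else rec(1L, length(s))
}

# Longest ORF (codons, stop included) by scanning every ATG.
oracle_longest_orf_nt <- function(seq) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (p in seq_len(max(0L, n - 2L))) {
    if (substr(seq, p, p + 2) != "ATG") next
    q <- p; len <- 0L
    while (q + 2 <= n) {
      len <- len + 1L
      if (substr(seq, q, q + 2) %in% stops) break
      q <- q + 3L
    }
    best <- max(best, len)
  }
  best * 3L
}

# Hypergeometric upper tail by direct summation.
oracle_hyper_tail <- function(k, term, bg, fg) {
  x <- k:min(term, fg)
  sum(choose(term, x) * choose(bg - term, fg - x)) / choose(bg, fg)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
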