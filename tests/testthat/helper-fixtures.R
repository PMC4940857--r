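# Shared fixtures: tiny genomes, peak builders and independent brute-force
# oracles used across the suite.

toy_genome <- function(len = c(chr1 = 100000, chr2 = 50000)) genome_model(len)

# Build a peak set from 0-based half-open coordinates (BED convention),
# mirroring how fixtures are written in the tests.
make_peaks <- function(chrom, start0, end0, summit_off = NULL, score = NULL,
                       genome = NULL, ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  summit <- if (is.null(summit_off)) NULL else start0 + summit_off + 1L
  peak_set(gr, summit = summit, score = score, genome = genome, ...)
}

random_peaks <- function(n, genome, width = 50L, seed = 1) {
  withr::with_seed(seed, {
    chrom <- sample(GenomeInfoDb::seqnames(genome), n, replace = TRUE)
    maxs <- GenomeInfoDb::seqlengths(genome)[chrom] - width
    start0 <- vapply(maxs, function(m) sample.int(m, 1), 1L)
    make_peaks(chrom, start0, start0 + width, score = stats::runif(n),
               genome = genome)
  })
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# --- independent oracles -----------------------------------------------------

# Nearest-edge distance by linear scan over every site.
oracle_nearest_distance <- function(pos_chrom, pos, sites) {
  s_chrom <- as.character(GenomeInfoDb::seqnames(sites))
  vapply(seq_along(pos), function(i) {
    j <- which(s_chrom == pos_chrom[i])
    if (!length(j)) return(Inf)
    min(vapply(j, function(k) {
      a <- BiocGenerics::start(sites)[k]; b <- BiocGenerics::end(sites)[k]
      if (pos[i] >= a && pos[i] <= b) 0 else min(abs(pos[i] - a), abs(pos[i] - b))
    }, 0))
  }, 0)
}

# All-pairs interval overlap (1-based closed), >= min_overlap shared bases.
oracle_overlaps_any <- function(a, b, min_overlap = 1L) {
  ac <- as.character(GenomeInfoDb::seqnames(a)); bc <- as.character(GenomeInfoDb::seqnames(b))
  as1 <- BiocGenerics::start(a); ae <- BiocGenerics::end(a)
  bs <- BiocGenerics::start(b); be <- BiocGenerics::end(b)
  vapply(seq_along(a), function(i) {
    any(bc == ac[i] & pmin(ae[i], be) - pmax(as1[i], bs) + 1 >= min_overlap)
  }, TRUE)
}

# Exhaustive both-strand PWM window scan on a character sequence.
oracle_scan <- function(seq, motif, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  v <- strsplit(seq, "")[[1]]
  L <- motif$length
  lo <- motif$log_odds
  score1 <- function(w) {
    if (any(w == "N")) return(-Inf)
    sum(vapply(seq_len(L), function(j) lo[w[j], j], 0))
  }
  hits <- 0L
  for (i in seq_len(length(v) - L + 1)) {
    w <- v[i:(i + L - 1)]
    rc <- rev(unname(comp[w]))
    if (max(score1(w), score1(rc)) >= threshold) hits <- hits + 1L
  }
  hits
}

# Hypergeometric upper tail P(X >= k) by direct log-binomial summation.
oracle_hyper_upper <- function(k, m, n_univ, n_draw) {
  if (k > min(m, n_draw)) return(0)
  kk <- k:min(m, n_draw)
  sum(exp(lchoose(m, kk) + lchoose(n_univ - m, n_draw - kk) -
            lchoose(n_univ, n_draw)))
}

# Two-sided exact rank-sum p by recursive subset enumeration (independent of
# the implementation's combn-based path).
oracle_ranksum_exact <- function(x, y) {
  rk <- rank(c(x, y))
  n1 <- length(x); N <- length(rk)
  mu <- n1 * (N + 1) / 2
  dev <- abs(sum(rk[seq_len(n1)]) - mu)
  count <- 0L; total <- 0L
  rec <- function(idx, left, sum_so_far) {
    if (left == 0) {
      total <<- total + 1L
      if (abs(sum_so_far - mu) >= dev - 1e-9) count <<- count + 1L
      return(invisible())
    }
    if (idx > N) return(invisible())
    if (N - idx + 1 < left) return(invisible())
    rec(idx + 1, left - 1, sum_so_far + rk[idx])
    rec(idx + 1, left, sum_so_far)
  }
  rec(1L, n1, 0)
  count / total
}

# Spearman rho from first principles: average ranks, then Pearson.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# OLS slope/p from explicit normal equations + t distribution.
oracle_ols <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - 2)
  covb <- s2 * solve(t(X) %*% X)
  t <- beta[2] / sqrt(covb[2, 2])
  list(slope = beta[2], p = 2 * stats::pt(-abs(t), length(y) - 2))
}
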