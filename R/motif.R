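BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Accepts a 4 x L matrix of per-position probabilities (columns summing to
#' 1) or raw counts (converted to probabilities with a +0.25 pseudocount per
#' cell). Probabilities are floored at 1e-4 and renormalized so log-odds
#' scores stay finite. Rows must be A, C, G, T.
#'
#' @param mat 4 x L numeric matrix (probabilities or counts), L >= 4.
#' @param name motif name.
#' @param background base background frequencies (default uniform).
#' @return an object of class `pwm` with elements `name`, `prob`,
#'   `background`, `log_odds` (log2(p/bg)), `length`.
#' @export
pwm <- function(mat, name = "motif", background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4) stop("PWM length must be >= 4")
  if (is.null(rownames(mat))) rownames(mat) <- BASES
  mat <- mat[BASES, , drop = FALSE]
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6)) {        # counts -> probabilities
    mat <- sweep(mat + 0.25, 2, cs + 1, "/")
  }
  mat <- pmax(mat, 1e-4)
  mat <- sweep(mat, 2, colSums(mat), "/")
  lo <- log2(mat / background)
  structure(list(name = name, prob = mat, background = background,
                 log_odds = lo, length = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$name, "': length ", x$length, ", max score ",
      round(pwm_max_score(x), 2), " bits\n", sep = "")
  invisible(x)
}

#' Maximum achievable log-odds score of a PWM
#' @param x a [pwm()].
#' @return score in bits.
#' @export
pwm_max_score <- function(x) sum(apply(x$log_odds, 2, max))

#' Consensus sequence of a PWM
#' @param x a [pwm()].
#' @return character consensus (most probable base per position).
#' @export
pwm_consensus <- function(x) paste(BASES[apply(x$prob, 2, which.max)], collapse = "")

#' Read JASPAR-style PWMs from a plain-text file
#'
#' Supports the JASPAR 2016+ format: a `>ID name` header followed by four
#' lines `A [ 1 2 3 ]` ... (brackets optional), in counts or probabilities.
#'
#' @param path file path.
#' @param background background frequencies passed to [pwm()].
#' @return a named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    stop_at <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    block <- lines[(i + 1):stop_at]
    if (length(block) < 4) stop("motif block with < 4 rows at line ", i)
    nm <- trimws(sub("^>", "", lines[i]))
    nm <- strsplit(nm, "\\s+")[[1]]
    nm <- nm[length(nm)]   # prefer the name over the accession
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      if (v[1] %in% BASES) v <- v[-1]
      as.numeric(v)
    })
    mat <- do.call(rbind, rows)
    rownames(mat) <- BASES
    out[[nm]] <- pwm(mat, name = nm, background = background)
  }
  out
}

.encode_seq <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  bad <- !(v %in% c(BASES, "N"))
  if (any(bad))
    stop("invalid sequence character(s): ",
         paste(unique(v[bad]), collapse = ", "))
  v
}

# Score all windows of a character base vector on both strands, returning the
# per-window max score; windows containing N score -Inf.
.window_scores <- function(chars, motif) {
  L <- motif$length
  nwin <- length(chars) - L + 1L
  if (nwin < 1) stop("sequence shorter than motif")
  s <- Biostrings::DNAString(paste(gsub("N", "A", paste(chars, collapse = "")),
                                   collapse = ""))
  lo <- motif$log_odds
  storage.mode(lo) <- "double"
  lo_rc <- lo[4:1, ncol(lo):1, drop = FALSE]  # reverse-complement scoring matrix
  rownames(lo_rc) <- BASES
  fw <- suppressWarnings(Biostrings::PWMscoreStartingAt(lo, s, seq_len(nwin)))
  rv <- suppressWarnings(Biostrings::PWMscoreStartingAt(lo_rc, s, seq_len(nwin)))
  sc <- pmax(fw, rv)
  npos <- which(chars == "N")
  if (length(npos)) {
    mask <- unique(unlist(lapply(npos, function(p)
      max(1L, p - L + 1L):min(nwin, p))))
    sc[mask] <- -Inf
  }
  sc
}

#' Count PWM hits in a sequence
#'
#' Scans every window of the sequence on both strands with log2-odds
#' scoring against the PWM background; a window is a hit when its best
#' strand score reaches `threshold`, and counts once even if both strands
#' pass. Windows containing N never hit. The default threshold is 60% of
#' the motif's maximum achievable score.
#'
#' @param seq DNA string over A/C/G/T/N (character or `DNAString`).
#' @param motif a [pwm()].
#' @param threshold log-odds threshold in bits (default
#'   `0.6 * pwm_max_score(motif)`).
#' @return integer hit count.
#' @export
scan_pwm <- function(seq, motif, threshold = NULL) {
  if (is.null(threshold)) threshold <- 0.6 * pwm_max_score(motif)
  chars <- .encode_seq(as.character(seq))
  sum(.window_scores(chars, motif) >= threshold)
}

# Total hit count across a set of sequences, computed in one scan of the
# N-spaced concatenation (spacer windows contain N and cannot hit).
.scan_total <- function(seqs, motif, threshold) {
  spacer <- strrep("N", motif$length)
  concat <- paste(vapply(seqs, as.character, ""), collapse = spacer)
  chars <- .encode_seq(concat)
  sum(.window_scores(chars, motif) >= threshold)
}

#' Shuffle a sequence preserving base composition
#'
#' Mononucleotide shuffle: a seeded uniformly random permutation of the
#' characters (the base multiset is preserved exactly). The dinucleotide
#' mode additionally preserves the dinucleotide composition via the
#' Altschul-Erickson random Eulerian-walk shuffle, for motifs sensitive to
#' GC/CpG structure.
#'
#' @param seq DNA string (character or `DNAString`).
#' @param seed integer seed; the same seed always yields the same output.
#' @param method `"mono"` (default) or `"di"`.
#' @return shuffled character string.
#' @export
scramble_sequence <- function(seq, seed, method = c("mono", "di")) {
  method <- match.arg(method)
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  if (!length(chars)) stop("empty sequence")
  withr::with_seed(seed, {
    if (method == "mono") {
      paste(sample(chars), collapse = "")
    } else {
      .dinuc_shuffle(chars)
    }
  })
}

# Altschul-Erickson dinucleotide-preserving shuffle on the doublet graph.
.dinuc_shuffle <- function(chars) {
  n <- length(chars)
  if (n < 3) return(paste(chars, collapse = ""))
  first <- chars[1]; last <- chars[n]
  edges <- split(chars[-1], chars[-n])       # outgoing edge multisets
  verts <- names(edges)
  repeat {
    # pick a random candidate last-edge per vertex (except the final vertex)
    last_edge <- vapply(verts, function(v) {
      if (v == last) NA_character_ else sample(edges[[v]], 1)
    }, "")
    # valid iff every chosen last-edge leads (via chosen edges) to `last`
    ok <- TRUE
    for (v in verts[verts != last]) {
      cur <- v; seen <- character(0)
      while (!is.na(cur) && cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- if (cur %in% names(last_edge)) last_edge[[cur]] else NA_character_
        if (!is.na(cur) && !(cur %in% verts)) cur <- NA_character_
      }
      if (is.na(cur) || cur %in% seen) { ok <- FALSE; break }
    }
    if (ok) break
  }
  shuffled <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last) return(sample(e))
    # remove one instance of the chosen last edge, shuffle the rest, append it
    i <- match(last_edge[[v]], e)
    c(sample(e[-i]), last_edge[[v]])
  })
  names(shuffled) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- shuffled[[cur]][used[cur]]
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Motif fold enrichment against a scrambled-sequence null
#'
#' Compares the total number of motif hits across a set of binding-site
#' sequences with the mean total found after scrambling every sequence,
#' over `n_scrambles` independent scrambles. The fold is
#' `observed / max(null_mean, 0.5)` (the floor guards against division by
#' zero when the null finds no hits).
#'
#' @param seqs character vector or `DNAStringSet` of site sequences
#'   (typically 100-bp summit windows).
#' @param motif a [pwm()].
#' @param threshold log-odds threshold in bits (default 60% of max score).
#' @param n_scrambles scrambles per sequence set (default 10).
#' @param seed integer seed, recorded in the result.
#' @param method shuffle order, `"mono"` or `"di"`.
#' @return object of class `motif_enrichment`: `motif`, `observed`,
#'   `null_mean`, `fold`, `n_scrambles`, `seed`.
#' @export
motif_fold_enrichment <- function(seqs, motif, threshold = NULL,
                                  n_scrambles = 10, seed = 1,
                                  method = c("mono", "di")) {
  method <- match.arg(method)
  if (length(seqs) == 0) stop("empty sequence set")
  if (n_scrambles < 1) stop("n_scrambles must be >= 1")
  if (is.null(threshold)) threshold <- 0.6 * pwm_max_score(motif)
  seqs <- vapply(seqs, as.character, "")
  observed <- .scan_total(seqs, motif, threshold)
  null_tot <- vapply(seq_len(n_scrambles), function(k) {
    scr <- vapply(seq_along(seqs), function(i)
      scramble_sequence(seqs[i], derive_seed(seed, k * 1000003L + i),
                        method = method), "")
    .scan_total(scr, motif, threshold)
  }, 0)
  null_mean <- mean(null_tot)
  structure(list(motif = motif$name, observed = observed,
                 null_mean = null_mean,
                 fold = observed / max(null_mean, 0.5),
                 n_scrambles = n_scrambles, seed = seed),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("motif '%s': observed %d hits, null mean %.2f, fold %.2f (%d scrambles, seed %d)\n",
              x$motif, x$observed, x$null_mean, x$fold, x$n_scrambles, x$seed))
  invisible(x)
}

#' Top-scoring peaks of a set
#'
#' The `n` highest-scoring peaks (score ties broken by coordinate), the
#' subset conventionally used for motif analysis.
#'
#' @param peaks peak-set `GRanges` with scores.
#' @param n number of peaks to keep (default 500).
#' @return a peak-set `GRanges`.
#' @export
top_enriched_sites <- function(peaks, n = 500L) {
  if (n > length(peaks)) {
    warning("requested ", n, " sites but only ", length(peaks),
            " available; returning all")
    n <- length(peaks)
  }
  ord <- order(-peaks$score, as.character(GenomeInfoDb::seqnames(peaks)),
               BiocGenerics::start(peaks))
  peaks[ord[seq_len(n)]]
}
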