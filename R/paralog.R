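# Bait-based apportioning of reads between two near-identical paralogs.
#
# A bait is a 50-column gap-free window of the pairwise alignment of the two
# gene copies with at least `min_diff` mismatches, so that no error-free read
# can exact-match both copies' segments of the same window.  Reads are
# assigned to a copy by exact substring match (forward or reverse
# complement) against that copy's bait segments.

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Select diagnostic bait windows discriminating two paralogs
#'
#' Enumerates every gap-free window of `window` aligned columns with at
#' least `min_diff` mismatches between the two copies, then samples
#' `n_baits` mutually non-overlapping windows uniformly at random (seeded).
#' If fewer qualify, all are returned with a warning.
#'
#' @param copy_a,copy_b Nucleotide CDS of the two copies (pre-aligned equal
#'   length, or alignable; global alignment is computed if lengths differ).
#' @param n_baits Number of baits to select (default 5).
#' @param window Window width in aligned columns (default 50).
#' @param min_diff Minimum mismatches per window (default 7).
#' @param seed Integer seed for the window sampling.
#' @return A tibble (class `bait_set`) with one row per bait: `bait`
#'   (id), `start` (0-based, half-open window start on the pairwise
#'   alignment), `end`, `start_a`, `start_b` (0-based ungapped starts on
#'   each copy), `seg_a`, `seg_b` (the two segments), `n_diff`.
#' @export
select_baits <- function(copy_a, copy_b, n_baits = 5, window = 50,
                         min_diff = 7, seed = 1L) {
  copy_a <- toupper(copy_a); copy_b <- toupper(copy_b)
  if (nchar(copy_a) != nchar(copy_b)) {
    al <- Biostrings::pairwiseAlignment(copy_a, copy_b, type = "global")
    aln_a <- as.character(Biostrings::alignedPattern(al))
    aln_b <- as.character(Biostrings::alignedSubject(al))
  } else {
    aln_a <- copy_a; aln_b <- copy_b
  }
  L <- nchar(aln_a)
  if (L < window) abort("aligned length is shorter than the bait window")
  a <- strsplit(aln_a, "")[[1L]]
  b <- strsplit(aln_b, "")[[1L]]
  gap <- a == "-" | b == "-"
  diff <- a != b & !gap

  # rolling window counts of mismatches and gaps
  cdiff <- cumsum(c(0L, diff))
  cgap <- cumsum(c(0L, gap))
  starts <- 0:(L - window)   # 0-based
  n_diff <- cdiff[starts + window + 1L] - cdiff[starts + 1L]
  n_gap <- cgap[starts + window + 1L] - cgap[starts + 1L]
  ok <- n_gap == 0L & n_diff >= min_diff
  if (!any(ok)) {
    abort(paste0("no gap-free ", window, "-column window with >= ", min_diff,
                 " differences; maximum observed divergence is ",
                 max(n_diff[n_gap == 0L], 0L), " differences"))
  }
  cand <- starts[ok]
  cand_diff <- n_diff[ok]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  chosen <- integer(0)
  avail <- seq_along(cand)
  while (length(chosen) < n_baits && length(avail)) {
    pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
    chosen <- c(chosen, pick)
    avail <- avail[abs(cand[avail] - cand[pick]) >= window]
  }
  if (length(chosen) < n_baits) {
    warn(paste0("only ", length(chosen), " non-overlapping qualifying window(s); ",
                "returning all of them"))
  }
  chosen <- sort(chosen)
  st <- cand[chosen]
  cum_a <- cumsum(a != "-"); cum_b <- cumsum(b != "-")
  out <- tibble(
    bait = seq_along(st),
    start = st, end = st + window,
    start_a = as.integer(ifelse(st == 0L, 0L, cum_a[st])),
    start_b = as.integer(ifelse(st == 0L, 0L, cum_b[st])),
    seg_a = substring(aln_a, st + 1L, st + window),
    seg_b = substring(aln_b, st + 1L, st + window),
    n_diff = cand_diff[chosen]
  )
  class(out) <- c("bait_set", class(out))
  out
}

#' Read a FASTQ file as a character vector of read sequences
#'
#' Malformed records are dropped by the underlying parser.
#'
#' @param file FASTQ path (optionally gzipped).
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(file) {
  as.character(Biostrings::readDNAStringSet(file, format = "fastq"))
}

#' Count reads matching each bait segment of each paralog
#'
#' A read increments copy X's count for bait j iff it contains bait j's
#' copy-X segment, or its reverse complement, as an exact substring.  Each
#' read is counted at most once per (bait, copy).
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param baits A bait set from [select_baits()].
#' @return A tibble (class `bait_counts`) with per-bait rows: `bait`,
#'   `count_a`, `count_b`; totals are in `attr(, "totals")` and from
#'   [bait_totals()].
#' @export
count_bait_reads <- function(reads, baits) {
  if (length(reads) == 1L && !grepl("^[ACGTNacgtn]*$", reads) && file.exists(reads)) {
    reads <- read_fastq_seqs(reads)
  }
  reads <- toupper(reads)
  hit <- function(seg) {
    if (!length(reads)) return(0L)
    fwd <- grepl(seg, reads, fixed = TRUE)
    rev <- grepl(revcomp(seg), reads, fixed = TRUE)
    sum(fwd | rev)
  }
  out <- tibble(
    bait = baits$bait,
    count_a = vapply(baits$seg_a, hit, integer(1), USE.NAMES = FALSE),
    count_b = vapply(baits$seg_b, hit, integer(1), USE.NAMES = FALSE)
  )
  class(out) <- c("bait_counts", class(out))
  attr(out, "totals") <- c(a = sum(out$count_a), b = sum(out$count_b))
  out
}

#' Total bait-matching read counts per copy
#' @param counts A `bait_counts` tibble.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
bait_totals <- function(counts) {
  c(a = sum(counts$count_a), b = sum(counts$count_b))
}

#' Relative expression of two paralogs from bait counts
#'
#' The within-sample expression ratio is the ratio of total bait-matching
#' read counts (copy A over copy B); an exhausted denominator gives an
#' infinite ratio with an explicit status rather than an error.  When the
#' TPM of the merged locus is supplied it is apportioned between the copies
#' by the count ratio.
#'
#' @param counts A `bait_counts` tibble from [count_bait_reads()].
#' @param tpm_combined Optional TPM of the merged (both-copy) locus.
#' @return One-row tibble: `total_a`, `total_b`, `ratio_a_over_b`, `status`
#'   (`"ok"`, `"denominator_zero"`, or `"undefined"`), and when
#'   `tpm_combined` is given, `tpm_a` and `tpm_b`.
#' @export
estimate_relative_expression <- function(counts, tpm_combined = NULL) {
  tot <- bait_totals(counts)
  if (tot[["a"]] == 0 && tot[["b"]] == 0) {
    out <- tibble(total_a = 0, total_b = 0, ratio_a_over_b = NA_real_,
                  status = "undefined")
  } else if (tot[["b"]] == 0) {
    out <- tibble(total_a = tot[["a"]], total_b = 0, ratio_a_over_b = Inf,
                  status = "denominator_zero")
  } else {
    out <- tibble(total_a = tot[["a"]], total_b = tot[["b"]],
                  ratio_a_over_b = tot[["a"]] / tot[["b"]], status = "ok")
  }
  if (!is.null(tpm_combined)) {
    denom <- tot[["a"]] + tot[["b"]]
    out$tpm_a <- if (denom > 0) tpm_combined * tot[["a"]] / denom else NA_real_
    out$tpm_b <- if (denom > 0) tpm_combined * tot[["b"]] / denom else NA_real_
  }
  out
}
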