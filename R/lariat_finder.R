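# Lariat (branchpoint-spanning) reads: a read crossing the
# 5'SS-branchpoint junction of an excised lariat is unalignable as-is;
# it is rescued by splitting just before the best donor-motif 7-mer and
# aligning the halves as an inverted pair.

#' Detect branchpoint-spanning reads among unalignable reads
#'
#' Each read is split just before the 7-mer best matching the donor
#' (5'SS) consensus; the two halves are aligned exhaustively (ungapped,
#' Hamming distance) and accepted only if (1) both halves are at least
#' `min_half` nt, (2) each half aligns with at most `max_mismatch`
#' mismatches, (3) the halves are separated by less than `max_sep` in
#' the genome, and (4) the pair placement is unique — with the second
#' (donor) half upstream of the first.  Survivors are kept when the
#' donor half starts exactly at a 5' splice site or recursive site and
#' the first half ends within `acceptor_window` nt upstream of a 3'
#' splice site or recursive site.  The branchpoint is the last genomic
#' base of the first half.
#'
#' @param reads data.frame with `read_id`, `seq`, and optionally
#'   `period`; or a character vector of read sequences.
#' @param genome `DNAStringSet` (forward strand is searched).
#' @param donor_pwm 7-column donor matrix from [build_donor_pwm()].
#' @param annotation `GenomeAnnotation`.
#' @param rs_sites optional data.frame of recursive sites (`chrom`,
#'   `site`).
#' @param min_half,max_mismatch,max_sep,acceptor_window constraints as
#'   above.
#' @return data.frame of accepted lariat reads: `read_id`, `chrom`,
#'   `split_at`, segment coordinates, `branchpoint`, `donor_anchor`,
#'   `acceptor_anchor`, `junction_type`, `branchpoint_context` (+/- 10
#'   nt), `period`.  Attribute `rejected` records read ids and reasons.
#' @export
find_lariat_reads <- function(reads, genome, donor_pwm, annotation,
                              rs_sites = NULL, min_half = 15L,
                              max_mismatch = 1L, max_sep = 1e6,
                              acceptor_window = 100L) {
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read%03d", seq_along(reads)),
                        seq = reads, period = "pooled",
                        stringsAsFactors = FALSE)
  if (is.null(reads$period)) reads$period <- "pooled"
  logp <- attr(donor_pwm, "logp")
  donors <- annotation$donor_sites
  acceptors <- annotation$acceptor_sites
  rs <- if (!is.null(rs_sites) && nrow(rs_sites))
    rs_sites else data.frame(chrom = character(0), site = integer(0))
  out <- list(); rej <- list()
  for (i in seq_len(nrow(reads))) {
    sq <- toupper(reads$seq[i])
    p <- .best_7mer(sq, logp)
    left <- substr(sq, 1L, p - 1L)
    right <- substr(sq, p, nchar(sq))
    if (nchar(left) < min_half || nchar(right) < min_half) {
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = reads$read_id[i], reason = "half shorter than 15 nt")
      next
    }
    combos <- .inverted_pair_hits(left, right, genome, max_mismatch,
                                  max_sep)
    if (nrow(combos) != 1L) {
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = reads$read_id[i],
        reason = if (nrow(combos) == 0L) "no valid inverted alignment"
                 else "pair alignment not unique")
      next
    }
    # second (right/donor) half must start at a 5'SS or recursive site
    don_type <-
      if (any(donors$chrom == combos$chrom &
              donors$pos == combos$right_start)) "5'SS"
      else if (any(rs$chrom == combos$chrom &
                   rs$site == combos$right_start)) "RS"
      else NA_character_
    # first (branchpoint) half must end within `acceptor_window` nt
    # upstream of a 3'SS or recursive site
    bp <- combos$left_end
    acc_hit <- acceptors$chrom == combos$chrom &
      bp >= acceptors$pos - acceptor_window & bp <= acceptors$pos
    rs_hit <- rs$chrom == combos$chrom &
      bp >= rs$site - acceptor_window & bp < rs$site
    acc_type <- if (any(acc_hit)) "3'SS" else if (any(rs_hit)) "RS"
                else NA_character_
    if (is.na(don_type) || is.na(acc_type)) {
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = reads$read_id[i],
        reason = "segments not anchored at splice/recursive sites")
      next
    }
    ctx <- as.character(Biostrings::subseq(
      genome[[combos$chrom]], max(1L, bp - 10L),
      min(length(genome[[combos$chrom]]), bp + 10L)))
    out[[length(out) + 1L]] <- data.frame(
      read_id = reads$read_id[i], chrom = combos$chrom, split_at = p,
      seg2_start = combos$right_start, seg2_end = combos$right_end,
      seg1_start = combos$left_start, seg1_end = combos$left_end,
      branchpoint = bp, donor_anchor = don_type,
      acceptor_anchor = acc_type,
      junction_type = paste0(don_type, "-", acc_type),
      mismatches = combos$left_nm + combos$right_nm,
      branchpoint_context = ctx, period = reads$period[i],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), chrom = character(0),
               split_at = integer(0), seg2_start = integer(0),
               seg2_end = integer(0), seg1_start = integer(0),
               seg1_end = integer(0), branchpoint = integer(0),
               donor_anchor = character(0), acceptor_anchor = character(0),
               junction_type = character(0), mismatches = integer(0),
               branchpoint_context = character(0), period = character(0),
               stringsAsFactors = FALSE)
  attr(res, "rejected") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(read_id = character(0), reason = character(0))
  res
}

# position of the best-scoring donor 7-mer (leftmost on ties)
.best_7mer <- function(seq, logp) {
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1L]]
  colmin <- apply(logp, 2L, min)
  sc <- vapply(seq_len(n - 6L), function(p) {
    ri <- match(b[p:(p + 6L)], rownames(logp))
    ok <- !is.na(ri)
    v <- colmin
    v[ok] <- logp[cbind(ri[ok], which(ok))]
    sum(v)
  }, numeric(1L))
  which.max(sc)
}

# all (left, right) ungapped placements obeying the inverted-pair
# geometry; returns zero, one, or many rows
.inverted_pair_hits <- function(left, right, genome, max_mismatch,
                                max_sep) {
  rows <- list()
  for (ch in names(genome)) {
    lh <- Biostrings::matchPattern(left, genome[[ch]],
                                   max.mismatch = max_mismatch)
    rh <- Biostrings::matchPattern(right, genome[[ch]],
                                   max.mismatch = max_mismatch)
    if (length(lh) == 0L || length(rh) == 0L) next
    for (a in seq_along(lh)) for (b in seq_along(rh)) {
      ls <- Biostrings::start(lh)[a]; rs <- Biostrings::start(rh)[b]
      if (rs >= ls) next                       # donor half must be upstream
      if (ls - rs >= max_sep) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, left_start = ls, left_end = Biostrings::end(lh)[a],
        right_start = rs, right_end = Biostrings::end(rh)[b],
        left_nm = Biostrings::neditStartingAt(
          Biostrings::DNAString(left), genome[[ch]], starting.at = ls),
        right_nm = Biostrings::neditStartingAt(
          Biostrings::DNAString(right), genome[[ch]], starting.at = rs),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), left_start = integer(0),
                      left_end = integer(0), right_start = integer(0),
                      right_end = integer(0), left_nm = integer(0),
                      right_nm = integer(0)))
  do.call(rbind, rows)
}

#' Post-hoc check that reported lariats obey every constraint
#' @param lariats output of [find_lariat_reads()].
#' @param min_half,max_mismatch,max_sep constraint values to verify.
#' @return TRUE invisibly; errors on the first violation.
#' @export
validate_lariats <- function(lariats, min_half = 15L, max_mismatch = 1L,
                             max_sep = 1e6) {
  with(lariats, {
    stopifnot(
      all(seg1_end - seg1_start + 1L >= min_half),
      all(seg2_end - seg2_start + 1L >= min_half),
      all(mismatches <= 2L * max_mismatch),
      all(seg1_start - seg2_start < max_sep),
      all(seg2_start < seg1_start))
  })
  invisible(TRUE)
}
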