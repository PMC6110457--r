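# Splicing kinetics from progressive 4sU labeling: per-segment
# half-lives from completed/incomplete junction-read fractions, the
# co-transcriptional delay ratio, the whole-intron mean lifetime, and
# splicing accuracy from junction dinucleotides.

#' Completed fraction under progressive labeling
#'
#' With transcripts labeled for `t` minutes, transcript ages within the
#' window are uniform; for first-order splicing at rate `lambda` the
#' expected completed fraction is
#' `theta(t) = 1 - (1 - exp(-lambda t)) / (lambda t)`, monotone in both
#' `t` and `lambda`.
#'
#' @param lambda splicing rate (1/min).
#' @param t labeling duration(s) (min).
#' @return completed fraction(s) in `[0, 1)`.
#' @export
theta_completed <- function(lambda, t) {
  x <- lambda * t
  ifelse(x < 1e-8, x / 2, 1 - (1 - exp(-x)) / x)
}

#' Fit a splicing half-life from per-period junction counts
#'
#' Minimizes the squared error between observed completed fractions
#' `ee / (ee + ie)` and `theta(t)` over `lambda` in
#' `[1e-4, 1e3]` per minute; the half-life is `ln 2 / lambda`.
#'
#' @param ee_counts completed (junction) read counts per period.
#' @param ie_counts incomplete (boundary-spanning) read counts.
#' @param times labeling durations in minutes.
#' @param floor_min resolution floor reported when splicing is complete
#'   at every period.
#' @return list with `lambda`, `half_life` (min), `flag` ("ok",
#'   "floor", or "infinite"), `fractions`, `sse`.
#' @export
estimate_half_life <- function(ee_counts, ie_counts,
                               times = c(5, 10, 20), floor_min = 0.1) {
  tot <- ee_counts + ie_counts
  use <- tot > 0
  if (!any(use)) stop("no labeling period with any reads")
  f <- ee_counts[use] / tot[use]
  t <- times[use]
  if (all(f == 1))
    return(list(lambda = log(2) / floor_min, half_life = floor_min,
                flag = "floor", fractions = f, sse = 0))
  if (all(f == 0))
    return(list(lambda = 0, half_life = Inf, flag = "infinite",
                fractions = f, sse = 0))
  obj <- function(loglam) sum((f - theta_completed(exp(loglam), t))^2)
  opt <- optimize(obj, interval = log(c(1e-4, 1e3)))
  lam <- exp(opt$minimum)
  list(lambda = lam, half_life = log(2) / lam, flag = "ok",
       fractions = f, sse = opt$objective)
}

#' Co-transcriptional splicing delay of the first recursive segment
#'
#' The time to transcribe the rest of the intron after the first
#' segment is `(L - l1) / rate`; the delay is the ratio of the first
#' segment's splicing half-life to that time.  A delay below 1 means
#' the segment is typically spliced before the 3' splice site exists.
#'
#' @param half_life_seg1 first-segment splicing half-life (min).
#' @param intron_length,seg1_length lengths (nt).
#' @param rate elongation rate (nt/min).
#' @return list with `txn_time` (min) and `delay` (ratio).
#' @export
splicing_delay <- function(half_life_seg1, intron_length, seg1_length,
                           rate = 1500) {
  txn <- (intron_length - seg1_length) / rate
  list(txn_time = txn, delay = half_life_seg1 / txn)
}

#' Mean lifetime of a one-site recursive intron
#'
#' The intron persists until both segments are spliced; for two
#' independent exponentials the expected maximum is
#' `1/lambda1 + 1/lambda2 - 1/(lambda1 + lambda2)`.  The time to
#' transcribe the first segment (`l1 / rate`) is added so the value is
#' comparable to whole-intron lifetimes measured from the 5' splice
#' site.
#'
#' @param lambda1,lambda2 segment splicing rates (1/min), positive.
#' @param l1 first-segment length (nt).
#' @param rate elongation rate (nt/min).
#' @return list with `waiting` (expected max of the two exponentials),
#'   `txn_seg1`, and their sum `tau_recursive` (min).
#' @export
recursive_intron_lifetime <- function(lambda1, lambda2, l1 = 0,
                                      rate = 1500) {
  stopifnot(lambda1 > 0, lambda2 > 0)
  waiting <- 1 / lambda1 + 1 / lambda2 - 1 / (lambda1 + lambda2)
  txn <- l1 / rate
  list(waiting = waiting, txn_seg1 = txn,
       tau_recursive = waiting + txn)
}

#' Tabulate per-segment complete/incomplete evidence and fit half-lives
#'
#' Segments are delimited by the recursive sites (internal boundaries)
#' and the 3' splice site (final boundary).  For each boundary,
#' incomplete evidence is the contiguous reads straddling it (the
#' segment has not yet been spliced there) and complete evidence is the
#' junction reads whose acceptor is that boundary (5'SS-RS / RS-RS for
#' internal sites; RS-3'SS and 5'SS-3'SS for the final one).
#'
#' @param junctions junction table from [extract_junction_reads()].
#' @param aln alignment table (contiguous reads supply incomplete
#'   counts).
#' @param rs_sites integer vector of recursive-site coordinates in the
#'   intron (sorted; may be empty).
#' @param intron list/row with `chrom`, `start`, `end`, `strand`.
#' @param periods labeling-period labels, in minutes.
#' @param polyA optional transcript end for the `txn_to_three` column.
#' @return data.frame, one row per segment: boundaries, lengths,
#'   `ie_count_<t>` / `ee_count_<t>` per period, `halflife`, `flag`,
#'   `txn_to_three`.
#' @export
assign_segment_junction_reads <- function(junctions, aln, rs_sites,
                                          intron,
                                          periods = c("5", "10", "20"),
                                          polyA = NA_integer_) {
  rs_sites <- sort(rs_sites)
  bounds <- c(as.integer(rs_sites), intron$end + 1L)
  seg_start <- c(intron$start, as.integer(rs_sites))
  body <- aln[aln$unique & !grepl("N", aln$cigar) &
                aln$chrom == intron$chrom, , drop = FALSE]
  jx <- junctions[junctions$chrom == intron$chrom &
                    junctions$gap_start >= intron$start &
                    junctions$gap_end <= intron$end, , drop = FALSE]
  rows <- lapply(seq_along(bounds), function(k) {
    b <- bounds[k]
    ie <- vapply(periods, function(p) {
      sum(body$period == p & body$pos <= b - 1L & body$end >= b)
    }, numeric(1L))
    ee <- vapply(periods, function(p) {
      sum(jx$count[jx$period == p & jx$gap_end == b - 1L])
    }, numeric(1L))
    fit <- if (sum(ie + ee) == 0)
      list(half_life = NA_real_, flag = "no reads", lambda = NA_real_)
    else estimate_half_life(ee, ie, as.numeric(periods))
    r <- data.frame(segment = k,
                    type = if (k == length(bounds)) "threess"
                           else "internal",
                    seg_start = seg_start[k], boundary = b,
                    length = b - seg_start[k],
                    halflife = fit$half_life, lambda = fit$lambda,
                    flag = fit$flag,
                    txn_to_three = if (is.na(polyA)) NA_real_
                                   else polyA - (b - 1L),
                    stringsAsFactors = FALSE)
    for (i in seq_along(periods)) {
      r[[paste0("ie_count_", periods[i])]] <- ie[i]
      r[[paste0("ee_count_", periods[i])]] <- ee[i]
    }
    r
  })
  do.call(rbind, rows)
}

#' Per-intron splicing accuracy from junction dinucleotides
#'
#' Classifies every junction read in an intron as `annotated` (exact
#' match to an annotated intron), `canonical` (terminal dinucleotides
#' GT..AG, GC..AG or AT..AC, or their reverse complements), or
#' `noncanonical`; the inaccuracy fraction is the read density from
#' non-canonical non-annotated junctions over all junction reads.
#'
#' @param junctions junction table.
#' @param annotation `GenomeAnnotation`.
#' @param genome `DNAStringSet`.
#' @return list with `junctions` (input plus `class` column) and
#'   `per_intron` (`intron_id`, `total_reads`, `noncanonical_reads`,
#'   `fraction`).
#' @export
splicing_accuracy <- function(junctions, annotation, genome) {
  if (nrow(junctions) == 0L)
    return(list(junctions = cbind(junctions, class = character(0)),
                per_intron = data.frame(intron_id = character(0),
                                        total_reads = integer(0),
                                        noncanonical_reads = integer(0),
                                        fraction = numeric(0))))
  intr <- annotation$introns
  ikey <- paste(as.character(GenomicRanges::seqnames(intr)),
                GenomicRanges::start(intr), GenomicRanges::end(intr))
  jkey <- paste(junctions$chrom, junctions$gap_start, junctions$gap_end)
  annotated <- jkey %in% ikey
  din <- vapply(seq_len(nrow(junctions)), function(i) {
    ch <- genome[[junctions$chrom[i]]]
    paste0(as.character(Biostrings::subseq(ch, junctions$gap_start[i],
                                           junctions$gap_start[i] + 1L)),
           "-",
           as.character(Biostrings::subseq(ch, junctions$gap_end[i] - 1L,
                                           junctions$gap_end[i])))
  }, character(1L))
  canon <- c("GT-AG", "GC-AG", "AT-AC", "CT-AC", "CT-GC", "GT-AT")
  junctions$class <- ifelse(annotated, "annotated",
                            ifelse(din %in% canon, "canonical",
                                   "noncanonical"))
  gr <- GenomicRanges::GRanges(junctions$chrom,
                               IRanges::IRanges(junctions$gap_start,
                                                junctions$gap_end))
  hits <- GenomicRanges::findOverlaps(gr, intr, type = "within")
  per <- lapply(split(S4Vectors::queryHits(hits),
                      S4Vectors::subjectHits(hits)), function(q) {
    tot <- sum(junctions$count[q])
    nc <- sum(junctions$count[q][junctions$class[q] == "noncanonical"])
    c(tot, nc)
  })
  per_intron <- data.frame(
    intron_id = intr$intron_id[as.integer(names(per))],
    total_reads = vapply(per, `[`, numeric(1L), 1L),
    noncanonical_reads = vapply(per, `[`, numeric(1L), 2L),
    stringsAsFactors = FALSE)
  per_intron$fraction <- per_intron$noncanonical_reads /
    per_intron$total_reads
  rownames(per_intron) <- NULL
  list(junctions = junctions, per_intron = per_intron)
}
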