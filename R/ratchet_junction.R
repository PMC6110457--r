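# Junction-read evidence: split reads joining an annotated 5' splice
# site to an intronic AG|GT, plus the search for alternative-order
# (RS-RS, RS-3'SS) events.

# TRUE where the genomic context at `site` is AG immediately upstream
# and GT starting at the site, in transcription sense
.has_aggt <- function(genome, chrom, site, strand) {
  n <- length(site)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  lens <- setNames(Biostrings::width(genome), names(genome))
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (strand[i] == "-") {
      if (site[i] - 1L < 1L || site[i] + 2L > lens[chrom[i]]) next
      ctx <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chrom[i]]], site[i] - 1L,
                           site[i] + 2L)))
    } else {
      if (site[i] - 2L < 1L || site[i] + 1L > lens[chrom[i]]) next
      ctx <- as.character(Biostrings::subseq(genome[[chrom[i]]],
                                             site[i] - 2L, site[i] + 1L))
    }
    ok[i] <- ctx == "AGGT"
  }
  ok
}

# the donor-sharing intron with the downstream-most acceptor: the
# largest annotated intron per 5' splice site
.largest_intron_per_donor <- function(annotation) {
  intr <- annotation$introns
  key <- paste(as.character(GenomicRanges::seqnames(intr)),
               as.character(GenomicRanges::strand(intr)), intr$donor)
  w <- GenomicRanges::width(intr)
  keep <- unlist(lapply(split(seq_along(intr), key), function(idx)
    idx[which.max(w[idx])]), use.names = FALSE)
  intr[keep]
}

#' Detect recursive sites from 5'SS-RS junction reads
#'
#' A candidate is a split-read junction whose upstream edge matches an
#' annotated 5' splice site exactly and whose downstream edge lands
#' strictly inside the intron (upstream of the downstream-most 3'
#' splice site sharing that donor) on an AG|GT.  Support is the
#' unique-read count per labeling period.
#'
#' @param junctions junction table from [extract_junction_reads()].
#' @param annotation `GenomeAnnotation`.
#' @param genome `DNAStringSet`.
#' @return data.frame: `chrom`, `strand`, `intron_id` (largest
#'   donor-sharing intron), `donor`, `site`, `period`, `count`.
#' @export
find_ratchet_junctions <- function(junctions, annotation, genome) {
  empty <- data.frame(chrom = character(0), strand = character(0),
                      intron_id = character(0), donor = integer(0),
                      site = integer(0), period = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (nrow(junctions) == 0L) return(empty)
  intr <- .largest_intron_per_donor(annotation)
  out <- list()
  for (i in seq_along(intr)) {
    ch <- as.character(GenomicRanges::seqnames(intr))[i]
    st <- as.character(GenomicRanges::strand(intr))[i]
    s <- GenomicRanges::start(intr)[i]; e <- GenomicRanges::end(intr)[i]
    if (st == "-") {
      j <- junctions[junctions$chrom == ch & junctions$gap_end == e &
                       junctions$gap_start > s, , drop = FALSE]
      if (nrow(j) == 0L) next
      j$site <- j$gap_start - 1L
    } else {
      j <- junctions[junctions$chrom == ch & junctions$gap_start == s &
                       junctions$gap_end < e, , drop = FALSE]
      if (nrow(j) == 0L) next
      j$site <- j$gap_end + 1L
    }
    j <- j[.has_aggt(genome, ch, j$site, st), , drop = FALSE]
    if (nrow(j) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, strand = st, intron_id = intr$intron_id[i],
      donor = intr$donor[i], site = j$site, period = j$period,
      count = j$count, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Classify every junction read within an intron
#'
#' Junctions partition into 5'SS-3'SS (the complete annotated
#' splicing event), 5'SS-RS, RS-RS and RS-3'SS according to whether
#' each edge matches the annotation or an intronic AG|GT; anything
#' else is labeled `other`.
#'
#' @param junctions junction table restricted by the caller as needed.
#' @param intron one-row view of an intron: list/data.frame with
#'   `chrom`, `start`, `end`, `strand`.
#' @param genome `DNAStringSet`.
#' @return `junctions` with a `category` column.
#' @export
categorize_junctions <- function(junctions, intron, genome) {
  ch <- intron$chrom; s <- intron$start; e <- intron$end
  st <- intron$strand
  inside <- junctions$chrom == ch & junctions$gap_start >= s &
    junctions$gap_end <= e
  j <- junctions[inside, , drop = FALSE]
  if (nrow(j) == 0L) { j$category <- character(0); return(j) }
  if (st == "-") {
    don_edge <- j$gap_end == e
    acc_edge <- j$gap_start == s
    rs_at_acc <- .has_aggt(genome, ch, j$gap_start - 1L, st)
    rs_at_don <- .has_aggt(genome, ch, j$gap_end + 1L, st)
  } else {
    don_edge <- j$gap_start == s
    acc_edge <- j$gap_end == e
    rs_at_acc <- .has_aggt(genome, ch, j$gap_end + 1L, st)
    rs_at_don <- .has_aggt(genome, ch, j$gap_start, st)
  }
  j$category <- ifelse(don_edge & acc_edge, "5'SS-3'SS",
                ifelse(don_edge & rs_at_acc, "5'SS-RS",
                ifelse(rs_at_don & acc_edge, "RS-3'SS",
                ifelse(rs_at_don & rs_at_acc, "RS-RS", "other"))))
  j
}

#' Search for alternative-order recursive junctions
#'
#' Reports RS-RS and RS-3'SS junction events — evidence that segments
#' were not removed strictly 5' to 3' — subject to: both endpoints are
#' intronic AG|GTs (or an AG|GT and the annotated 3'SS), the implied
#' recursive segment is at least `min_segment` nt, support is at least
#' `min_reads` unique reads, and every involved recursive site scores
#' above `min_motif`.
#'
#' @param junctions junction table.
#' @param annotation `GenomeAnnotation`.
#' @param genome `DNAStringSet`.
#' @param pwm `SpliceSitePWM` for motif gating.
#' @param min_reads,min_segment,min_motif thresholds.
#' @return data.frame with `chrom`, `strand`, `intron_id`, `category`,
#'   `gap_start`, `gap_end`, `count`, `min_site_score`.
#' @export
find_alternative_order_junctions <- function(junctions, annotation,
                                             genome, pwm,
                                             min_reads = 3L,
                                             min_segment = 1000L,
                                             min_motif = 0.85) {
  intr <- annotation$introns
  out <- list()
  for (i in seq_along(intr)) {
    iv <- list(chrom = as.character(GenomicRanges::seqnames(intr))[i],
               start = GenomicRanges::start(intr)[i],
               end = GenomicRanges::end(intr)[i],
               strand = as.character(GenomicRanges::strand(intr))[i])
    j <- categorize_junctions(junctions, iv, genome)
    j <- j[j$category %in% c("RS-RS", "RS-3'SS"), , drop = FALSE]
    if (nrow(j) == 0L) next
    agg <- stats::aggregate(list(count = j$count),
                            by = j[c("gap_start", "gap_end", "category")],
                            FUN = sum)
    agg <- agg[agg$count >= min_reads &
                 (agg$gap_end - agg$gap_start + 1L) >= min_segment, ,
               drop = FALSE]
    if (nrow(agg) == 0L) next
    keep <- logical(nrow(agg)); msc <- numeric(nrow(agg))
    for (r in seq_len(nrow(agg))) {
      rs <- if (iv$strand == "-") agg$gap_end[r] + 1L else agg$gap_start[r]
      sites <- rs
      if (agg$category[r] == "RS-RS")
        sites <- c(sites, if (iv$strand == "-") agg$gap_start[r] - 1L
                          else agg$gap_end[r] + 1L)
      w <- site_window(genome, iv$chrom, sites, iv$strand, pwm)
      if (any(is.na(w))) next
      sc <- score_sites(w, pwm)
      msc[r] <- min(sc)
      keep[r] <- all(sc > min_motif)
    }
    agg <- agg[keep, , drop = FALSE]
    if (nrow(agg) == 0L) next
    agg$min_site_score <- msc[keep]
    agg$chrom <- iv$chrom; agg$strand <- iv$strand
    agg$intron_id <- intr$intron_id[i]
    out[[length(out) + 1L]] <- agg
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      intron_id = character(0), category = character(0),
                      gap_start = integer(0), gap_end = integer(0),
                      count = integer(0), min_site_score = numeric(0)))
  df <- do.call(rbind, out)
  df[c("chrom", "strand", "intron_id", "category", "gap_start",
       "gap_end", "count", "min_site_score")]
}
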