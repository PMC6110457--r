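# Read-pair evidence: pairs straddling a recursive junction are
# assigned to candidate AG|GT sites by a sparse EM mixture (a GEM-style
# deconvolution with a motif prior and an insert-length likelihood).

#' Pair up mates from an alignment table
#'
#' @param aln alignment table from [read_alignments()].
#' @param split_ok keep pairs whose reads contain N gaps (default
#'   drops them; spanning-pair geometry and fragment-length training
#'   both want contiguous mates).
#' @return data.frame: `read_id`, `chrom`, `read1_start`, `read1_end`,
#'   `read2_start`, `read2_end`, `period` (read 1 is the leftmost mate).
#' @export
pair_mates <- function(aln, split_ok = FALSE) {
  aln <- aln[aln$unique, , drop = FALSE]
  if (!split_ok) aln <- aln[!grepl("N", aln$cigar), , drop = FALSE]
  cnt <- table(aln$read_id)
  keep <- names(cnt)[cnt == 2L]
  aln <- aln[aln$read_id %in% keep, , drop = FALSE]
  if (nrow(aln) == 0L)
    return(data.frame(read_id = character(0), chrom = character(0),
                      read1_start = integer(0), read1_end = integer(0),
                      read2_start = integer(0), read2_end = integer(0),
                      period = character(0), stringsAsFactors = FALSE))
  aln <- aln[order(aln$read_id, aln$pos), , drop = FALSE]
  first <- seq(1L, nrow(aln), by = 2L)
  data.frame(read_id = aln$read_id[first],
             chrom = aln$chrom[first],
             read1_start = aln$pos[first], read1_end = aln$end[first],
             read2_start = aln$pos[first + 1L],
             read2_end = aln$end[first + 1L],
             period = aln$period[first], stringsAsFactors = FALSE)
}

#' Select read pairs that can only span a recursive junction
#'
#' Keeps pairs whose first read ends close upstream of an annotated 5'
#' splice site and whose second read lies in the intron more than
#' `min_downstream` nt downstream, then drops any pair already
#' explained by ordinary splicing — an implied insert under
#' `min_downstream` nt conditional on completion of some annotated
#' splicing event contained in the pair's span.
#'
#' @param pairs from [pair_mates()].
#' @param annotation `GenomeAnnotation`.
#' @param max_upstream how far upstream of the donor read 1 may end
#'   (nt); bounded by plausible fragment length.
#' @param min_downstream minimum distance into the intron (nt).
#' @return `pairs` restricted to candidates, with `intron_id` and
#'   `donor` columns.
#' @export
select_spanning_pairs <- function(pairs, annotation,
                                  max_upstream = 300L,
                                  min_downstream = 1000L) {
  intr <- .largest_intron_per_donor(annotation)
  out <- list()
  for (i in seq_along(intr)) {
    ch <- as.character(GenomicRanges::seqnames(intr))[i]
    st <- as.character(GenomicRanges::strand(intr))[i]
    if (st == "-") next  # pair geometry below is for plus-strand genes
    d <- intr$donor[i]
    e <- GenomicRanges::end(intr)[i]
    sel <- pairs$chrom == ch &
      pairs$read1_end < d & pairs$read1_end >= d - max_upstream &
      pairs$read2_start >= pairs$read1_end + min_downstream &
      pairs$read2_start >= d & pairs$read2_end <= e
    p <- pairs[sel, , drop = FALSE]
    if (nrow(p) == 0L) next
    p <- p[!.explained_by_annotation(p, annotation, min_downstream), ,
           drop = FALSE]
    if (nrow(p) == 0L) next
    p$intron_id <- intr$intron_id[i]
    p$donor <- d
    out[[length(out) + 1L]] <- p
  }
  if (length(out) == 0L)
    return(cbind(pairs[0, , drop = FALSE],
                 data.frame(intron_id = character(0), donor = integer(0))))
  do.call(rbind, out)
}

# TRUE for pairs whose insert drops below `lim` after removing some
# annotated intron contained in the pair span (completed splicing)
.explained_by_annotation <- function(pairs, annotation, lim = 1000L) {
  intr <- annotation$introns
  vapply(seq_len(nrow(pairs)), function(n) {
    span <- pairs$read2_end[n] - pairs$read1_start[n] + 1L
    inside <- as.character(GenomicRanges::seqnames(intr)) ==
      pairs$chrom[n] &
      GenomicRanges::start(intr) >= pairs$read1_start[n] &
      GenomicRanges::end(intr) <= pairs$read2_end[n]
    if (!any(inside)) return(FALSE)
    any(span - GenomicRanges::width(intr)[inside] < lim)
  }, logical(1L))
}

#' Empirical fragment-length distribution
#'
#' Histogram of implied insert lengths over all read pairs (and pooled
#' junction reads): the pair span minus the lengths of annotated
#' introns contained in it (completed splicing), smoothed with a
#' Gaussian kernel.
#'
#' @param aln alignment table (pairs are formed internally; reads with
#'   N gaps participate via their genomic span minus annotated gaps).
#' @param annotation `GenomeAnnotation`.
#' @param max_len histogram support (lengths 0..`max_len`).
#' @param bw Gaussian smoothing bandwidth (nt); 0 disables smoothing.
#' @return A `FragmentLengthDistribution`: `prob` (length
#'   `max_len + 1`), `raw` counts, `n`, `bw`, `mean`.
#' @export
estimate_fragment_distribution <- function(aln, annotation,
                                           max_len = 2000L, bw = 10) {
  aln <- aln[aln$unique, , drop = FALSE]
  s <- tapply(aln$pos, aln$read_id, min)
  e <- tapply(aln$end, aln$read_id, max)
  ch <- tapply(aln$chrom, aln$read_id, function(x) x[1L])
  span <- as.integer(e) - as.integer(s) + 1L
  intr <- annotation$introns
  sub <- vapply(seq_along(span), function(n) {
    inside <- as.character(GenomicRanges::seqnames(intr)) == ch[n] &
      GenomicRanges::start(intr) >= as.integer(s[n]) &
      GenomicRanges::end(intr) <= as.integer(e[n])
    sum(GenomicRanges::width(intr)[inside])
  }, integer(1L))
  new_fragment_distribution(span - sub, max_len, bw)
}

#' @rdname estimate_fragment_distribution
#' @param lengths integer vector of insert lengths (alternative entry
#'   point when inserts are already known).
#' @export
new_fragment_distribution <- function(lengths, max_len = 2000L,
                                      bw = 10) {
  lengths <- lengths[lengths >= 0L & lengths <= max_len]
  raw <- tabulate(lengths + 1L, nbins = max_len + 1L)
  prob <- if (bw > 0) {
    half <- ceiling(4 * bw)
    kern <- dnorm(-half:half, sd = bw)
    sm <- stats::filter(c(numeric(half), raw, numeric(half)),
                        kern, sides = 2L)
    as.numeric(sm[(half + 1L):(half + max_len + 1L)])
  } else as.numeric(raw)
  prob <- prob / sum(prob)
  structure(list(prob = prob, raw = raw, n = sum(raw), bw = bw,
                 max_len = max_len,
                 mean = sum((0:max_len) * prob)),
            class = "FragmentLengthDistribution")
}

#' @export
print.FragmentLengthDistribution <- function(x, ...) {
  cat(sprintf(
    "FragmentLengthDistribution: n = %d, mean = %.1f nt, bw = %g\n",
    x$n, x$mean, x$bw))
  invisible(x)
}

#' Probability of an insert length under the empirical distribution
#' @param fd `FragmentLengthDistribution`.
#' @param len integer length(s); lengths outside the support get 0.
#' @export
fragment_prob <- function(fd, len) {
  p <- numeric(length(len))
  ok <- !is.na(len) & len >= 0L & len <= fd$max_len
  p[ok] <- fd$prob[len[ok] + 1L]
  p
}

#' Sparse EM assignment of spanning pairs to candidate recursive sites
#'
#' Candidate positions are the intronic AG|GTs with motif score above
#' `motif_floor`; the prior is initialized proportional to
#' `max(0, M(i) - motif_floor)`.  The E-step gives each pair a
#' responsibility proportional to `prior * P(implied insert)`, where
#' the implied insert for site `m` is the portion of the fragment
#' upstream of the donor plus the portion downstream of `m`.  The
#' M-step adds junction reads at each site to the effective counts,
#' subtracts the sparsity penalty `alpha = assigned reads / 40` and
#' truncates at zero before renormalizing.  The algorithm stops when no
#' prior changes by more than `tol`; pairs are then MAP-assigned.
#'
#' @param pairs spanning pairs for one intron ([select_spanning_pairs()]).
#' @param junction_counts named integer vector: 5'SS-RS junction reads
#'   per site coordinate (names are coordinates), or NULL.
#' @param fragment_dist `FragmentLengthDistribution`.
#' @param pwm `SpliceSitePWM`.
#' @param genome `DNAStringSet`.
#' @param intron list/row with `chrom`, `start`, `end`, `strand`.
#' @param donor donor coordinate (first intronic base).
#' @param motif_floor prior support threshold on the motif score.
#' @param tol convergence tolerance on the prior.
#' @param max_iter EM iteration cap.
#' @param alpha_denom sparsity denominator (assigned reads / this).
#' @return A `GemModel`: `sites` (candidate table with `prior`,
#'   `effective_reads`, `map_pairs`, `junction_reads`, `motif_score`),
#'   `assignments` (MAP site per pair, NA when unassignable),
#'   `responsibilities`, `loglik` trace, `converged`, `iterations`.
#'   Empty-support inputs yield a zero-row `sites` with a warning.
#' @export
gem_infer_sites <- function(pairs, junction_counts, fragment_dist, pwm,
                            genome, intron, donor, motif_floor = 0.8,
                            tol = 1e-5, max_iter = 500L,
                            alpha_denom = 40) {
  aggt <- .intron_aggt(genome, pwm, intron$chrom, intron$start,
                       intron$end, intron$strand)
  aggt <- aggt[aggt$motif_score > motif_floor, , drop = FALSE]
  empty <- structure(list(
    sites = data.frame(site = integer(0), motif_score = numeric(0),
                       prior = numeric(0), effective_reads = numeric(0),
                       map_pairs = integer(0), junction_reads = numeric(0)),
    assignments = rep(NA_integer_, nrow(pairs)),
    responsibilities = NULL, loglik = numeric(0),
    converged = FALSE, iterations = 0L), class = "GemModel")
  if (nrow(aggt) == 0L) {
    warning("no candidate position with positive motif prior")
    return(empty)
  }
  m <- aggt$site
  J <- numeric(length(m))
  if (!is.null(junction_counts) && length(junction_counts)) {
    hit <- match(as.character(m), names(junction_counts))
    J[!is.na(hit)] <- junction_counts[hit[!is.na(hit)]]
  }
  n <- nrow(pairs)
  # implied insert of pair i under site j
  lik <- if (n > 0L) {
    up <- donor - pairs$read1_start
    ins <- outer(pairs$read2_end + 1L, m, "-") + up
    matrix(fragment_prob(fragment_dist, as.integer(ins)),
           nrow = n)
  } else matrix(numeric(0), nrow = 0L, ncol = length(m))
  pri <- aggt$motif_score - motif_floor
  pri <- pri / sum(pri)
  alpha <- (n + sum(J)) / alpha_denom
  ll <- numeric(0)
  converged <- FALSE
  R <- matrix(numeric(0), n, length(m))
  for (it in seq_len(max_iter)) {
    W <- sweep(lik, 2L, pri, "*")
    rs <- rowSums(W)
    ll <- c(ll, sum(log(rs[rs > 0])))
    R <- W / ifelse(rs > 0, rs, 1)
    R[rs == 0, ] <- 0    # pairs impossible under every candidate
    Nm <- colSums(R) + J
    pri_new <- pmax(0, Nm - alpha)
    if (sum(pri_new) == 0) {
      warning("sparsity removed all candidate sites")
      return(empty)
    }
    pri_new <- pri_new / sum(pri_new)
    done <- max(abs(pri_new - pri)) <= tol
    pri <- pri_new
    if (done) { converged <- TRUE; iterations <- it; break }
    iterations <- it
  }
  assignments <- if (n > 0L) {
    W <- sweep(lik, 2L, pri, "*")
    map <- max.col(W, ties.method = "first")
    ifelse(rowSums(W) > 0, m[map], NA_integer_)
  } else integer(0)
  eff <- if (n > 0L) colSums(R) + J else J
  structure(list(
    sites = data.frame(site = m, motif_score = aggt$motif_score,
                       prior = pri, effective_reads = eff,
                       map_pairs = as.integer(
                         tabulate(match(assignments, m), length(m))),
                       junction_reads = J),
    assignments = assignments, responsibilities = R, loglik = ll,
    converged = converged, iterations = iterations),
    class = "GemModel")
}

#' @export
print.GemModel <- function(x, ...) {
  cat("GemModel:", nrow(x$sites), "candidate sites,",
      sum(x$sites$prior > 0), "supported;",
      if (x$converged) "converged" else "not converged",
      "after", x$iterations, "iterations\n")
  invisible(x)
}
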