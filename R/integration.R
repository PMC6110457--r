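# Evidence integration: merge the three detectors, apply the candidate
# filters and confidence tiers, and provide subsampling sensitivity and
# iterative GO enrichment.

#' Filter candidate recursive sites
#'
#' Removes candidates that are (1) in genes below `min_tpm`, (2) in
#' introns with fewer than `min_spanning` reads spanning the complete
#' 5' to 3' splice junction (counted on the largest donor-sharing
#' intron), or (3) coincident with an annotated 5' splice site.
#'
#' @param calls data.frame with at least `site`, `chrom`, `TPM`,
#'   `spanning_reads`.
#' @param annotation `GenomeAnnotation` (for the donor overlap check).
#' @param min_tpm,min_spanning thresholds.
#' @return the retained calls; attribute `removed` holds dropped rows
#'   with a `reason` column.
#' @export
filter_candidates <- function(calls, annotation, min_tpm = 1,
                              min_spanning = 3L) {
  if (nrow(calls) == 0L) {
    attr(calls, "removed") <- cbind(calls, reason = character(0))
    return(calls)
  }
  don <- annotation$donor_sites
  at_donor <- vapply(seq_len(nrow(calls)), function(i)
    any(don$chrom == calls$chrom[i] & don$pos == calls$site[i]),
    logical(1L))
  reason <- ifelse(calls$TPM < min_tpm, "TPM",
            ifelse(calls$spanning_reads < min_spanning, "spanning_reads",
            ifelse(at_donor, "annotated 5'SS overlap", NA_character_)))
  kept <- calls[is.na(reason), , drop = FALSE]
  removed <- calls[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  attr(kept, "removed") <- removed
  kept
}

#' Assign confidence tiers to recursive-site calls
#'
#' High confidence: detected by at least 2 methods and either more than
#' `support_threshold` supporting junction reads plus read pairs or a
#' sawtooth FDR of at most `high_fdr`.  Medium: at least 1 method and
#' either the same support or FDR at most `medium_fdr`.  Everything
#' else is rejected.  When a sawtooth-presence flag is available
#' (fitted density jump at the call at least 1.5-fold), high confidence
#' additionally requires it — the automated stand-in for visual
#' inspection of the read densities.
#'
#' @param calls data.frame with `n_methods`, `support` (junction +
#'   pair reads), `fdr` (NA when no sawtooth evidence), optionally
#'   `sawtooth_flag` (logical or NA).
#' @param support_threshold,high_fdr,medium_fdr tier parameters.
#' @return `calls` with a `confidence` column in
#'   `{"high", "medium", "rejected"}`.
#' @export
assign_confidence <- function(calls, support_threshold = 5,
                              high_fdr = 0.05, medium_fdr = 0.20) {
  if (nrow(calls) == 0L) { calls$confidence <- character(0); return(calls) }
  fdr <- if (is.null(calls$fdr)) rep(NA_real_, nrow(calls)) else calls$fdr
  flag <- if (is.null(calls$sawtooth_flag)) rep(NA, nrow(calls))
          else calls$sawtooth_flag
  gate <- function(k, f)
    calls$n_methods >= k &
      (calls$support > support_threshold | (!is.na(fdr) & fdr <= f))
  high <- gate(2L, high_fdr) & (is.na(flag) | flag)
  medium <- gate(1L, medium_fdr)
  calls$confidence <- ifelse(high, "high",
                             ifelse(medium, "medium", "rejected"))
  calls
}

#' Detection sensitivity under read subsampling
#'
#' Bernoulli-subsamples reads (whole read pairs, by read id) to each
#' fraction, re-runs a detection function, and reports the number of
#' detected sites per fraction; optionally stratified by an
#' expression split.
#'
#' @param aln alignment table.
#' @param run_fn function(alignment table) returning a calls
#'   data.frame (one row per detected site; a `TPM` column enables the
#'   expression split).
#' @param fractions subsampling fractions in `[0, 1]`.
#' @param seed integer seed.
#' @param tpm_split when not NULL, also report detections in genes at
#'   or below / above this TPM.
#' @return data.frame with `fraction`, `n_detected` (and `n_low_tpm`,
#'   `n_high_tpm` when split).
#' @export
subsample_sensitivity <- function(aln, run_fn,
                                  fractions = c(0.001, 0.005, 0.01,
                                                0.025, 0.05, 0.1, 0.2,
                                                0.3, 0.4, 0.5, 0.6, 0.7,
                                                0.8, 0.9),
                                  seed = 1L, tpm_split = NULL) {
  ids <- unique(aln$read_id)
  .with_seed(seed, {
    rows <- lapply(fractions, function(f) {
      keep <- if (f >= 1) ids else ids[runif(length(ids)) < f]
      calls <- run_fn(aln[aln$read_id %in% keep, , drop = FALSE])
      r <- data.frame(fraction = f, n_detected = nrow(calls))
      if (!is.null(tpm_split) && !is.null(calls$TPM)) {
        r$n_low_tpm <- sum(calls$TPM <= tpm_split)
        r$n_high_tpm <- sum(calls$TPM > tpm_split)
      }
      r
    })
    do.call(rbind, rows)
  })
}

#' Iterative GO enrichment with term elimination
#'
#' Repeatedly: test every term for enrichment of the foreground within
#' the background by a one-sided Fisher exact test, record the most
#' significant term, remove its genes from both sets, and continue
#' until the foreground is empty or no term remains.
#' Benjamini-Hochberg correction is applied across the reported terms.
#'
#' @param foreground,background character vectors of gene ids; the
#'   background must contain the foreground.
#' @param ontology data.frame with `gene_id` and `term`.
#' @return data.frame of reported terms in elimination order, with the
#'   2x2 table counts, `p`, and `p_adj`.
#' @export
iterative_go_enrichment <- function(foreground, background, ontology) {
  fg <- unique(foreground); bg <- unique(union(background, foreground))
  res <- list()
  repeat {
    if (length(fg) == 0L) break
    terms <- unique(ontology$term[ontology$gene_id %in% bg])
    if (length(terms) == 0L) break
    stats <- lapply(terms, function(tm) {
      genes <- unique(ontology$gene_id[ontology$term == tm])
      a <- sum(fg %in% genes)
      b <- length(fg) - a
      cc <- sum(bg %in% genes) - a
      d <- length(bg) - length(fg) - cc
      p <- fisher.test(matrix(c(a, b, cc, d), 2L),
                       alternative = "greater")$p.value
      data.frame(term = tm, fg_in = a, fg_out = b, bg_in = cc,
                 bg_out = d, p = p, stringsAsFactors = FALSE)
    })
    stats <- do.call(rbind, stats)
    top <- stats[which.min(stats$p), , drop = FALSE]
    res[[length(res) + 1L]] <- top
    gone <- unique(ontology$gene_id[ontology$term == top$term])
    fg <- setdiff(fg, gone)
    bg <- setdiff(bg, gone)
  }
  if (length(res) == 0L)
    return(data.frame(term = character(0), fg_in = integer(0),
                      fg_out = integer(0), bg_in = integer(0),
                      bg_out = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Run the full recursive-site detection pipeline
#'
#' Orchestrates annotation/genome/alignment loading, PWM training, the
#' three detectors, evidence merging, candidate filtering and
#' confidence tiers, producing one row per candidate site in the
#' standard summary layout.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param annotation `GenomeAnnotation`, exon `GRanges`, or GFF3 path.
#' @param alignments alignment table, or SAM/BAM/TSV path.
#' @param expression data.frame (`gene_id`, `TPM`) or TSV path.
#' @param coverage named list of per-base intronic coverage vectors
#'   keyed by intron id (as produced by
#'   [simulate_ratchet_experiment()]), a bedGraph path, or NULL to
#'   derive coverage from the alignments.
#' @param repeats optional repeat `GRanges` or BED path.
#' @param methods detectors to run, subset of
#'   `c("junction", "pair", "sawtooth")`.
#' @param mcmc list of [mcmc_sawtooth()] schedule overrides
#'   (`iterations`, `burn_in`, `sample_every`).
#' @param fdr_shuffles shuffles for the sawtooth FDR.
#' @param min_tpm,min_spanning candidate filters.
#' @param support_threshold,high_fdr,medium_fdr confidence tiers.
#' @param seed integer seed driving the MCMC and FDR shuffles.
#' @return data.frame of calls (one per site) with evidence columns,
#'   `confidence`, and the summary-table fields used by
#'   [write_sites_tsv()].  Attributes: `skipped` (introns not scanned
#'   and why), `removed` (filtered candidates).
#' @export
run_ratchet_pipeline <- function(genome, annotation, alignments,
                                 expression, coverage = NULL,
                                 repeats = NULL,
                                 methods = c("junction", "pair",
                                             "sawtooth"),
                                 mcmc = list(iterations = 1e5,
                                             burn_in = 1e4,
                                             sample_every = 50L),
                                 fdr_shuffles = 200L,
                                 min_tpm = 1, min_spanning = 3L,
                                 support_threshold = 5,
                                 high_fdr = 0.05, medium_fdr = 0.20,
                                 seed = 1L) {
  genome <- load_genome(genome)
  if (!inherits(annotation, "GenomeAnnotation"))
    annotation <- load_annotation(annotation)
  alignments <- read_alignments(alignments)
  if (is.character(expression))
    expression <- read.table(expression, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (is.character(repeats)) repeats <- rtracklayer::import(repeats)
  if (is.character(coverage)) coverage <- .coverage_from_bedgraph(coverage)
  periods <- intersect(c("5", "10", "20"),
                       unique(alignments$period))
  junctions <- extract_junction_reads(alignments)
  pwm <- build_pwms(annotation, genome)
  spanning <- intron_spanning_counts(junctions, annotation)
  intr <- .largest_intron_per_donor(annotation)
  iv <- data.frame(intron_id = intr$intron_id,
                   chrom = as.character(GenomicRanges::seqnames(intr)),
                   start = GenomicRanges::start(intr),
                   end = GenomicRanges::end(intr),
                   strand = as.character(GenomicRanges::strand(intr)),
                   donor = intr$donor, gene_id = intr$gene_id,
                   stringsAsFactors = FALSE)
  iv$spanning_reads <- spanning$spanning_reads[
    match(iv$intron_id, spanning$intron_id)]
  iv$TPM <- expression$TPM[match(iv$gene_id, expression$gene_id)]
  iv$TPM[is.na(iv$TPM)] <- 0

  ev <- new.env(parent = emptyenv()); ev$tab <- list()
  note <- function(intron_row, site, method, field, value) {
    key <- paste(intron_row$intron_id, site)
    rec <- ev$tab[[key]]
    if (is.null(rec))
      rec <- list(intron = intron_row, site = site, methods = character(0),
                  junction_by_period = setNames(numeric(length(periods)),
                                                periods),
                  pair_by_period = setNames(numeric(length(periods)),
                                            periods),
                  junction_total = 0, pair_total = 0,
                  sawtooth_score = NA_real_, mcmc_probability = NA_real_,
                  fdr = NA_real_)
    rec$methods <- union(rec$methods, method)
    rec[[field]] <- value
    ev$tab[[key]] <- rec
  }

  rj <- if ("junction" %in% methods)
    find_ratchet_junctions(junctions, annotation, genome) else
    data.frame(intron_id = character(0))
  if (nrow(rj)) {
    for (key in unique(paste(rj$intron_id, rj$site))) {
      sub <- rj[paste(rj$intron_id, rj$site) == key, , drop = FALSE]
      row <- iv[iv$intron_id == sub$intron_id[1L], , drop = FALSE]
      if (nrow(row) == 0L) next
      per <- setNames(numeric(length(periods)), periods)
      for (p in intersect(sub$period, periods))
        per[p] <- sum(sub$count[sub$period == p])
      note(row, sub$site[1L], "junction", "junction_by_period", per)
      note(row, sub$site[1L], "junction", "junction_total",
           sum(sub$count))
    }
  }

  if ("pair" %in% methods) {
    pairs <- pair_mates(alignments)
    span_pairs <- select_spanning_pairs(pairs, annotation)
    fragdist <- estimate_fragment_distribution(alignments, annotation)
    for (id in unique(span_pairs$intron_id)) {
      p <- span_pairs[span_pairs$intron_id == id, , drop = FALSE]
      row <- iv[iv$intron_id == id, , drop = FALSE]
      if (nrow(row) == 0L) next
      jc <- rj[rj$intron_id == id, , drop = FALSE]
      jcounts <- if (nrow(jc)) tapply(jc$count, jc$site, sum) else NULL
      gm <- suppressWarnings(gem_infer_sites(
        p, jcounts, fragdist, pwm, genome,
        list(chrom = row$chrom, start = row$start, end = row$end,
             strand = row$strand), donor = row$donor))
      hit <- gm$sites[gm$sites$prior > 0 & gm$sites$map_pairs > 0, ,
                      drop = FALSE]
      for (r in seq_len(nrow(hit))) {
        per <- setNames(numeric(length(periods)), periods)
        asn <- p$period[!is.na(gm$assignments) &
                          gm$assignments == hit$site[r]]
        for (pp in intersect(asn, periods))
          per[pp] <- sum(asn == pp)
        note(row, hit$site[r], "pair", "pair_by_period", per)
        note(row, hit$site[r], "pair", "pair_total", hit$map_pairs[r])
      }
    }
  }

  skipped <- list(); profiles <- list()
  if ("sawtooth" %in% methods) {
    for (i in seq_len(nrow(iv))) {
      row <- iv[i, , drop = FALSE]
      counts <- .intron_counts(coverage, alignments, row)
      if (is.null(counts)) next
      prof <- preprocess_coverage(counts, row$start, row$end,
                                  chrom = row$chrom, strand = row$strand,
                                  repeats = repeats,
                                  exons = annotation$exons,
                                  spanning_reads = row$spanning_reads)
      if (inherits(prof, "skipped_intron")) {
        skipped[[row$intron_id]] <- prof$reason
        next
      }
      profiles[[row$intron_id]] <- prof
      track <- mcmc_sawtooth(prof,
                             iterations = mcmc$iterations,
                             burn_in = mcmc$burn_in,
                             sample_every = mcmc$sample_every,
                             seed = seed + i)
      peaks <- call_peaks(track, genome, pwm)
      peaks <- estimate_sawtooth_fdr(peaks, track, genome, pwm,
                                     n_shuffles = fdr_shuffles,
                                     seed = seed + i)
      for (r in seq_len(nrow(peaks))) {
        note(row, peaks$site[r], "sawtooth", "sawtooth_score",
             peaks$sawtooth_score[r])
        note(row, peaks$site[r], "sawtooth", "mcmc_probability",
             peaks$mcmc_probability[r])
        note(row, peaks$site[r], "sawtooth", "fdr", peaks$fdr[r])
      }
    }
  }

  calls <- .collect_calls(ev$tab, periods, genome, pwm, profiles)
  calls <- filter_candidates(calls, annotation, min_tpm, min_spanning)
  removed <- attr(calls, "removed")
  calls <- assign_confidence(calls, support_threshold, high_fdr,
                             medium_fdr)
  calls$high_confidence <- as.integer(calls$confidence == "high")
  attr(calls, "skipped") <- skipped
  attr(calls, "removed") <- removed
  calls
}

.coverage_from_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr  # returned as GRanges; per-intron extraction happens downstream
}

# per-base counts for one intron: from the coverage list / GRanges if
# given, otherwise fragment coverage computed from the alignments
.intron_counts <- function(coverage, alignments, row) {
  if (is.null(coverage))
    return(fragment_coverage(alignments, row$chrom, row$start, row$end))
  if (is.list(coverage) && !methods::is(coverage, "GRanges")) {
    v <- coverage[[row$intron_id]]
    return(v)
  }
  cv <- coverage[as.character(GenomicRanges::seqnames(coverage)) ==
                   row$chrom]
  if (length(cv) == 0L) return(NULL)
  out <- numeric(row$end - row$start + 1L)
  keep <- GenomicRanges::start(cv) <= row$end &
    GenomicRanges::end(cv) >= row$start
  cv <- cv[keep]
  for (i in seq_along(cv)) {
    a <- max(GenomicRanges::start(cv)[i], row$start) - row$start + 1L
    b <- min(GenomicRanges::end(cv)[i], row$end) - row$start + 1L
    out[a:b] <- cv$score[i]
  }
  out
}

.collect_calls <- function(tab, periods, genome, pwm, profiles) {
  if (length(tab) == 0L)
    return(data.frame(intron = character(0), intron_id = character(0),
                      gene = character(0), chrom = character(0),
                      site = integer(0), TPM = numeric(0),
                      spanning_reads = integer(0), n_methods = integer(0),
                      method = character(0), support = numeric(0),
                      junction_reads = character(0),
                      spanning_read_pairs = character(0),
                      sawtooth_score = numeric(0),
                      mcmc_probability = numeric(0), fdr = numeric(0),
                      sawtooth_flag = logical(0), motif = character(0),
                      motif_score = numeric(0),
                      recursive_site = integer(0),
                      completed_splicing_junction_reads = integer(0),
                      recursive_index = numeric(0)))
  rows <- lapply(tab, function(rec) {
    iv <- rec$intron
    fmt <- function(v, total) paste0(
      "[", paste(c(v, total), collapse = ","), "]")
    data.frame(
      intron = iv$intron_id, intron_id = iv$intron_id,
      gene = iv$gene_id, chrom = iv$chrom, site = rec$site,
      TPM = iv$TPM, spanning_reads = iv$spanning_reads,
      n_methods = length(rec$methods),
      method = paste(sort(rec$methods), collapse = "+"),
      support = rec$junction_total + rec$pair_total,
      junction_reads = fmt(rec$junction_by_period, rec$junction_total),
      spanning_read_pairs = fmt(rec$pair_by_period, rec$pair_total),
      sawtooth_score = rec$sawtooth_score,
      mcmc_probability = rec$mcmc_probability, fdr = rec$fdr,
      sawtooth_flag = .jump_flag(profiles[[iv$intron_id]], rec$site),
      recursive_site = rec$site,
      completed_splicing_junction_reads = iv$spanning_reads,
      recursive_index = NA_real_,
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  calls$motif <- site_window(genome, calls$chrom, calls$site,
                             "+", pwm)
  calls$motif_score <- NA_real_
  ok <- !is.na(calls$motif)
  if (any(ok))
    calls$motif_score[ok] <- as.numeric(score_sites(calls$motif[ok], pwm))
  calls
}

# automated sawtooth-presence check: fitted density just downstream of
# the call at least 1.5-fold the upstream fit, on the binned profile
.jump_flag <- function(profile, site, min_jump = 1.5) {
  if (is.null(profile)) return(NA)
  s <- round((site - profile$start + 1L) / profile$bin_size)
  B <- length(profile$bins)
  if (s < 2L || s > B - 2L) return(NA)
  up <- heteroscedastic_regression(profile$bins[1:s], x = 0:(s - 1L))
  dn <- heteroscedastic_regression(profile$bins[(s + 1L):B], x = s:(B - 1L))
  pu <- up$intercept + up$slope * s
  pd <- dn$intercept + dn$slope * s
  if (pu <= 0) pd > 0 else pd >= min_jump * pu
}
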