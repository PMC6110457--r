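# Seed-deterministic generators emulating the signals each detector
# assumes: sawtooth coverage decay, junction reads across recursive
# sites, insert-length-distributed spanning pairs, lariat reads, and
# progressive-labeling junction counts.

# consensus used when planting recursive elements and annotated splice
# sites: polypyrimidine 3'SS window ending in AG, then a donor starting
# with GT.  Chosen so PWMs trained on the synthetic annotation score
# planted sites near 1 and background AGGTs low.
.RS_CONSENSUS_3SS <- "TTTCTTTTTCTTTCTTTCAG"
.RS_CONSENSUS_5SS <- "GTAAGT"

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

#' Specify a simulated recursive intron
#'
#' @param length intron length (nt).
#' @param sites recursive-site offsets within the intron (1-based,
#'   strictly increasing, each at least 1 kb from the intron ends and
#'   from each other).  The offset marks the first base of the planted
#'   GT.
#' @param start_density expected reads per nt at the start of each
#'   segment (recycled to `length(sites) + 1` segments).
#' @param decay fraction of the start density remaining at the segment
#'   end; the fold jump at a site is
#'   `start_density[k+1] / (start_density[k] * decay)` and must be at
#'   least 1.5.
#' @param frag_mean,frag_sd fragment-length distribution (normal).
#' @param noise_scale variance-to-mean ratio of the count noise; 0
#'   yields the exact linear expectation, 1 is Poisson.
#' @param motif_mismatches random substitutions applied to the planted
#'   26-nt consensus element (outside the central AG|GT).
#' @param seed integer seed or NULL.
#' @return a `sawtooth_spec` list, validated.
#' @export
sawtooth_spec <- function(length, sites = integer(0), start_density = 20,
                          decay = 0.5, frag_mean = 300, frag_sd = 50,
                          noise_scale = 1, motif_mismatches = 1L,
                          seed = NULL) {
  sites <- as.integer(sort(sites))
  nseg <- length(sites) + 1L
  start_density <- rep_len(start_density, nseg)
  if (any(start_density <= 0)) stop("segment densities must be positive")
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]")
  bounds <- c(1L, sites, length + 1L)
  if (any(diff(bounds) < 1000L))
    stop("recursive sites must be >= 1 kb from neighbors and intron ends")
  if (length(sites)) {
    jump <- start_density[-1L] / (start_density[-nseg] * decay)
    if (any(jump < 1.5))
      stop("segment densities violate the 1.5-fold jump at a planted site")
  }
  structure(list(length = as.integer(length), sites = sites,
                 start_density = start_density, decay = decay,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 noise_scale = noise_scale,
                 motif_mismatches = as.integer(motif_mismatches),
                 seed = seed),
            class = "sawtooth_spec")
}

#' Expected sawtooth coverage for a spec
#'
#' Linear decay within each recursive segment from the segment's start
#' density down to `decay` times it, restarting at each planted site.
#'
#' @param spec a [sawtooth_spec()].
#' @return numeric vector of per-base expectations, length `spec$length`.
#' @export
sawtooth_expectation <- function(spec) {
  bounds <- c(1L, spec$sites, spec$length + 1L)
  ex <- numeric(spec$length)
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L] - 1L
    d <- spec$start_density[k]
    frac <- if (b > a) (seq(a, b) - a) / (b - a) else 0
    ex[a:b] <- d * (1 - (1 - spec$decay) * frac)
  }
  ex
}

#' Simulate sawtooth coverage and the matching intron sequence
#'
#' Draws per-base counts around the piecewise-linear expectation (count
#' variance proportional to the mean) and builds a random intron
#' sequence with the 26-nt recursive element planted at each site.
#' Background AG|GT occurrences within 50 nt of a planted site are
#' scrubbed by single-base substitution so decoy density near planted
#' sites is controlled.
#'
#' @param spec a [sawtooth_spec()].
#' @return list with `coverage` (numeric; exact expectation when
#'   `noise_scale == 0`), `expected`, `sequence` (character), `sites`.
#' @export
simulate_sawtooth_coverage <- function(spec) {
  .with_seed(spec$seed, {
    ex <- sawtooth_expectation(spec)
    cov <- if (spec$noise_scale == 0) ex else
      rpois(spec$length, ex / spec$noise_scale) * spec$noise_scale
    seq <- .rand_dna(spec$length)
    for (s in spec$sites) {
      el <- .noisy_element(spec$motif_mismatches)
      substr(seq, s - 20L, s + 5L) <- el
    }
    seq <- .scrub_aggt(seq, spec$sites, window = 50L)
    list(coverage = cov, expected = ex, sequence = seq,
         sites = spec$sites)
  })
}

.noisy_element <- function(mismatches) {
  el <- strsplit(paste0(.RS_CONSENSUS_3SS, .RS_CONSENSUS_5SS), "")[[1L]]
  mutable <- setdiff(seq_along(el), 19:22)  # keep the AG|GT center
  if (mismatches > 0L) {
    at <- sample(mutable, min(mismatches, length(mutable)))
    el[at] <- vapply(el[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  }
  paste(el, collapse = "")
}

# replace the G of GT in stray AGGTs near (but not at) planted sites
.scrub_aggt <- function(seq, sites, window = 50L) {
  repeat {
    hits <- Biostrings::start(
      Biostrings::matchPattern("AGGT", Biostrings::DNAString(seq)))
    cand <- hits + 2L  # site coordinate of each occurrence
    bad <- cand[vapply(cand, function(p)
      any(abs(p - sites) <= window) && !(p %in% sites), logical(1L))]
    if (length(bad) == 0L) return(seq)
    for (p in bad) substr(seq, p, p) <- "C"
  }
}

#' Simulate read pairs spanning a recursive junction
#'
#' Each pair has read 1 ending upstream of the donor and read 2 inside
#' the intron downstream of the true site; the implied insert (portion
#' before the donor plus portion after the site) is drawn from the
#' fragment-length distribution.
#'
#' @param n_pairs number of pairs.
#' @param donor 5' splice-site coordinate (first intronic base).
#' @param site true recursive-site coordinate.
#' @param frag_mean,frag_sd normal fragment-length parameters; `frag_sd
#'   = 0` gives every pair exactly `frag_mean`.
#' @param read_len read length (nt).
#' @param chrom chromosome name.
#' @param period labeling-period label.
#' @param prefix read-id prefix.
#' @param seed integer seed or NULL.
#' @return alignment-table data.frame (two rows per pair, CIGAR
#'   `<read_len>M`), with attribute `pairs` (one row per pair with the
#'   drawn fragment length).
#' @export
simulate_read_pairs <- function(n_pairs, donor, site, frag_mean = 300,
                                frag_sd = 50, read_len = 50L,
                                chrom = "chrS", period = "pooled",
                                prefix = "pair", seed = NULL) {
  .with_seed(seed, {
    if (n_pairs == 0L) {
      out <- data.frame(read_id = character(0), mate = integer(0),
                        chrom = character(0), pos = integer(0),
                        cigar = character(0), strand = character(0),
                        unique = logical(0), period = character(0),
                        stringsAsFactors = FALSE)
      attr(out, "pairs") <- data.frame()
      return(out)
    }
    fl <- if (frag_sd == 0) rep(frag_mean, n_pairs) else
      round(rnorm(n_pairs, frag_mean, frag_sd))
    fl <- pmax(fl, 2L * read_len + 2L)
    u <- vapply(fl, function(f)
      sample(seq(read_len, f - read_len), 1L), numeric(1L))
    r1s <- as.integer(donor - u)
    r2e <- as.integer(site + (fl - u) - 1L)
    ids <- sprintf("%s%04d", prefix, seq_len(n_pairs))
    out <- data.frame(
      read_id = rep(ids, each = 2L),
      mate = rep(c(1L, 2L), n_pairs),
      chrom = chrom,
      pos = as.integer(rbind(r1s, r2e - read_len + 1L)),
      cigar = sprintf("%dM", read_len),
      strand = rep(c("+", "-"), n_pairs),
      unique = TRUE, period = period, stringsAsFactors = FALSE)
    attr(out, "pairs") <- data.frame(read_id = ids, fragment = fl,
                                     read1_start = r1s, read2_end = r2e,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Simulate split junction reads across a splice gap
#'
#' @param counts named integer vector: reads per labeling period.
#' @param gap_start,gap_end removed interval (1-based closed), e.g.
#'   donor .. site-1 for a 5'SS-RS junction.
#' @param read_len read length.
#' @param chrom chromosome.
#' @param prefix read-id prefix.
#' @param seed integer seed or NULL.
#' @return alignment-table rows with `<m>M<gap>N<read_len-m>M` CIGARs.
#' @export
simulate_junction_reads <- function(counts, gap_start, gap_end,
                                    read_len = 50L, chrom = "chrS",
                                    prefix = "jx", seed = NULL) {
  .with_seed(seed, {
    n <- sum(counts)
    if (n == 0L) return(data.frame())
    m1 <- sample(seq(10L, read_len - 10L), n, replace = TRUE)
    gap <- gap_end - gap_start + 1L
    data.frame(
      read_id = sprintf("%s%04d", prefix, seq_len(n)),
      mate = 1L, chrom = chrom,
      pos = as.integer(gap_start - m1),
      cigar = sprintf("%dM%dN%dM", m1, gap, read_len - m1),
      strand = "+", unique = TRUE,
      period = rep(names(counts), counts), stringsAsFactors = FALSE)
  })
}

#' Simulate incomplete/complete junction counts across labeling periods
#'
#' Counts follow the progressive-labeling completed fraction
#' `theta(t) = 1 - (1 - exp(-lambda t)) / (lambda t)` at the stated
#' sequencing depth (binomial draws).
#'
#' @param half_life_min splicing half-life (minutes); 0 and `Inf` give
#'   the all-complete / all-incomplete boundaries.
#' @param labeling_periods labeling durations (minutes).
#' @param depth reads per period.
#' @param seed integer seed or NULL.
#' @return data.frame with `period`, `ee_count` (complete), `ie_count`
#'   (incomplete) and the generating `theta`.
#' @export
simulate_labeling_counts <- function(half_life_min,
                                     labeling_periods = c(5, 10, 20),
                                     depth = 1e4, seed = NULL) {
  .with_seed(seed, {
    lambda <- log(2) / half_life_min
    th <- theta_completed(lambda, labeling_periods)
    ee <- rbinom(length(labeling_periods), depth, th)
    data.frame(period = as.character(labeling_periods),
               ee_count = ee, ie_count = as.integer(depth) - ee,
               theta = th, stringsAsFactors = FALSE)
  })
}

#' Construct a branchpoint-spanning (lariat) read
#'
#' The read is the sequence ending at the branchpoint concatenated with
#' the sequence starting at the donor (or recursive site), the
#' signature of reading across the 5'SS-branchpoint junction of an
#' excised lariat.
#'
#' @param genome `DNAStringSet`.
#' @param chrom chromosome.
#' @param donor donor (5'SS or recursive-site) coordinate: first base
#'   of the downstream half.
#' @param branchpoint branchpoint coordinate: last base of the upstream
#'   half.
#' @param len_up,len_down half lengths (the finder requires >= 15 nt).
#' @param mismatches_per_half random substitutions planted in each half.
#' @param seed integer seed or NULL.
#' @return list with `read` (character), `split_at` (1-based position in
#'   the read where the donor half begins), `donor`, `branchpoint`.
#' @export
simulate_lariat_read <- function(genome, chrom, donor, branchpoint,
                                 len_up = 25L, len_down = 26L,
                                 mismatches_per_half = 0L, seed = NULL) {
  .with_seed(seed, {
    up <- as.character(Biostrings::subseq(
      genome[[chrom]], branchpoint - len_up + 1L, branchpoint))
    dn <- as.character(Biostrings::subseq(
      genome[[chrom]], donor, donor + len_down - 1L))
    if (mismatches_per_half > 0L) {
      up <- .mutate_string(up, mismatches_per_half)
      dn <- .mutate_string(dn, mismatches_per_half)
    }
    list(read = paste0(up, dn), split_at = len_up + 1L,
         donor = donor, branchpoint = branchpoint)
  })
}

.mutate_string <- function(s, k) {
  at <- sample(nchar(s), k)
  for (p in at) {
    b <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }
  s
}

#' Simulate a complete recursive-splicing experiment
#'
#' Builds a one-chromosome genome of two-exon genes, plants recursive
#' sites (with sawtooth coverage, junction reads and spanning pairs) in
#' some introns and leaves the rest as single-segment decoys, so the
#' full detection pipeline can run end to end offline.
#'
#' @param n_recursive,n_decoy gene counts.
#' @param intron_length intron lengths, recycled over recursive genes.
#' @param decoy_length intron lengths for decoys.
#' @param junction_counts named per-period 5'SS-RS junction read counts
#'   per recursive intron.
#' @param rs3_counts per-period RS-3'SS junction read counts.
#' @param full_counts per-period complete 5'SS-3'SS junction reads (all
#'   introns; feeds the spanning-read filter).
#' @param n_pairs spanning read pairs per recursive intron.
#' @param n_bg_pairs exonic background pairs (fragment-length training).
#' @param start_density,decay coverage model, see [sawtooth_spec()].
#' @param frag_mean,frag_sd fragment-length distribution.
#' @param tpm expression assigned to every gene.
#' @param seed integer seed.
#' @return list with `genome` (`DNAStringSet`), `annotation`
#'   (`GenomeAnnotation`), `alignments` (alignment table), `coverage`
#'   (named list of per-base intronic coverage keyed by intron id),
#'   `expression` (gene_id/TPM), and `truth` (planted sites per intron).
#' @export
simulate_ratchet_experiment <- function(
    n_recursive = 5L, n_decoy = 5L, intron_length = 12000L,
    decoy_length = 10000L,
    junction_counts = c("5" = 4L, "10" = 6L, "20" = 8L),
    rs3_counts = c("5" = 3L, "10" = 4L, "20" = 5L),
    full_counts = c("5" = 2L, "10" = 3L, "20" = 4L),
    n_pairs = 30L, n_bg_pairs = 150L,
    start_density = 20, decay = 0.5, frag_mean = 300, frag_sd = 50,
    tpm = 50, seed = 1L) {
  .with_seed(seed, {
    n_genes <- n_recursive + n_decoy
    ex1 <- 600L; ex2 <- 300L; spacer <- 500L
    ilen <- c(rep_len(as.integer(intron_length), n_recursive),
              rep_len(as.integer(decoy_length), n_decoy))
    chrom_seq <- character(0)
    offset <- 0L
    exons <- list(); truth <- list(); covs <- list(); aln <- list()
    for (g in seq_len(n_genes)) {
      recursive <- g <= n_recursive
      L <- ilen[g]
      site_off <- if (recursive) as.integer(round(L / 2)) else integer(0)
      spec <- sawtooth_spec(L, sites = site_off,
                            start_density = start_density, decay = decay,
                            frag_mean = frag_mean, frag_sd = frag_sd,
                            seed = NULL)
      sim <- simulate_sawtooth_coverage(spec)
      iseq <- sim$sequence
      # annotated splice sites carry the training consensus
      substr(iseq, 1L, 6L) <- .noisy_element(1L) |> substr(21L, 26L)
      substr(iseq, L - 19L, L) <- .noisy_element(1L) |> substr(1L, 20L)
      gene_seq <- paste0(.rand_dna(ex1), iseq, .rand_dna(ex2))
      gstart <- offset + spacer + 1L
      i_s <- gstart + ex1            # first intronic base (donor)
      i_e <- i_s + L - 1L
      gid <- sprintf("g%02d", g)
      exons[[g]] <- GenomicRanges::GRanges(
        "chrS", IRanges::IRanges(c(gstart, i_e + 1L),
                                 c(i_s - 1L, i_e + ex2)),
        strand = "+", tx_id = paste0(gid, ".t1"), gene_id = gid)
      intron_id <- sprintf("chrS:%d-%d:+", i_s, i_e)
      covs[[intron_id]] <- sim$coverage
      rows <- list()
      rows$full <- simulate_junction_reads(
        full_counts, i_s, i_e, chrom = "chrS",
        prefix = paste0(gid, "_ee"))
      if (recursive) {
        site <- i_s + site_off - 1L
        truth[[gid]] <- data.frame(gene_id = gid, intron_id = intron_id,
                                   site = site, stringsAsFactors = FALSE)
        rows$jx <- simulate_junction_reads(
          junction_counts, i_s, site - 1L, chrom = "chrS",
          prefix = paste0(gid, "_jx"))
        rows$rs3 <- simulate_junction_reads(
          rs3_counts, site, i_e, chrom = "chrS",
          prefix = paste0(gid, "_rs3"))
        rows$pairs <- simulate_read_pairs(
          n_pairs, donor = i_s, site = site, frag_mean = frag_mean,
          frag_sd = frag_sd, chrom = "chrS",
          prefix = paste0(gid, "_sp"))
        # unspliced reads straddling the site (incomplete evidence)
        ie <- junction_counts + 2L
        m <- sum(ie)
        rows$body <- data.frame(
          read_id = sprintf("%s_ie%03d", gid, seq_len(m)),
          mate = 1L, chrom = "chrS",
          pos = as.integer(site - sample(10:40, m, replace = TRUE)),
          cigar = "50M", strand = "+", unique = TRUE,
          period = rep(names(ie), ie), stringsAsFactors = FALSE)
      }
      # background exonic pairs for the fragment-length histogram
      nb <- ceiling(n_bg_pairs / n_genes)
      fl <- pmax(round(rnorm(nb, frag_mean, frag_sd)), 102L)
      x <- gstart + as.integer(runif(nb, 0, ex1 - max(fl) - 1L))
      rows$bg <- data.frame(
        read_id = rep(sprintf("%s_bg%03d", gid, seq_len(nb)), each = 2L),
        mate = rep(c(1L, 2L), nb), chrom = "chrS",
        pos = as.integer(rbind(x, x + fl - 50L)),
        cigar = "50M", strand = rep(c("+", "-"), nb), unique = TRUE,
        period = "pooled", stringsAsFactors = FALSE)
      aln[[g]] <- do.call(rbind, lapply(unname(rows), function(d)
        d[c("read_id", "mate", "chrom", "pos", "cigar", "strand",
            "unique", "period")]))
      chrom_seq <- c(chrom_seq, .rand_dna(spacer), gene_seq)
      offset <- gstart + ex1 + L + ex2 - 1L
    }
    chrom_seq <- c(chrom_seq, .rand_dna(spacer))
    genome <- Biostrings::DNAStringSet(paste(chrom_seq, collapse = ""))
    names(genome) <- "chrS"
    ann <- load_annotation(do.call(c, exons))
    list(genome = genome, annotation = ann,
         alignments = do.call(rbind, aln), coverage = covs,
         expression = data.frame(gene_id = sprintf("g%02d",
                                                   seq_len(n_genes)),
                                 TPM = tpm, stringsAsFactors = FALSE),
         truth = if (length(truth)) do.call(rbind, unname(truth))
                 else data.frame())
  })
}

#' Write an experiment's fixtures to disk (FASTA, GFF3, TSV, bedGraph)
#'
#' @param expt result of [simulate_ratchet_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_experiment <- function(expt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gff3"),
             alignments = file.path(dir, "alignments.tsv"),
             expression = file.path(dir, "expression.tsv"),
             coverage = file.path(dir, "coverage.bedgraph"))
  Biostrings::writeXStringSet(expt$genome, paths["genome"])
  ex <- expt$annotation$exons
  ex$type <- "exon"
  ex$Parent <- ex$tx_id
  rtracklayer::export(ex, paths["annotation"], format = "gff3")
  write.table(expt$alignments, paths["alignments"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(expt$expression, paths["expression"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cov <- do.call(c, lapply(names(expt$coverage), function(id) {
    p <- strsplit(id, "[:-]")[[1L]]
    s <- as.integer(p[2L])
    GenomicRanges::GRanges(p[1L],
      IRanges::IRanges(s:(s + length(expt$coverage[[id]]) - 1L),
                       width = 1L),
      score = as.numeric(expt$coverage[[id]]))
  }))
  rtracklayer::export(cov, paths["coverage"], format = "bedGraph")
  invisible(paths)
}
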