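#' Build juxtaposed splice-site position weight matrices
#'
#' Tallies the intronic portions of all annotated splice sites: the 3'
#' splice-site window (`a3` nt ending in AG at the intron end) and the
#' 5' splice-site window (`a5` nt starting with GT at the intron
#' start), strand-corrected.  The juxtaposed recursive-site matrix is
#' the 3'SS columns followed by the 5'SS columns, so a perfect
#' recursive element reads `...AG|GT...` across the center.
#'
#' @param annotation `GenomeAnnotation` with at least one intron.
#' @param genome `DNAStringSet` (or FASTA path).
#' @param a3,a5 intronic window widths for the 3'SS and 5'SS portions.
#'   Defaults (20 and 6) are typical intronic extents for compact
#'   invertebrate splice-site models; both are configurable.
#' @param pseudocount added per base per column before normalization.
#' @return A `SpliceSitePWM`: probability matrices `three`, `five`,
#'   `juxtaposed` (4 x width, rows A/C/G/T), the log2 matrix `logp`,
#'   and the attainable `min_score` / `max_score` bit-score bounds.
#' @export
build_pwms <- function(annotation, genome, a3 = 20L, a5 = 6L,
                       pseudocount = 1) {
  genome <- load_genome(genome)
  intr <- annotation$introns
  if (length(intr) == 0L) stop("annotation has no introns; cannot build PWMs")
  keep <- GenomicRanges::width(intr) >= (a3 + a5)
  intr <- intr[keep]
  if (length(intr) == 0L) stop("no intron long enough for the PWM windows")
  minus <- as.character(GenomicRanges::strand(intr)) == "-"
  ch <- as.character(GenomicRanges::seqnames(intr))
  s <- GenomicRanges::start(intr); e <- GenomicRanges::end(intr)
  # transcription-sense first a5 bases and last a3 bases of each intron
  five_f <- ifelse(minus, e - a5 + 1L, s)
  three_f <- ifelse(minus, s, e - a3 + 1L)
  five_w <- .fetch_windows(genome, ch, five_f, a5, minus)
  three_w <- .fetch_windows(genome, ch, three_f, a3, minus)
  three <- .count_pwm(three_w, pseudocount)
  five <- .count_pwm(five_w, pseudocount)
  new_pwm(three, five)
}

new_pwm <- function(three, five) {
  jux <- cbind(three, five)
  stopifnot(all(abs(colSums(jux) - 1) < 1e-9))
  logp <- log2(jux)
  structure(list(
    three = three, five = five, juxtaposed = jux, logp = logp,
    a3 = ncol(three), a5 = ncol(five),
    min_score = sum(apply(logp, 2L, min)),
    max_score = sum(apply(logp, 2L, max))
  ), class = "SpliceSitePWM")
}

#' @export
print.SpliceSitePWM <- function(x, ...) {
  cat("SpliceSitePWM: 3'SS width", x$a3, "+ 5'SS width", x$a5,
      sprintf("| bit score range [%.2f, %.2f]\n", x$min_score, x$max_score))
  invisible(x)
}

.fetch_windows <- function(genome, chrom, start, width, minus) {
  w <- Biostrings::DNAStringSet(rep("", length(start)))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    w[i] <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(start[i], width = width))
  }
  if (any(minus))
    w[minus] <- Biostrings::reverseComplement(w[minus])
  w
}

.count_pwm <- function(windows, pseudocount) {
  cm <- Biostrings::consensusMatrix(windows)[c("A", "C", "G", "T"), ,
                                             drop = FALSE]
  cm <- cm + pseudocount
  sweep(cm, 2L, colSums(cm), "/")
}

#' Score candidate windows with the normalized bit score
#'
#' The bit score of a window is the sum over columns of the log2
#' probability of its base; the normalized score is
#' `(bits - min) / (max - min)` where min/max are the extreme
#' attainable bit scores, so scores always lie in `[0, 1]` and the
#' per-column consensus scores exactly 1.  Ambiguous bases (N)
#' contribute the column minimum.
#'
#' @param windows character vector or `DNAStringSet`, each of width
#'   `pwm$a3 + pwm$a5`, already strand-corrected (transcription sense).
#' @param pwm `SpliceSitePWM`.
#' @return numeric vector of scores in `[0, 1]`, with attribute
#'   `canonical_center` flagging windows whose center reads `AG|GT`.
#' @export
score_sites <- function(windows, pwm) {
  windows <- toupper(as.character(windows))
  wlen <- pwm$a3 + pwm$a5
  if (any(nchar(windows) != wlen))
    stop("window width must equal the juxtaposed PWM width (", wlen, ")")
  colmin <- apply(pwm$logp, 2L, min)
  m <- matrix(unlist(strsplit(windows, "")), nrow = wlen)
  bits <- vapply(seq_along(windows), function(i) {
    ri <- match(m[, i], rownames(pwm$logp))
    ok <- !is.na(ri)
    v <- colmin
    v[ok] <- pwm$logp[cbind(ri[ok], which(ok))]
    sum(v)
  }, numeric(1L))
  sc <- (bits - pwm$min_score) / (pwm$max_score - pwm$min_score)
  attr(sc, "canonical_center") <-
    substr(windows, pwm$a3 - 1L, pwm$a3) == "AG" &
    substr(windows, pwm$a3 + 1L, pwm$a3 + 2L) == "GT"
  sc
}

#' Extract the juxtaposed motif window around a recursive-site candidate
#'
#' The site coordinate is the first base of the GT on the transcribed
#' strand (for minus-strand sites, the forward-strand coordinate whose
#' complement is that G).  Windows are returned in transcription sense.
#'
#' @param genome `DNAStringSet`.
#' @param chrom chromosome name (recycled).
#' @param site integer vector of site coordinates.
#' @param strand "+" or "-" (recycled).
#' @param pwm `SpliceSitePWM` supplying the window geometry.
#' @return character vector of windows (NA where out of range).
#' @export
site_window <- function(genome, chrom, site, strand, pwm) {
  n <- length(site)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  minus <- strand == "-"
  start <- ifelse(minus, site - pwm$a5 + 1L, site - pwm$a3)
  lens <- setNames(Biostrings::width(genome), names(genome))
  ok <- start >= 1L & (start + pwm$a3 + pwm$a5 - 1L) <= lens[chrom]
  out <- rep(NA_character_, n)
  if (any(ok)) {
    w <- .fetch_windows(genome, chrom[ok], start[ok], pwm$a3 + pwm$a5,
                        minus[ok])
    out[ok] <- as.character(w)
  }
  out
}

#' Find all AG|GT recursive-site candidates in a region
#'
#' @param genome `DNAStringSet`.
#' @param chrom chromosome.
#' @param start,end region (1-based closed).
#' @param strand strand of the host transcript.
#' @return integer vector of site coordinates (first base of GT on the
#'   transcribed strand, forward-genome coordinates).
#' @export
scan_aggt <- function(genome, chrom, start, end, strand = "+") {
  seq <- Biostrings::subseq(genome[[chrom]], start, end)
  pat <- if (strand == "-") "ACCT" else "AGGT"
  hits <- Biostrings::matchPattern(pat, seq)
  p <- Biostrings::start(hits) + start - 1L
  if (strand == "-") p + 1L else p + 2L
}

#' Build a transcription-sense donor (5'SS) PWM of arbitrary width
#'
#' Used by the lariat finder, which scans reads for the 7-mer best
#' matching the donor consensus.
#'
#' @inheritParams build_pwms
#' @param width number of intronic columns starting at the GT.
#' @return 4 x width probability matrix (rows A/C/G/T) with attributes
#'   `logp`, `min_score`, `max_score`.
#' @export
build_donor_pwm <- function(annotation, genome, width = 7L,
                            pseudocount = 1) {
  genome <- load_genome(genome)
  intr <- annotation$introns
  intr <- intr[GenomicRanges::width(intr) >= width]
  if (length(intr) == 0L) stop("no intron long enough for the donor PWM")
  minus <- as.character(GenomicRanges::strand(intr)) == "-"
  ch <- as.character(GenomicRanges::seqnames(intr))
  s <- GenomicRanges::start(intr); e <- GenomicRanges::end(intr)
  f <- ifelse(minus, e - width + 1L, s)
  m <- .count_pwm(.fetch_windows(genome, ch, f, width, minus), pseudocount)
  lp <- log2(m)
  attr(m, "logp") <- lp
  attr(m, "min_score") <- sum(apply(lp, 2L, min))
  attr(m, "max_score") <- sum(apply(lp, 2L, max))
  m
}

#' Serialize / deserialize a SpliceSitePWM as plain text
#' @param pwm `SpliceSitePWM`.
#' @param path file path.
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(t(pwm$juxtaposed))
  df <- cbind(position = seq_len(nrow(df)),
              part = rep(c("threess", "fivess"), c(pwm$a3, pwm$a5)), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  m <- t(as.matrix(df[c("A", "C", "G", "T")]))
  new_pwm(m[, df$part == "threess", drop = FALSE],
          m[, df$part == "fivess", drop = FALSE])
}
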