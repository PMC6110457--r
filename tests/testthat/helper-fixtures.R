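# shared in-code fixtures

# three-transcript toy annotation on two strands
toy_exons <- function() {
  GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(
      c(101, 301, 101, 501, 2101, 2401),
      c(200, 400, 200, 600, 2200, 2500)),
    strand = c("+", "+", "+", "+", "-", "-"),
    tx_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g2"))
}

# random genome with a fixed seed, as a DNAStringSet
toy_genome <- function(len = 3000L, seed = 99L, name = "chr1") {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  names(g) <- name
  g
}

# a minimal alignment table row
aln_row <- function(read_id, pos, cigar, mate = 1L, chrom = "chr1",
                    strand = "+", unique = TRUE, period = "pooled") {
  data.frame(read_id = read_id, mate = mate, chrom = chrom, pos = pos,
             cigar = cigar, strand = strand, unique = unique,
             period = period, stringsAsFactors = FALSE)
}

# independent PWM tally used as the counting oracle: plain character
# bookkeeping, no Biostrings
oracle_pwm_counts <- function(windows, pseudocount = 1) {
  wlen <- nchar(windows[1L])
  m <- matrix(pseudocount, 4L, wlen,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (w in windows) for (j in seq_len(wlen)) {
    b <- substr(w, j, j)
    m[b, j] <- m[b, j] + 1
  }
  sweep(m, 2L, colSums(m), "/")
}

# hypergeometric upper-tail by direct summation (Fisher oracle)
oracle_fisher_greater <- function(a, b, cc, d) {
  # P(X >= a) for X ~ Hypergeom(white = a+b? no: margins fixed)
  m <- a + cc; n <- b + d; k <- a + b
  xs <- max(0L, k - n):min(k, m)
  p <- sum(vapply(xs[xs >= a], function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)),
    numeric(1L)))
  p
}
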