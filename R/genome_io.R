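#' Load a gene annotation and derive introns
#'
#' Reads GFF3/GTF (via rtracklayer) or accepts an exon `GRanges` built
#' in code, and derives one intron per gap between consecutive exons of
#' each transcript.  All coordinates are 1-based closed on the forward
#' genomic strand; strand-aware notions (which end is the 5' splice
#' site) are resolved at use sites.
#'
#' @param x path to a GFF3/GTF file, or a `GRanges` of exons carrying
#'   `tx_id` and `gene_id` metadata columns.
#' @return A `GenomeAnnotation` object: a list with `genes`,
#'   `transcripts` (data frames), `exons`, `introns` (`GRanges`; introns
#'   carry `tx_id`, `gene_id`, `intron_id`, `donor`, `acceptor`), and
#'   `donor_sites` / `acceptor_sites` (integer positions per chromosome
#'   of the first / last intronic base of each annotated intron).
#' @examples
#' ex <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 301), c(200, 400)),
#'   strand = "+", tx_id = "t1", gene_id = "g1")
#' ann <- load_annotation(ex)
#' ann$introns   # one intron, 201-300
#' @export
load_annotation <- function(x) {
  exons <- if (is.character(x)) .import_exons(x) else .as_exon_granges(x)
  .validate_exons(exons)
  introns <- derive_introns(exons)
  tx <- unique(data.frame(
    tx_id = exons$tx_id, gene_id = exons$gene_id,
    stringsAsFactors = FALSE))
  genes <- unique(data.frame(
    gene_id = exons$gene_id,
    chrom = as.character(GenomicRanges::seqnames(exons)),
    strand = as.character(GenomicRanges::strand(exons)),
    stringsAsFactors = FALSE))
  structure(list(
    genes = genes,
    transcripts = tx,
    exons = exons,
    introns = introns,
    donor_sites = unique(data.frame(
      chrom = as.character(GenomicRanges::seqnames(introns)),
      pos = introns$donor, strand = as.character(GenomicRanges::strand(introns)),
      stringsAsFactors = FALSE)),
    acceptor_sites = unique(data.frame(
      chrom = as.character(GenomicRanges::seqnames(introns)),
      pos = introns$acceptor, strand = as.character(GenomicRanges::strand(introns)),
      stringsAsFactors = FALSE))
  ), class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      length(x$exons), "exons,", length(x$introns), "introns\n")
  invisible(x)
}

.import_exons <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("annotation contains no exon features")
  md <- S4Vectors::mcols(gr)
  tx_id <- if ("transcript_id" %in% names(md)) {
    as.character(md$transcript_id)
  } else if ("Parent" %in% names(md)) {
    p <- md$Parent
    if (any(lengths(p) != 1L)) {
      bad <- which(lengths(p) != 1L)[1L]
      stop("exon feature #", bad, " has ", lengths(p)[bad],
           " Parent attributes; expected exactly one transcript parent")
    }
    as.character(unlist(p))
  } else stop("exon features carry neither transcript_id nor Parent")
  gene_id <- if ("gene_id" %in% names(md)) {
    as.character(md$gene_id)
  } else sub("\\.t[0-9]+$|\\.[0-9]+$", "", tx_id)
  out <- GenomicRanges::granges(gr)
  out$tx_id <- tx_id
  out$gene_id <- gene_id
  out
}

.as_exon_granges <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  if (is.null(gr$tx_id) || is.null(gr$gene_id))
    stop("exon GRanges must carry tx_id and gene_id metadata columns")
  gr
}

.validate_exons <- function(exons) {
  if (any(is.na(exons$tx_id)))
    stop("orphan exon without a transcript parent at index ",
         which(is.na(exons$tx_id))[1L])
  sp <- split(exons, exons$tx_id)
  for (i in seq_along(sp)) {
    e <- sp[[i]]
    o <- order(GenomicRanges::start(e))
    if (length(e) > 1L &&
        any(GenomicRanges::start(e)[o][-1L] <=
            GenomicRanges::end(e)[o][-length(e)])) {
      stop("overlapping or unsorted exons in transcript ", names(sp)[i])
    }
  }
  invisible(TRUE)
}

#' Derive introns as gaps between consecutive exons of each transcript
#'
#' @param exons exon `GRanges` with `tx_id`, `gene_id` metadata.
#' @return intron `GRanges` with `tx_id`, `gene_id`, `intron_id`,
#'   `donor` (first intronic base in transcription direction) and
#'   `acceptor` (last intronic base in transcription direction).
#' @export
derive_introns <- function(exons) {
  pieces <- lapply(split(seq_along(exons), exons$tx_id), function(idx) {
    e <- exons[idx]
    e <- e[order(GenomicRanges::start(e))]
    if (length(e) < 2L) return(NULL)
    s <- GenomicRanges::end(e)[-length(e)] + 1L
    en <- GenomicRanges::start(e)[-1L] - 1L
    if (any(en < s)) stop("zero-length intron in transcript ", e$tx_id[1L])
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(e)[1L], IRanges::IRanges(s, en),
      strand = GenomicRanges::strand(e)[1L],
      tx_id = e$tx_id[1L], gene_id = e$gene_id[1L])
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (length(pieces) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$tx_id <- character(0); gr$gene_id <- character(0)
    gr$intron_id <- character(0); gr$donor <- integer(0); gr$acceptor <- integer(0)
    return(gr)
  }
  introns <- do.call(c, unname(pieces))
  minus <- as.character(GenomicRanges::strand(introns)) == "-"
  introns$donor <- ifelse(minus, GenomicRanges::end(introns),
                          GenomicRanges::start(introns))
  introns$acceptor <- ifelse(minus, GenomicRanges::start(introns),
                             GenomicRanges::end(introns))
  introns$intron_id <- sprintf(
    "%s:%d-%d:%s", as.character(GenomicRanges::seqnames(introns)),
    GenomicRanges::start(introns), GenomicRanges::end(introns),
    as.character(GenomicRanges::strand(introns)))
  introns
}

#' Load a genome FASTA as a DNAStringSet
#' @param path FASTA file path (or a `DNAStringSet`, returned as is).
#' @export
load_genome <- function(path) {
  if (methods::is(path, "DNAStringSet")) return(path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read aligned reads from SAM/BAM or the tab-delimited alignment table
#'
#' The tab-delimited dialect has columns `read_id`, `mate` (1/2),
#' `chrom`, `pos` (1-based leftmost), `cigar`, `strand`, `unique`
#' (0/1), `period` (labeling period label, e.g. "5", "10", "20" or
#' "pooled").  SAM/BAM files are read through Rsamtools on the same
#' code path; uniqueness is taken as MAPQ >= `min_mapq` and the period
#' from the read group (`RG`) when present.
#'
#' @param x path (.sam/.bam/.tsv) or a data frame already in the dialect.
#' @param min_mapq MAPQ threshold for calling an alignment unique.
#' @return data.frame in the dialect above, plus `end` (rightmost
#'   aligned reference base).
#' @export
read_alignments <- function(x, min_mapq = 10L) {
  if (is.data.frame(x)) {
    aln <- x
  } else if (grepl("\\.(sam|bam)$", x, ignore.case = TRUE)) {
    bam <- x
    if (grepl("\\.sam$", x, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(x, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    ga <- GenomicAlignments::readGAlignments(
      bam, use.names = FALSE,
      param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "mapq"), tag = "RG"))
    md <- S4Vectors::mcols(ga)
    aln <- data.frame(
      read_id = md$qname,
      mate = ifelse(bitwAnd(md$flag, 0x80L) > 0L, 2L, 1L),
      chrom = as.character(GenomicAlignments::seqnames(ga)),
      pos = GenomicAlignments::start(ga),
      cigar = GenomicAlignments::cigar(ga),
      strand = as.character(GenomicAlignments::strand(ga)),
      unique = !is.na(md$mapq) & md$mapq >= min_mapq,
      period = if (!is.null(md$RG)) ifelse(is.na(md$RG), "pooled", md$RG)
               else "pooled",
      stringsAsFactors = FALSE)
  } else {
    aln <- read.table(x, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = list(period = "character"))
  }
  need <- c("read_id", "mate", "chrom", "pos", "cigar", "strand",
            "unique", "period")
  miss <- setdiff(need, names(aln))
  if (length(miss)) stop("alignment table missing columns: ",
                         paste(miss, collapse = ", "))
  aln$unique <- as.logical(aln$unique)
  aln$period <- as.character(aln$period)
  aln$end <- aln$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar) - 1L
  aln
}

#' Extract splice junctions from split alignments
#'
#' Walks CIGAR N gaps and aggregates one junction per gap per labeling
#' period.  A junction is the removed interval `[gap_start, gap_end]`
#' (1-based closed); only unique alignments are counted.
#'
#' @param aln alignment table from [read_alignments()].
#' @param region optional `GRanges` restricting junctions to gaps that
#'   lie within it.
#' @return data.frame with `chrom`, `gap_start`, `gap_end`, `period`,
#'   `count`.  Reads without N gaps contribute nothing.
#' @export
extract_junction_reads <- function(aln, region = NULL) {
  aln <- aln[aln$unique, , drop = FALSE]
  empty <- data.frame(chrom = character(0), gap_start = integer(0),
                      gap_end = integer(0), period = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty)
  gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = "N")
  n <- lengths(gaps)
  if (sum(n) == 0L) return(empty)
  flat <- unlist(gaps)
  idx <- rep(seq_len(nrow(aln)), n)
  j <- data.frame(chrom = aln$chrom[idx],
                  gap_start = IRanges::start(flat),
                  gap_end = IRanges::end(flat),
                  period = aln$period[idx],
                  stringsAsFactors = FALSE)
  if (!is.null(region)) {
    gr <- GenomicRanges::GRanges(j$chrom,
                                 IRanges::IRanges(j$gap_start, j$gap_end))
    j <- j[IRanges::overlapsAny(gr, region, type = "within"), , drop = FALSE]
    if (nrow(j) == 0L) return(empty)
  }
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(j))),
    by = j[c("chrom", "gap_start", "gap_end", "period")], FUN = sum)
  agg[order(agg$chrom, agg$gap_start, agg$gap_end, agg$period), ,
      drop = FALSE]
}

#' Per-base fragment coverage over a window
#'
#' Counts, at each position, the number of read pairs whose fragment
#' (leftmost to rightmost aligned base across both mates) straddles the
#' position — pairs spanning a position count as covering it.
#'
#' @param aln alignment table from [read_alignments()].
#' @param chrom,start,end window (1-based closed).
#' @return integer vector of length `end - start + 1`.
#' @export
fragment_coverage <- function(aln, chrom, start, end) {
  aln <- aln[aln$unique & aln$chrom == chrom, , drop = FALSE]
  if (nrow(aln) == 0L) return(integer(end - start + 1L))
  s <- tapply(aln$pos, aln$read_id, min)
  e <- tapply(aln$end, aln$read_id, max)
  ir <- IRanges::IRanges(as.integer(s), as.integer(e))
  cv <- IRanges::coverage(ir, width = max(end, max(IRanges::end(ir))))
  as.integer(cv[start:end])
}

#' Count reads spanning the complete 5'SS to 3'SS junction per intron
#'
#' @param junctions junction table from [extract_junction_reads()].
#' @param annotation `GenomeAnnotation`.
#' @return data.frame with `intron_id` and `spanning_reads` (summed over
#'   labeling periods; exact-coordinate match to the annotated intron).
#' @export
intron_spanning_counts <- function(junctions, annotation) {
  intr <- annotation$introns
  key <- paste(as.character(GenomicRanges::seqnames(intr)),
               GenomicRanges::start(intr), GenomicRanges::end(intr))
  jkey <- paste(junctions$chrom, junctions$gap_start, junctions$gap_end)
  cnt <- tapply(junctions$count, jkey, sum)
  data.frame(intron_id = intr$intron_id,
             spanning_reads = as.integer(ifelse(key %in% names(cnt),
                                                cnt[key], 0L)),
             stringsAsFactors = FALSE)
}

#' Write introns (or any ranges) to BED6
#' @param gr `GRanges`; `intron_id` (if present) becomes the name field.
#' @param path output file ending in `.bed`.
#' @export
write_bed <- function(gr, path) {
  out <- GenomicRanges::granges(gr)
  nm <- if (!is.null(gr$intron_id)) gr$intron_id else
    if (!is.null(names(gr))) names(gr) else rep(".", length(gr))
  out$name <- nm
  out$score <- if (!is.null(gr$score)) gr$score else rep(0L, length(gr))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Write recursive-site calls as a summary TSV
#'
#' Mirrors the standard per-site summary layout: `intron`, `gene`,
#' `TPM`, `completed_splicing_junction_reads`, `recursive_site`,
#' `method`, `high_confidence`, `junction_reads` (per-period comma list
#' `[5m,10m,20m,total]`), `spanning_read_pairs` (same layout),
#' `sawtooth_score`, `mcmc_probability`, `recursive_index` (reserved,
#' emitted as NA), `motif`, `motif_score`.
#'
#' @param calls data.frame of calls from [run_ratchet_pipeline()].
#' @param path output path.
#' @export
write_sites_tsv <- function(calls, path) {
  cols <- c("intron", "gene", "TPM", "completed_splicing_junction_reads",
            "recursive_site", "method", "high_confidence",
            "junction_reads", "spanning_read_pairs", "sawtooth_score",
            "mcmc_probability", "recursive_index", "motif", "motif_score")
  for (cc in setdiff(cols, names(calls))) calls[[cc]] <- NA
  write.table(calls[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
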