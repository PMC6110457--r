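# helper: annotation with fully controlled intron sequences on one
# chromosome; introns long enough for the default 20+6 windows
pwm_fixture <- function(intron_seqs, exon = 50L) {
  seqs <- character(0); exons <- list(); pos <- 0L
  for (i in seq_along(intron_seqs)) {
    iseq <- intron_seqs[i]
    gstart <- pos + 1L
    istart <- gstart + exon
    iend <- istart + nchar(iseq) - 1L
    seqs <- c(seqs, strrep("A", exon), iseq, strrep("A", exon))
    exons[[i]] <- GenomicRanges::GRanges("chrP",
      IRanges::IRanges(c(gstart, iend + 1L), c(istart - 1L, iend + exon)),
      strand = "+", tx_id = sprintf("t%d", i),
      gene_id = sprintf("g%d", i))
    pos <- iend + exon
  }
  g <- Biostrings::DNAStringSet(paste(seqs, collapse = ""))
  names(g) <- "chrP"
  list(genome = g, ann = load_annotation(do.call(c, exons)))
}

mk_intron <- function(first6, last20, mid = 40L)
  paste0(first6, strrep("C", mid), last20)

test_that("degenerate training sets give point-mass columns", {
  fx <- pwm_fixture(rep(mk_intron("GTAAGT", strrep("T", 18) |> paste0("AG")), 4))
  pwm <- build_pwms(fx$ann, fx$genome)
  # every 5'SS window is GTAAGT: each column concentrates on one base
  expect_true(all(apply(pwm$five, 2L, max) == (4 + 1) / (4 + 4)))
  expect_equal(colSums(pwm$juxtaposed), rep(1, 26), tolerance = 1e-12)
})

test_that("a single differing base splits a column 50/50", {
  fx <- pwm_fixture(c(mk_intron("GTAAGT", paste0(strrep("T", 18), "AG")),
                      mk_intron("GTATGT", paste0(strrep("T", 18), "AG"))))
  pwm <- build_pwms(fx$ann, fx$genome)
  col <- pwm$five[, 4L]   # A vs T at donor position 4
  expect_equal(col[["A"]], col[["T"]])
  expect_equal(col[["A"]], (1 + 1) / (2 + 4))
})

test_that("tallied frequencies match an independent counting oracle", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  donors <- vapply(1:10, function(i)
    paste0("GT", paste(sample(bases, 4, TRUE), collapse = "")),
    character(1L))
  acceptors <- vapply(1:10, function(i)
    paste0(paste(sample(bases, 18, TRUE), collapse = ""), "AG"),
    character(1L))
  fx <- pwm_fixture(mapply(mk_intron, donors, acceptors))
  pwm <- build_pwms(fx$ann, fx$genome)
  expect_equal(unname(pwm$five), unname(oracle_pwm_counts(donors)),
               tolerance = 1e-12)
  expect_equal(unname(pwm$three), unname(oracle_pwm_counts(acceptors)),
               tolerance = 1e-12)
})

test_that("normalized bit scores hit 0/1 at anti-consensus/consensus", {
  expt <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 1,
                                      seed = 23)
  pwm <- build_pwms(expt$annotation, expt$genome)
  cons <- paste(rownames(pwm$juxtaposed)[apply(pwm$juxtaposed, 2L,
                                               which.max)],
                collapse = "")
  anti <- paste(rownames(pwm$juxtaposed)[apply(pwm$juxtaposed, 2L,
                                               which.min)],
                collapse = "")
  expect_equal(as.numeric(score_sites(cons, pwm)), 1)
  expect_equal(as.numeric(score_sites(anti, pwm)), 0)
  # all scores bounded in [0, 1] on random windows
  set.seed(1)
  rnd <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 26, TRUE), collapse = ""),
    character(1L))
  sc <- score_sites(rnd, pwm)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("a two-column toy PWM matches closed-form arithmetic", {
  # counts {A:1, C:1} and {G:2}, pseudocount 1 per base
  three <- matrix(c(2, 2, 1, 1) / 6, 4L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  five <- matrix(c(1, 1, 3, 1) / 6, 4L,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- new_pwm(three, five)
  bits <- log2(2 / 6) + log2(3 / 6)
  mn <- log2(1 / 6) + log2(1 / 6)
  mx <- log2(2 / 6) + log2(3 / 6)
  expect_equal(as.numeric(score_sites("AG", pwm)), (bits - mn) / (mx - mn))
  expect_equal(as.numeric(score_sites("AG", pwm)), 1)  # consensus
  expect_equal(as.numeric(score_sites("GA", pwm)), 0)  # anti-consensus
  # monotone: improving one column's base never lowers the score
  expect_lt(as.numeric(score_sites("TG", pwm)),
            as.numeric(score_sites("AG", pwm)))
})

test_that("N bases score as the column minimum", {
  expt <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 1,
                                      seed = 29)
  pwm <- build_pwms(expt$annotation, expt$genome)
  w <- site_window(expt$genome, "chrS", expt$truth$site, "+", pwm)
  wN <- w; substr(wN, 1, 1) <- "N"
  worst <- w
  substr(worst, 1, 1) <- rownames(pwm$logp)[which.min(pwm$logp[, 1])]
  expect_equal(as.numeric(score_sites(wN, pwm)),
               as.numeric(score_sites(worst, pwm)))
  expect_lte(as.numeric(score_sites(wN, pwm)),
             as.numeric(score_sites(w, pwm)))
})

test_that("scores are strand-invariant for strand-corrected windows", {
  # a minus-strand intron whose transcription-sense windows equal a
  # plus-strand intron's windows must score identically
  donor <- "GTAAGT"; acc <- paste0(strrep("T", 18), "AG")
  fx <- pwm_fixture(rep(mk_intron(donor, acc), 3))
  pwm <- build_pwms(fx$ann, fx$genome)
  site_plus <- 500L
  g <- toy_genome(1200, seed = 31, name = "chrM")
  s <- as.character(g[["chrM"]])
  win <- paste0(acc, donor)
  substr(s, site_plus - 20L, site_plus + 5L) <- win
  gp <- Biostrings::DNAStringSet(s); names(gp) <- "chrM"
  wp <- site_window(gp, "chrM", site_plus, "+", pwm)
  # embed the reverse complement elsewhere and read it minus-strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(win)))
  substr(s, 800L, 825L) <- rc
  gm <- Biostrings::DNAStringSet(s); names(gm) <- "chrM"
  # minus-strand site coordinate: forward base complementing the G of GT
  wm <- site_window(gm, "chrM", 800L + 5L, "-", pwm)
  expect_equal(wm, win)
  expect_equal(score_sites(wp, pwm), score_sites(wm, pwm))
})

test_that("AGGT scanning returns site coordinates on both strands", {
  g <- Biostrings::DNAStringSet("CCCAGGTCCCCACCTCCC")
  names(g) <- "c"
  expect_equal(scan_aggt(g, "c", 1, 18, "+"), 6L)   # G of GT
  expect_equal(scan_aggt(g, "c", 1, 18, "-"), 13L)  # ACCT at 12..15
})

test_that("PWMs serialize to text and back", {
  expt <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 1,
                                      seed = 37)
  pwm <- build_pwms(expt$annotation, expt$genome)
  f <- file.path(tempdir(), "pwm.tsv")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back$juxtaposed, pwm$juxtaposed, tolerance = 1e-9)
  expect_equal(back$min_score, pwm$min_score, tolerance = 1e-9)
})
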