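pair_fixture <- function(seed = 51L, ...) {
  simulate_ratchet_experiment(n_recursive = 1, n_decoy = 1, seed = seed,
                              ...)
}

test_that("spanning-pair selection applies the stated geometry gates", {
  expt <- pair_fixture()
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  donor <- iv[1]
  base <- data.frame(read_id = "x", chrom = "chrS",
                     read1_start = donor - 90L, read1_end = donor - 41L,
                     read2_start = donor + 5000L,
                     read2_end = donor + 5049L, period = "pooled",
                     stringsAsFactors = FALSE)
  kept <- select_spanning_pairs(base, expt$annotation)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$donor, donor)
  # read 2 only 600 nt downstream: dropped
  near <- base
  near$read2_start <- donor + 560L; near$read2_end <- donor + 609L
  expect_equal(nrow(select_spanning_pairs(near, expt$annotation)), 0L)
  # read 1 too far upstream of the donor: dropped
  far <- base
  far$read1_start <- donor - 500L; far$read1_end <- donor - 451L
  expect_equal(nrow(select_spanning_pairs(far, expt$annotation)), 0L)
})

test_that("pairs explained by completed annotated splicing are dropped", {
  # pair spanning the entire annotated intron with a short implied
  # insert once the intron is removed
  expt <- pair_fixture(seed = 53L)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  donor <- iv[1]; iend <- iv[2]
  p <- data.frame(read_id = "y", chrom = "chrS",
                  read1_start = donor - 100L, read1_end = donor - 51L,
                  read2_start = iend + 100L, read2_end = iend + 149L,
                  period = "pooled", stringsAsFactors = FALSE)
  expect_equal(nrow(select_spanning_pairs(p, expt$annotation)), 0L)
})

test_that("fragment distribution: point mass, two bins, sampled mean", {
  fd <- new_fragment_distribution(rep(300L, 80), bw = 0)
  expect_equal(which.max(fd$prob) - 1L, 300L)
  expect_equal(fragment_prob(fd, 300L), 1)
  expect_equal(fragment_prob(fd, 299L), 0)
  expect_equal(fragment_prob(fd, 5000L), 0)   # outside support

  fd2 <- new_fragment_distribution(c(rep(290L, 50), rep(310L, 50)),
                                   bw = 0)
  expect_equal(fd2$raw[c(291L, 311L)], c(50L, 50L))
  expect_equal(sum(fd2$raw), 100L)

  set.seed(3)
  draws <- round(rnorm(1e4, 300, 50))
  fd3 <- new_fragment_distribution(draws)
  expect_lt(abs(fd3$mean - 300), 3 * 50 / sqrt(1e4))
  expect_equal(sum(fd3$prob), 1, tolerance = 1e-9)
})

test_that("fragment estimation subtracts completed annotated introns", {
  expt <- pair_fixture(seed = 59L)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  donor <- iv[1]; iend <- iv[2]
  ilen <- iend - donor + 1L
  # exonic pair (insert 300) and a pair spanning the spliced intron
  # (genomic span ilen + 400, implied insert 400)
  rows <- rbind(
    aln_row("e1", donor - 550L, "50M", chrom = "chrS"),
    aln_row("e1", donor - 300L, "50M", mate = 2L, chrom = "chrS"),
    aln_row("s1", donor - 200L, "50M", chrom = "chrS"),
    aln_row("s1", iend + 151L, "50M", mate = 2L, chrom = "chrS"))
  fd <- estimate_fragment_distribution(read_alignments(rows),
                                       expt$annotation, bw = 0)
  expect_equal(which(fd$raw > 0) - 1L, c(300L, 400L))
})

test_that("a single candidate takes the whole prior and all pairs", {
  expt <- pair_fixture(seed = 61L)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  pwm <- build_pwms(expt$annotation, expt$genome)
  aln <- read_alignments(expt$alignments)
  sp <- select_spanning_pairs(pair_mates(aln), expt$annotation)
  fd <- new_fragment_distribution(round(rnorm(5000, 300, 50)))
  gm <- gem_infer_sites(sp, NULL, fd, pwm, expt$genome,
                        list(chrom = "chrS", start = iv[1], end = iv[2],
                             strand = "+"), donor = iv[1])
  expect_equal(sum(gm$sites$prior > 0), 1L)
  expect_equal(gm$sites$prior[gm$sites$site == expt$truth$site], 1)
  expect_true(all(gm$assignments == expt$truth$site))
  expect_true(gm$converged)
})

test_that("impossible inserts under every candidate empty the model", {
  expt <- pair_fixture(seed = 67L)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  pwm <- build_pwms(expt$annotation, expt$genome)
  aln <- read_alignments(expt$alignments)
  sp <- select_spanning_pairs(pair_mates(aln), expt$annotation)
  # fragment distribution concentrated far from any implied insert
  fd <- new_fragment_distribution(rep(1900L, 100), bw = 0)
  expect_warning(
    gm <- gem_infer_sites(sp, NULL, fd, pwm, expt$genome,
                          list(chrom = "chrS", start = iv[1],
                               end = iv[2], strand = "+"),
                          donor = iv[1]),
    "sparsity|no candidate")
  expect_equal(nrow(gm$sites), 0L)
})

test_that("EM separates two candidate sites; exact-Bayes oracle agrees", {
  # two AGGT candidates 2 kb apart; 200 pairs simulated from site A
  expt <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 0,
                                      intron_length = 12000L,
                                      n_pairs = 200L, seed = 71L)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  site_a <- expt$truth$site
  site_b <- site_a + 2000L
  # plant a second, equally strong element at site B
  g <- as.character(expt$genome[["chrS"]])
  wa <- substr(g, site_a - 20L, site_a + 5L)
  substr(g, site_b - 20L, site_b + 5L) <- wa
  genome <- Biostrings::DNAStringSet(g); names(genome) <- "chrS"
  pwm <- build_pwms(expt$annotation, genome)
  aln <- read_alignments(expt$alignments)
  sp <- select_spanning_pairs(pair_mates(aln), expt$annotation)
  fd <- new_fragment_distribution(round(rnorm(2e4, 300, 50)))
  gm <- gem_infer_sites(sp, NULL, fd, pwm, genome,
                        list(chrom = "chrS", start = iv[1], end = iv[2],
                             strand = "+"), donor = iv[1])
  expect_true(all(c(site_a, site_b) %in% gm$sites$site))
  pa <- gm$sites$prior[gm$sites$site == site_a]
  pb <- gm$sites$prior[gm$sites$site == site_b]
  expect_gt(pa, pb)
  expect_gte(mean(gm$assignments == site_a, na.rm = TRUE), 0.95)
  # oracle: exact Bayes posterior under the true generating
  # distribution and equal priors, pair by pair
  up <- iv[1] - sp$read1_start
  ins_a <- up + sp$read2_end - site_a + 1L
  ins_b <- up + sp$read2_end - site_b + 1L
  post_a <- dnorm(ins_a, 300, 50) /
    (dnorm(ins_a, 300, 50) + dnorm(ins_b, 300, 50))
  oracle_map <- ifelse(post_a >= 0.5, site_a, site_b)
  expect_gte(mean(gm$assignments == oracle_map), 0.95)
})

test_that("EM invariants: prior simplex, motif support, likelihood ascent", {
  expt <- pair_fixture(seed = 73L)
  iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
  pwm <- build_pwms(expt$annotation, expt$genome)
  aln <- read_alignments(expt$alignments)
  sp <- select_spanning_pairs(pair_mates(aln), expt$annotation)
  fd <- new_fragment_distribution(round(rnorm(5000, 300, 50)))
  jc <- setNames(5, as.character(expt$truth$site))
  gm <- gem_infer_sites(sp, jc, fd, pwm, expt$genome,
                        list(chrom = "chrS", start = iv[1], end = iv[2],
                             strand = "+"), donor = iv[1])
  expect_equal(sum(gm$sites$prior), 1, tolerance = 1e-12)
  # positions below the motif floor never acquire prior: every
  # candidate in the model already passed, and junction reads count
  # toward effective reads
  expect_true(all(gm$sites$motif_score > 0.8))
  expect_equal(gm$sites$junction_reads[gm$sites$site == expt$truth$site],
               5)
  expect_true(all(diff(gm$loglik) > -1e-8))
})

test_that("planted sites are MAP-recovered across 20 seeded fixtures", {
  hits <- vapply(1:20, function(s) {
    expt <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 0,
                                        intron_length = 10000L,
                                        n_pairs = 25L, seed = 100L + s)
    iv <- as.integer(strsplit(expt$truth$intron_id, "[:-]")[[1]][2:3])
    pwm <- build_pwms(expt$annotation, expt$genome)
    aln <- read_alignments(expt$alignments)
    sp <- select_spanning_pairs(pair_mates(aln), expt$annotation)
    fd <- new_fragment_distribution(round(rnorm(5000, 300, 50)))
    gm <- suppressWarnings(gem_infer_sites(
      sp, NULL, fd, pwm, expt$genome,
      list(chrom = "chrS", start = iv[1], end = iv[2], strand = "+"),
      donor = iv[1]))
    if (nrow(gm$sites) == 0L) return(FALSE)
    top <- gm$sites$site[which.max(gm$sites$prior)]
    abs(top - expt$truth$site) <= 10L
  }, logical(1L))
  expect_gte(sum(hits), 19L)
})
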