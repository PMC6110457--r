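test_that("sawtooth specs are validated", {
  expect_error(sawtooth_spec(5000, sites = 4500), ">= 1 kb")
  expect_error(sawtooth_spec(5000, sites = 2500,
                             start_density = c(10, 10), decay = 0.9),
               "1.5-fold")
  expect_silent(sawtooth_spec(5000, sites = 2500))
})

test_that("zero sites give a single linear decay; zero noise is exact", {
  spec <- sawtooth_spec(3000, noise_scale = 0, seed = 1)
  sim <- simulate_sawtooth_coverage(spec)
  expect_equal(sim$coverage, sim$expected)
  d <- diff(sim$expected)
  expect_true(all(d <= 0))
  expect_equal(length(unique(round(d, 12))), 1L)  # constant slope
})

test_that("planted coverage matches the closed-form expectation", {
  spec <- sawtooth_spec(12000, sites = c(4000, 8000), start_density = 20,
                        seed = 21)
  sim <- simulate_sawtooth_coverage(spec)
  # closed-form segment-wise expectation (the generator's oracle)
  bounds <- c(1, 4000, 8000, 12001)
  for (k in 1:3) {
    a <- bounds[k]; b <- bounds[k + 1] - 1
    idx <- a:b
    expected <- 20 * (1 - 0.5 * (idx - a) / (b - a))
    expect_equal(sim$expected[idx], expected, tolerance = 1e-12)
    # Poisson means: per-bin average within 3 standard errors
    se <- sqrt(mean(expected) / length(idx))
    expect_lt(abs(mean(sim$coverage[idx]) - mean(expected)), 3 * se)
  }
  # AGGT present exactly at planted sites, absent within +/- 50 nt
  for (s in spec$sites) {
    expect_equal(substr(sim$sequence, s - 2, s + 1), "AGGT")
    near <- substr(sim$sequence, s - 52, s + 53)
    hits <- gregexpr("AGGT", near)[[1]]
    hits <- hits[hits > 0] + (s - 52) + 1  # site coords of matches
    expect_true(all(abs(hits - s) <= 1))
  }
})

test_that("generators are seed-deterministic", {
  spec <- sawtooth_spec(9000, sites = 4500, seed = 7)
  expect_identical(simulate_sawtooth_coverage(spec),
                   simulate_sawtooth_coverage(spec))
  a <- simulate_read_pairs(20, donor = 1000, site = 5000, seed = 3)
  b <- simulate_read_pairs(20, donor = 1000, site = 5000, seed = 3)
  expect_identical(a, b)
  e1 <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 1, seed = 5)
  e2 <- simulate_ratchet_experiment(n_recursive = 1, n_decoy = 1, seed = 5)
  expect_identical(e1$alignments, e2$alignments)
  expect_identical(as.character(e1$genome), as.character(e2$genome))
})

test_that("read pairs carry the stated implied insert", {
  expect_equal(nrow(simulate_read_pairs(0, 1000, 5000)), 0L)
  # degenerate distribution: every implied insert is exactly 300
  aln <- simulate_read_pairs(50, donor = 1000, site = 5000,
                             frag_mean = 300, frag_sd = 0, seed = 2)
  p <- attr(aln, "pairs")
  implied <- (1000 - p$read1_start) + (p$read2_end - 5000 + 1)
  expect_true(all(implied == 300))
  # sampled case: mean within 3 SE of 300
  aln2 <- simulate_read_pairs(1e4, donor = 2000, site = 9000,
                              frag_mean = 300, frag_sd = 50, seed = 4)
  p2 <- attr(aln2, "pairs")
  implied2 <- (2000 - p2$read1_start) + (p2$read2_end - 9000 + 1)
  expect_lt(abs(mean(implied2) - 300), 3 * 50 / sqrt(1e4))
  # geometry: read 1 fully upstream of donor, read 2 at/after the site
  expect_true(all(p2$read1_start + 49 < 2000))
  expect_true(all(p2$read2_end - 49 >= 9000))
})

test_that("labeling counts follow the progressive-labeling fractions", {
  all_done <- simulate_labeling_counts(0, depth = 100, seed = 1)
  expect_true(all(all_done$ie_count == 0))
  none <- simulate_labeling_counts(Inf, depth = 100, seed = 1)
  expect_true(all(none$ee_count == 0))
  sl <- simulate_labeling_counts(10, depth = 1e4, seed = 6)
  th <- theta_completed(log(2) / 10, c(5, 10, 20))
  frac <- sl$ee_count / (sl$ee_count + sl$ie_count)
  se <- sqrt(th * (1 - th) / 1e4)
  expect_true(all(abs(frac - th) < 3 * se))
})

test_that("lariat reads are a branchpoint half joined to a donor half", {
  g <- toy_genome(4000)
  lr <- simulate_lariat_read(g, "chr1", donor = 500, branchpoint = 3000,
                             len_up = 25, len_down = 26)
  expect_equal(nchar(lr$read), 51L)
  expect_equal(lr$split_at, 26L)
  expect_equal(substr(lr$read, 1, 25),
               as.character(Biostrings::subseq(g[["chr1"]], 2976, 3000)))
  expect_equal(substr(lr$read, 26, 51),
               as.character(Biostrings::subseq(g[["chr1"]], 500, 525)))
})

test_that("experiment fixtures are mutually consistent", {
  expt <- simulate_ratchet_experiment(n_recursive = 2, n_decoy = 1,
                                      seed = 13)
  # planted AGGT exists in the genome at every truth site
  for (i in seq_len(nrow(expt$truth))) {
    s <- expt$truth$site[i]
    expect_equal(as.character(Biostrings::subseq(
      expt$genome[["chrS"]], s - 2, s + 1)), "AGGT")
  }
  # junction reads land on the planted sites
  jx <- extract_junction_reads(read_alignments(expt$alignments))
  rj <- find_ratchet_junctions(jx, expt$annotation, expt$genome)
  expect_setequal(unique(rj$site), expt$truth$site)
  # coverage vectors span their introns exactly
  for (id in names(expt$coverage)) {
    p <- as.integer(strsplit(id, "[:-]")[[1]][2:3])
    expect_length(expt$coverage[[id]], p[2] - p[1] + 1L)
  }
  # written fixtures are readable back
  dir <- file.path(tempdir(), "expt_fixture")
  paths <- write_experiment(expt, dir)
  ann2 <- load_annotation(paths[["annotation"]])
  expect_equal(sort(ann2$introns$intron_id),
               sort(expt$annotation$introns$intron_id))
  g2 <- load_genome(paths[["genome"]])
  expect_equal(as.character(g2[["chrS"]]),
               as.character(expt$genome[["chrS"]]))
})

test_that("planted-site recovery from read pairs matches simulation", {
  # invariant: junction support equals the number of simulated reads
  expt <- simulate_ratchet_experiment(
    n_recursive = 1, n_decoy = 0,
    junction_counts = c("5" = 3L, "10" = 5L, "20" = 7L), seed = 17)
  jx <- extract_junction_reads(read_alignments(expt$alignments))
  rj <- find_ratchet_junctions(jx, expt$annotation, expt$genome)
  expect_equal(sum(rj$count), 15L)
  expect_equal(unique(rj$site), expt$truth$site)
})
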