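# Sawtooth detection: heteroscedastic piecewise regression scored by
# BIC, explored by an MCMC over recursive-site configurations, followed
# by motif-informed peak calling and shuffle-based FDR.

#' Preprocess intronic coverage into a binned profile
#'
#' Drops exon-overlapping positions, replaces RepeatMasker regions plus
#' 100 flanking nt with the median read density of the 900 nt on either
#' side, and averages the result over 100 nt bins.  Introns of 8 kb or
#' less are skipped (regression over short segments is too sensitive to
#' count noise); a skip marker is returned instead of a profile.
#'
#' @param counts per-base counts across the intron (position 1 =
#'   intron start).
#' @param intron_start,intron_end genomic coordinates (1-based closed).
#' @param chrom chromosome name.
#' @param strand intron strand.
#' @param repeats optional `GRanges` of repeat annotation.
#' @param exons optional `GRanges` of exon annotation to subtract.
#' @param spanning_reads number of complete 5'SS-3'SS junction reads
#'   supporting the intron; at least one is required.
#' @param bin_size bin width in nt.
#' @param min_length minimum intron length for analysis.
#' @return A `CoverageProfile` (list with `bins`, `counts`, `offsets`,
#'   coordinates), or a `skipped_intron` object carrying the reason.
#' @export
preprocess_coverage <- function(counts, intron_start, intron_end,
                                chrom = "chrS", strand = "+",
                                repeats = NULL, exons = NULL,
                                spanning_reads = 1L, bin_size = 100L,
                                min_length = 8000L) {
  L <- intron_end - intron_start + 1L
  stopifnot(length(counts) == L)
  if (L <= min_length)
    return(structure(list(reason = sprintf(
      "intron length %d <= %d nt: short-segment regressions are noise-prone",
      L, min_length)), class = "skipped_intron"))
  if (spanning_reads < 1L)
    return(structure(list(reason = "no spanning splice junction read"),
                     class = "skipped_intron"))
  counts <- as.numeric(counts)
  offsets <- seq(intron_start, intron_end)
  if (!is.null(repeats) && length(repeats) > 0L) {
    counts <- .mask_repeats(counts, intron_start, intron_end, chrom,
                            repeats)
  }
  if (!is.null(exons) && length(exons) > 0L) {
    ex <- repeats_in_window(exons, chrom, intron_start, intron_end)
    drop <- logical(L)
    for (i in seq_len(nrow(ex)))
      drop[(ex$start[i] - intron_start + 1L):
           (ex$end[i] - intron_start + 1L)] <- TRUE
    counts <- counts[!drop]
    offsets <- offsets[!drop]
  }
  n_bins <- ceiling(length(counts) / bin_size)
  grp <- rep(seq_len(n_bins), each = bin_size,
             length.out = length(counts))
  bins <- as.numeric(tapply(counts, grp, mean))
  structure(list(chrom = chrom, start = intron_start, end = intron_end,
                 strand = strand, counts = counts, offsets = offsets,
                 bins = bins, bin_size = as.integer(bin_size),
                 n_bins = n_bins, length = length(counts)),
            class = "CoverageProfile")
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat(sprintf("CoverageProfile %s:%d-%d (%s): %d bins of %d nt\n",
              x$chrom, x$start, x$end, x$strand, x$n_bins, x$bin_size))
  invisible(x)
}

# clip ranges overlapping [start, end] on chrom to the window,
# returned as a data.frame of local genomic intervals
repeats_in_window <- function(gr, chrom, start, end) {
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  s <- pmax(GenomicRanges::start(gr), start)
  e <- pmin(GenomicRanges::end(gr), end)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

.mask_repeats <- function(counts, intron_start, intron_end, chrom,
                          repeats, flank = 100L, med_win = 900L) {
  rp <- repeats_in_window(repeats, chrom,
                          intron_start - flank, intron_end + flank)
  if (nrow(rp) == 0L) return(counts)
  # expand by the 100 nt flank, merge overlapping blocks, clip to intron
  ir <- IRanges::reduce(IRanges::IRanges(rp$start - flank,
                                         rp$end + flank))
  L <- length(counts)
  orig <- counts
  for (i in seq_along(ir)) {
    a <- max(IRanges::start(ir)[i] - intron_start + 1L, 1L)
    b <- min(IRanges::end(ir)[i] - intron_start + 1L, L)
    if (a > b) next
    left <- orig[max(1L, a - med_win):max(1L, a - 1L)]
    right <- orig[min(L, b + 1L):min(L, b + med_win)]
    nb <- c(if (a > 1L) left, if (b < L) right)
    counts[a:b] <- if (length(nb)) median(nb) else 0
  }
  counts
}

#' Iteratively reweighted linear fit for count-like noise
#'
#' Fits `y ~ x` by weighted least squares where the variance at each
#' position is taken proportional to the expected coverage: weights are
#' updated to `1 / fitted` and the fit repeated until no weight changes
#' by more than `tol`.  The first pass is ordinary least squares.
#'
#' @param y response (binned read density), length >= 2.
#' @param x predictor; defaults to `seq_along(y) - 1`.
#' @param tol convergence tolerance on the maximum weight change.
#' @param weight_floor weight used where the fit predicts <= 0.
#' @param max_iter iteration cap.
#' @return list with `slope`, `intercept`, `weights`, `rss` (weighted
#'   residual sum of squares at the converged fit), `iterations`.
#' @export
heteroscedastic_regression <- function(y, x = seq_along(y) - 1,
                                       tol = 1e-3, weight_floor = 1e-6,
                                       max_iter = 100L) {
  stopifnot(length(y) >= 2L, length(x) == length(y))
  w <- rep(1, length(y))
  for (it in seq_len(max_iter)) {
    fit <- .wls(x, y, w)
    pred <- fit$intercept + fit$slope * x
    w_next <- ifelse(pred > 0, 1 / pred, weight_floor)
    if (max(abs(w_next - w)) <= tol) {
      return(list(slope = fit$slope, intercept = fit$intercept,
                  weights = w_next,
                  rss = sum(w_next * (y - pred)^2), iterations = it))
    }
    w <- w_next
  }
  list(slope = fit$slope, intercept = fit$intercept, weights = w_next,
       rss = sum(w_next * (y - pred)^2), iterations = max_iter)
}

.wls <- function(x, y, w) {
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  den <- sum(w * x * x) * sw - swx^2
  slope <- if (den == 0) 0 else (sum(w * x * y) * sw - swx * swy) / den
  list(slope = slope, intercept = (swy - slope * swx) / sw)
}

# --- state evaluation -------------------------------------------------

# segment fits are cached across the whole chain: proposals revisit the
# same (a, b) spans constantly and the fit depends only on the span
.segment_fit <- function(cache, bins, a, b) {
  key <- paste0(a, ":", b)
  f <- cache[[key]]
  if (is.null(f)) {
    idx <- (a + 1L):b               # bins of segment [a, b) in 0-based x
    f <- heteroscedastic_regression(bins[idx], x = idx - 1L)
    cache[[key]] <- f
  }
  f
}

# evaluate a state (sorted site vector, possibly empty); returns NULL
# when the 1.5-fold jump constraint is violated at any site
.eval_state <- function(sites, bins, cache, L_nt, min_jump = 1.5,
                        temperature = 5) {
  B <- length(bins)
  bounds <- c(0L, sites, B)
  rss <- 0
  fits <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    f <- .segment_fit(cache, bins, bounds[k], bounds[k + 1L])
    fits[[k]] <- f
    rss <- rss + f$rss
  }
  for (j in seq_along(sites)) {
    s <- sites[j]
    up <- fits[[j]]$intercept + fits[[j]]$slope * s
    dn <- fits[[j + 1L]]$intercept + fits[[j + 1L]]$slope * s
    ok <- if (up <= 0) dn > 0 else dn >= min_jump * up
    if (!ok) return(NULL)
  }
  n <- length(sites)
  bic <- L_nt * rss + 2 * (2 * n) * log(L_nt)
  list(sites = sites, rss = rss, bic = bic, fits = fits)
}

#' BIC of a recursive-site configuration on a coverage profile
#'
#' Fits each segment delimited by the proposed sites with
#' [heteroscedastic_regression()] and returns
#' `BIC(M) = L * RSS(M) + 2 * (2N) * log(L)` with `L` the intron
#' length in nt, `RSS(M)` the summed weighted residuals and `N` the
#' number of sites.  Configurations violating the minimum fitted-density
#' jump at any site are invalid.
#'
#' @param profile `CoverageProfile`.
#' @param sites integer vector of site bin boundaries (may be empty).
#' @param min_jump minimum fold increase of the fitted density at a site.
#' @return list with `valid`, `bic`, `rss`.
#' @export
sawtooth_bic <- function(profile, sites, min_jump = 1.5) {
  cache <- new.env(parent = emptyenv())
  st <- .eval_state(sort(as.integer(sites)), profile$bins, cache,
                    profile$length, min_jump)
  if (is.null(st)) return(list(valid = FALSE, bic = NA_real_,
                               rss = NA_real_))
  list(valid = TRUE, bic = st$bic, rss = st$rss)
}

#' Metropolis acceptance probability of the sawtooth chain
#'
#' A proposal with lower BIC is adopted deterministically; otherwise it
#' is adopted with probability `exp(-(BIC_new - BIC_old) / T)`, halved
#' when the current state has zero recursive sites (compensating the
#' asymmetric proposal distribution at the empty state).
#'
#' @param bic_old,bic_new BIC of the current and proposed states.
#' @param from_zero does the current state have zero sites?
#' @param temperature scaling constant T.
#' @return acceptance probability in `[0, 1]`.
#' @export
mcmc_acceptance <- function(bic_old, bic_new, from_zero = FALSE,
                            temperature = 5) {
  d <- bic_new - bic_old
  if (d <= 0) return(1)
  p <- exp(-d / temperature)
  if (from_zero) p <- p / 2
  p
}

#' MCMC inference of recursive-site configurations from binned coverage
#'
#' Round-based chain over sets of proposed recursive sites (bin
#' boundaries).  Each round perturbs the current state — add a site
#' (probability 0.4), remove one (0.4), or shift one locally by 1-5
#' bins (0.2) — and evaluates the proposal by
#' `BIC(M) = L * RSS(M) + 2 * (2N) * log(L)`, where `RSS(M)` is the
#' weighted residual sum over the per-segment heteroscedastic fits,
#' `L` the intron length (nt) and `N` the number of sites.  Proposals
#' whose fitted density does not rise at least `min_jump`-fold at every
#' site are rejected outright.  A better (lower-BIC) state is adopted
#' deterministically; a worse one with probability
#' `exp(-(BIC_new - BIC_old) / T)`, halved when leaving the zero-site
#' state.  After burn-in the current state is sampled at a fixed
#' frequency and per-bin probabilities are the site sample frequencies.
#'
#' @param profile a `CoverageProfile` (at least 80 bins).
#' @param iterations,burn_in,sample_every chain schedule.  The
#'   full-scale defaults mirror a production run (1e7 / 1e5 / 50);
#'   desk-scale analyses use 1e5 iterations with a 1e4 burn-in.
#' @param temperature score-scaling constant T.
#' @param min_jump minimum fitted-density fold increase at a site.
#' @param min_segment minimum segment length in bins.
#' @param min_separation minimum distance between proposed sites (bins).
#' @param seed integer seed.
#' @return A `SiteProbabilityTrack`: `prob` (per-bin-boundary site
#'   probability), `n_samples`, `state_sizes` (sampled site counts),
#'   `final_state`, `acceptance_rate`, and the input `profile`.
#' @export
mcmc_sawtooth <- function(profile, iterations = 1e7, burn_in = 1e5,
                          sample_every = 50L, temperature = 5,
                          min_jump = 1.5, min_segment = 5L,
                          min_separation = 10L, seed = 1L) {
  stopifnot(inherits(profile, "CoverageProfile"))
  bins <- profile$bins
  B <- length(bins)
  if (B < 80L) stop("profile has ", B, " bins; need at least 80")
  .with_seed(seed, {
    cache <- new.env(parent = emptyenv())
    L_nt <- profile$length
    lo <- min_segment; hi <- B - min_segment
    valid_site <- function(s, others)
      s >= lo && s <= hi && (length(others) == 0L ||
                             min(abs(s - others)) >= min_separation)
    cur <- .eval_state(integer(0), bins, cache, L_nt, min_jump,
                       temperature)
    counts <- numeric(B)
    sizes <- integer(0)
    n_samples <- 0L; n_accept <- 0L
    for (it in seq_len(iterations)) {
      u <- runif(1)
      prop_sites <- NULL
      if (u < 0.4) {                      # add
        cand <- setdiff(lo:hi, unlist(lapply(cur$sites, function(s)
          (s - min_separation + 1L):(s + min_separation - 1L))))
        if (length(cand))
          prop_sites <- sort(c(cur$sites, cand[sample.int(length(cand), 1L)]))
      } else if (u < 0.8) {               # remove
        if (length(cur$sites))
          prop_sites <- cur$sites[-sample.int(length(cur$sites), 1L)]
      } else {                            # local shift
        if (length(cur$sites)) {
          i <- sample.int(length(cur$sites), 1L)
          d <- sample(c(-5:-1, 1:5), 1L)
          s2 <- cur$sites[i] + d
          if (valid_site(s2, cur$sites[-i]))
            prop_sites <- sort(c(cur$sites[-i], s2))
        }
      }
      if (!is.null(prop_sites)) {
        prop <- .eval_state(prop_sites, bins, cache, L_nt, min_jump,
                            temperature)
        if (!is.null(prop)) {
          p <- mcmc_acceptance(cur$bic, prop$bic,
                               from_zero = length(cur$sites) == 0L,
                               temperature = temperature)
          if (p >= 1 || runif(1) < p) {
            cur <- prop; n_accept <- n_accept + 1L
          }
        }
      }
      if (it > burn_in && (it - burn_in) %% sample_every == 0L) {
        n_samples <- n_samples + 1L
        if (length(cur$sites)) counts[cur$sites] <-
            counts[cur$sites] + 1L
        sizes <- c(sizes, length(cur$sites))
      }
    }
    structure(list(prob = if (n_samples) counts / n_samples
                          else numeric(B),
                   n_samples = n_samples, state_sizes = sizes,
                   final_state = cur$sites,
                   acceptance_rate = n_accept / iterations,
                   profile = profile),
              class = "SiteProbabilityTrack")
  })
}

#' @export
print.SiteProbabilityTrack <- function(x, ...) {
  cat(sprintf(
    "SiteProbabilityTrack: %d samples, max P = %.3f, mean sites/sample = %.2f\n",
    x$n_samples, max(x$prob), mean(x$state_sizes)))
  invisible(x)
}

# genomic coordinate of bin boundary s (between bins s-1 and s,
# 0-based): the first retained base of bin s
.boundary_pos <- function(profile, s) {
  profile$offsets[pmin(s * profile$bin_size + 1L,
                       length(profile$offsets))]
}

#' Logistic flank of the peak position potential
#'
#' Outside a called probability region the position potential decays
#' logistically: `1 / (1 + exp(k * (d - x0)))` at distance `d` nt from
#' the region edge, with `x0 = 500` and `|k| = 6/500`, so the value is
#' 0.5 exactly 500 nt outside an edge and near zero at 1000 nt.
#'
#' @param d distance (nt) outside the region edge (>= 0).
#' @param x0 inflection distance.
#' @param k decay rate.
#' @return potential value(s) in (0, 1).
#' @export
flank_potential <- function(d, x0 = 500, k = 6 / 500) {
  1 / (1 + exp(k * (d - x0)))
}

#' Position potential of a point relative to a called region
#' @param pos genomic position(s).
#' @param region_start,region_end region edges (1 inside the region).
#' @inheritParams flank_potential
#' @export
position_potential <- function(pos, region_start, region_end,
                               x0 = 500, k = 6 / 500) {
  d_left <- region_start - pos
  d_right <- pos - region_end
  ifelse(pos < region_start, flank_potential(d_left, x0, k),
         ifelse(pos > region_end, flank_potential(d_right, x0, k), 1))
}

# merge regions (data.frame start/end) closer than merge_nt
.merge_regions <- function(regions, merge_nt = 500) {
  if (nrow(regions) == 0L) return(regions)
  regions <- regions[order(regions$start), , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(regions$start, regions$end),
                        min.gapwidth = merge_nt + 1L)
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

# score all candidate AGGTs against a set of (merged) regions; one
# winner per region: the maximum of S(i) = P(i) * max(M(i) - 0.8, 0)
.score_regions <- function(regions, aggt, merge_nt = 500, x0 = 500,
                           k = 6 / 500, motif_floor = 0.8) {
  regions <- .merge_regions(regions, merge_nt)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    if (nrow(aggt) == 0L) next
    P <- position_potential(aggt$site, regions$start[i],
                            regions$end[i], x0, k)
    S <- P * pmax(aggt$motif_score - motif_floor, 0)
    if (all(S <= 0)) next                      # no scorable AGGT: drop
    j <- which.max(S)
    out[[i]] <- data.frame(site = aggt$site[j],
                           region_start = regions$start[i],
                           region_end = regions$end[i],
                           sawtooth_score = S[j],
                           motif_score = aggt$motif_score[j],
                           position_potential = P[j])
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L)
    return(data.frame(site = integer(0), region_start = integer(0),
                      region_end = integer(0), sawtooth_score = numeric(0),
                      motif_score = numeric(0),
                      position_potential = numeric(0)))
  do.call(rbind, out)
}

#' Call recursive sites from an MCMC probability track
#'
#' Thresholds the track at `threshold`, merges regions within
#' `merge_nt`, builds the position potential (1 inside a region,
#' logistic flanks outside), scores every intronic AG|GT by
#' `S(i) = P(i) * max(M(i) - 0.8, 0)` and reports the maximum-scoring
#' AGGT per region.  Regions where no AGGT scores above zero are
#' dropped.
#'
#' @param track `SiteProbabilityTrack` from [mcmc_sawtooth()].
#' @param genome `DNAStringSet`.
#' @param pwm `SpliceSitePWM`.
#' @param threshold track probability threshold.
#' @param merge_nt merge distance for adjacent regions.
#' @param x0,k flank potential parameters.
#' @param motif_floor motif score subtracted inside S(i).
#' @return data.frame of calls: `chrom`, `site`, `region_start`,
#'   `region_end`, `sawtooth_score`, `mcmc_probability`, `motif`,
#'   `motif_score`.
#' @export
call_peaks <- function(track, genome, pwm, threshold = 0.08,
                       merge_nt = 500, x0 = 500, k = 6 / 500,
                       motif_floor = 0.8) {
  profile <- track$profile
  above <- which(track$prob > threshold)
  if (length(above) == 0L)
    return(data.frame(chrom = character(0), site = integer(0),
                      region_start = integer(0), region_end = integer(0),
                      sawtooth_score = numeric(0),
                      mcmc_probability = numeric(0),
                      motif = character(0), motif_score = numeric(0)))
  runs <- split(above, cumsum(c(1L, diff(above) > 1L)))
  regions <- do.call(rbind, lapply(runs, function(r)
    data.frame(start = .boundary_pos(profile, min(r)),
               end = .boundary_pos(profile, max(r)))))
  aggt <- .intron_aggt(genome, pwm, profile$chrom, profile$start,
                       profile$end, profile$strand)
  calls <- .score_regions(regions, aggt, merge_nt, x0, k, motif_floor)
  if (nrow(calls) == 0L)
    return(data.frame(chrom = character(0), site = integer(0),
                      region_start = integer(0), region_end = integer(0),
                      sawtooth_score = numeric(0),
                      mcmc_probability = numeric(0),
                      motif = character(0), motif_score = numeric(0)))
  # region-level MCMC support: maximum track probability in the region
  calls$mcmc_probability <- vapply(seq_len(nrow(calls)), function(i) {
    bpos <- .boundary_pos(profile, seq_along(track$prob))
    inside <- bpos >= calls$region_start[i] & bpos <= calls$region_end[i]
    if (any(inside)) max(track$prob[inside]) else 0
  }, numeric(1L))
  calls$chrom <- profile$chrom
  calls$motif <- site_window(genome, profile$chrom, calls$site,
                             profile$strand, pwm)
  calls[c("chrom", "site", "region_start", "region_end",
          "sawtooth_score", "mcmc_probability", "motif", "motif_score")]
}

.intron_aggt <- function(genome, pwm, chrom, start, end, strand) {
  sites <- scan_aggt(genome, chrom, start, end, strand)
  if (length(sites) == 0L)
    return(data.frame(site = integer(0), motif_score = numeric(0)))
  w <- site_window(genome, chrom, sites, strand, pwm)
  keep <- !is.na(w)
  data.frame(site = sites[keep],
             motif_score = as.numeric(score_sites(w[keep], pwm)))
}

#' Shuffle-based FDR for sawtooth peak calls
#'
#' Repositions the observed above-threshold regions uniformly across
#' the intron (region count and lengths preserved), re-applies the peak
#' calling procedure, and estimates, for each observed site score `s`,
#' `FDR(s) = mean null peaks with S >= s / observed peaks with S >= s`,
#' clipped to `[0, 1]`.
#'
#' @param calls output of [call_peaks()] for one intron.
#' @param track the `SiteProbabilityTrack` the calls came from.
#' @param genome `DNAStringSet`.
#' @param pwm `SpliceSitePWM`.
#' @param n_shuffles number of uniform repositionings.
#' @param seed integer seed.
#' @inheritParams call_peaks
#' @return `calls` with an `fdr` column, plus attributes `null_scores`
#'   and `shuffled_regions` (the last shuffle, for auditing).
#' @export
estimate_sawtooth_fdr <- function(calls, track, genome, pwm,
                                  n_shuffles = 200L, seed = 1L,
                                  merge_nt = 500, x0 = 500, k = 6 / 500,
                                  motif_floor = 0.8) {
  if (nrow(calls) == 0L) {
    calls$fdr <- numeric(0)
    return(calls)
  }
  profile <- track$profile
  lens <- calls$region_end - calls$region_start + 1L
  aggt <- .intron_aggt(genome, pwm, profile$chrom, profile$start,
                       profile$end, profile$strand)
  .with_seed(seed, {
    null_scores <- vector("list", n_shuffles)
    shuffle_lengths <- matrix(0L, n_shuffles, length(lens))
    last <- NULL
    for (b in seq_len(n_shuffles)) {
      starts <- vapply(lens, function(l)
        profile$start +
          sample.int(profile$end - profile$start - l + 2L, 1L) - 1L,
        numeric(1L))
      reg <- data.frame(start = as.integer(starts),
                        end = as.integer(starts) + lens - 1L)
      shuffle_lengths[b, ] <- reg$end - reg$start + 1L
      last <- reg
      nc <- .score_regions(reg, aggt, merge_nt, x0, k, motif_floor)
      null_scores[[b]] <- nc$sawtooth_score
    }
    nulls <- unlist(null_scores)
    calls$fdr <- vapply(calls$sawtooth_score, function(s) {
      obs <- sum(calls$sawtooth_score >= s)
      min(1, (sum(nulls >= s) / n_shuffles) / obs)
    }, numeric(1L))
    attr(calls, "null_scores") <- nulls
    attr(calls, "shuffled_regions") <- last
    attr(calls, "shuffle_lengths") <- shuffle_lengths
    calls
  })
}
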