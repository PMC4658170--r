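## Site-level contamination experiment: mix sample-derived and contaminant
## (reference-homozygous) read observations at constant total coverage, call
## genotypes with a diploid binomial-likelihood caller, and report detection
## power / FN / FP against the contamination level.

#' Configuration of the contamination experiment
#'
#' @param coverage mean total depth (default 150, constant across
#'   contamination levels).
#' @param levels contaminant fractions in `[0, 1)`; default the assessed
#'   grid 0, 0.25, 0.50, 0.75, 0.90, 0.95, 0.98, 0.99.
#' @param error_rate per-base miscall probability in (0, 0.5).
#' @param n_het_sites,n_homalt_sites,n_ref_sites site counts for truth
#'   heterozygous, truth homozygous-alt and non-variant sites.
#' @param qual_threshold phred call threshold (default 40).
#' @param prior_variant total prior mass on the two variant genotypes
#'   (split evenly between het and hom-alt).
#' @param depth_model `"poisson"` (depth ~ Poisson(coverage)) or `"fixed"`
#'   (depth == coverage, matching the analytic oracle).
#' @param seed RNG seed.
#' @return a `ContaminationConfig` list.
#' @export
contamination_config <- function(coverage = 150,
                                 levels = c(0, .25, .50, .75, .90, .95, .98, .99),
                                 error_rate = 0.01,
                                 n_het_sites = 4000L,
                                 n_homalt_sites = 2000L,
                                 n_ref_sites = 4000L,
                                 qual_threshold = 40,
                                 prior_variant = 0.001,
                                 depth_model = c("poisson", "fixed"),
                                 seed = 1L) {
  stopifnot(coverage > 0, all(levels >= 0), all(levels < 1),
            error_rate > 0, error_rate < 0.5, qual_threshold >= 0,
            prior_variant > 0, prior_variant < 1)
  structure(
    list(coverage = coverage, levels = levels, error_rate = error_rate,
         n_het_sites = as.integer(n_het_sites),
         n_homalt_sites = as.integer(n_homalt_sites),
         n_ref_sites = as.integer(n_ref_sites),
         qual_threshold = qual_threshold, prior_variant = prior_variant,
         depth_model = match.arg(depth_model), seed = as.integer(seed)),
    class = "ContaminationConfig"
  )
}

## Per-read probability of observing the alt allele, by read origin.
## A sample read carries alt with prob 0 (ref genotype), 1/2 (het) or 1
## (hom-alt); a carried alt is miscalled to ref with prob e and a carried
## ref is miscalled to the specific alt with prob e/3 (uniform over the
## three non-ref bases). Contaminant reads are reference-homozygous.
alt_read_prob <- function(genotype, error_rate) {
  p_carry <- switch(genotype, ref = 0, het = 0.5, homalt = 1,
                    stop_data("genotype must be ref, het or homalt"))
  p_carry * (1 - error_rate) + (1 - p_carry) * error_rate / 3
}

## Marginal alt probability of one read at contamination c.
site_alt_prob <- function(genotype, contamination, error_rate) {
  (1 - contamination) * alt_read_prob(genotype, error_rate) +
    contamination * alt_read_prob("ref", error_rate)
}

#' Simulate the read observations at one site
#'
#' Depth is Poisson(coverage) (or fixed); each read originates from the
#' sample with probability `1 - contamination`, else from the
#' reference-homozygous contaminant, and is observed as the alt allele with
#' the origin's alt probability (carried-allele frequency combined with the
#' miscall model; see the package vignette). Reads are coupled so that under
#' common random numbers a read switching from sample to contaminant origin
#' can only lose its alt observation, which makes the power monotone in the
#' contamination level pointwise.
#'
#' @param genotype `"ref"`, `"het"` or `"homalt"`.
#' @param contamination contaminant fraction in `[0, 1)` (1 allowed as a
#'   degenerate limit).
#' @param coverage mean depth.
#' @param error_rate per-base miscall probability.
#' @param depth_model `"poisson"` or `"fixed"`.
#' @return list (`SiteObservation`) with `depth` and `alt_count`.
#' @export
simulate_site <- function(genotype, contamination, coverage, error_rate,
                          depth_model = c("poisson", "fixed")) {
  obs <- simulate_sites(1L, genotype, contamination, coverage, error_rate,
                        depth_model = match.arg(depth_model))
  list(depth = obs$depth[1], alt_count = obs$alt_count[1])
}

## Vectorized site simulation with the common-random-number coupling:
## for each read, u_origin decides sample vs contaminant (contaminant iff
## u_origin < c) and u_obs < p(origin) decides the alt observation, with
## p(contaminant) <= p(sample), so alt_count is non-increasing in c when
## the RNG stream is shared across levels.
simulate_sites <- function(n, genotype, contamination, coverage, error_rate,
                           depth_model = "poisson") {
  depth <- if (depth_model == "fixed") rep(as.integer(round(coverage)), n)
           else stats::rpois(n, coverage)
  total <- sum(depth)
  p_s <- alt_read_prob(genotype, error_rate)
  p_c <- alt_read_prob("ref", error_rate)
  u_origin <- stats::runif(total)
  u_obs <- stats::runif(total)
  is_cont <- u_origin < contamination
  alt <- ifelse(is_cont, u_obs < p_c, u_obs < p_s)
  site <- rep.int(seq_len(n), depth)
  alt_count <- integer(n)
  if (total > 0) {
    tab <- tapply(alt, factor(site, levels = seq_len(n)), sum)
    alt_count <- as.integer(ifelse(is.na(tab), 0L, tab))
  }
  list(depth = depth, alt_count = alt_count)
}

#' Diploid genotype-likelihood call at one site
#'
#' Genotype likelihoods are `Binomial(depth, p_g)` on the alt-read count
#' with `p_ref = e/3`, `p_het = (1-e)/2 + e/6`, `p_homalt = 1-e`; the
#' posterior combines them with prior mass `1 - prior_variant` on ref and
#' `prior_variant / 2` on each variant genotype. The call quality is
#' `-10 log10 P(ref | data)` and the site is called variant iff
#' `qual >= qual_threshold`.
#'
#' @param depth,alt_count site observation (or a `SiteObservation` list can
#'   be spread into these). Vectorized over sites.
#' @param error_rate per-base miscall probability.
#' @param prior_variant total prior on the variant genotypes.
#' @param qual_threshold phred threshold for calling.
#' @return data.frame with columns genotype (maximum-posterior genotype;
#'   `"ref"` with qual 0 at depth 0), qual, called.
#' @export
call_genotype <- function(depth, alt_count, error_rate = 0.01,
                          prior_variant = 0.001, qual_threshold = 40) {
  stopifnot(all(alt_count >= 0), all(alt_count <= depth))
  p_g <- c(ref = alt_read_prob("ref", error_rate),
           het = alt_read_prob("het", error_rate),
           homalt = alt_read_prob("homalt", error_rate))
  log_prior <- c(ref = log1p(-prior_variant),
                 het = log(prior_variant / 2),
                 homalt = log(prior_variant / 2))
  n <- length(depth)
  geno <- character(n); qual <- numeric(n)
  ll <- vapply(names(p_g), function(g)
    stats::dbinom(alt_count, depth, p_g[[g]], log = TRUE) + log_prior[[g]],
    numeric(n))
  if (n == 1L) ll <- matrix(ll, nrow = 1L, dimnames = list(NULL, names(p_g)))
  for (i in seq_len(n)) {
    if (depth[i] == 0L) { geno[i] <- "ref"; qual[i] <- 0; next }
    lse <- logsumexp(ll[i, ])
    log_post_ref <- ll[i, "ref"] - lse
    qual[i] <- max(0, -10 / log(10) * log_post_ref)
    geno[i] <- names(p_g)[which.max(ll[i, ])]
  }
  data.frame(genotype = geno, qual = qual,
             called = depth > 0L & qual >= qual_threshold,
             stringsAsFactors = FALSE)
}

## Vectorized caller returning only the called indicator; avoids the per-site
## loop for large simulations by evaluating qual on the distinct
## (depth, alt_count) pairs.
called_variant <- function(depth, alt_count, error_rate, prior_variant,
                           qual_threshold) {
  key <- paste(depth, alt_count)
  uniq <- !duplicated(key)
  res <- call_genotype(depth[uniq], alt_count[uniq], error_rate = error_rate,
                       prior_variant = prior_variant,
                       qual_threshold = qual_threshold)
  res$called[match(key, key[uniq])]
}

#' Run the contamination experiment
#'
#' For each contamination level, simulates the configured truth
#' (heterozygous and homozygous-alt) and non-variant sites, calls each site,
#' and reports the number of calls, the false-negative rate over truth sites
#' and the false-positive rate over calls (fraction of calls arising at
#' non-variant sites). The RNG stream is re-seeded identically at every
#' level (common random numbers), so with the read coupling of
#' [simulate_site()] the FN rate is monotone non-decreasing in the
#' contamination level by construction, not just in expectation.
#'
#' @param cfg a [contamination_config()].
#' @return a `SimResult`: data.frame with one row per level and columns
#'   level, n_calls, fn_rate, fp_rate, het_power, homalt_power.
#' @export
run_contamination_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ContaminationConfig"))
  rows <- lapply(cfg$levels, function(cl) {
    set.seed(derive_seed(cfg$seed, 13L))   # CRN: identical stream per level
    het <- simulate_sites(cfg$n_het_sites, "het", cl, cfg$coverage,
                          cfg$error_rate, cfg$depth_model)
    hom <- simulate_sites(cfg$n_homalt_sites, "homalt", cl, cfg$coverage,
                          cfg$error_rate, cfg$depth_model)
    ref <- simulate_sites(cfg$n_ref_sites, "ref", cl, cfg$coverage,
                          cfg$error_rate, cfg$depth_model)
    called_het <- called_variant(het$depth, het$alt_count, cfg$error_rate,
                                 cfg$prior_variant, cfg$qual_threshold)
    called_hom <- called_variant(hom$depth, hom$alt_count, cfg$error_rate,
                                 cfg$prior_variant, cfg$qual_threshold)
    called_ref <- called_variant(ref$depth, ref$alt_count, cfg$error_rate,
                                 cfg$prior_variant, cfg$qual_threshold)
    n_truth <- cfg$n_het_sites + cfg$n_homalt_sites
    n_calls <- sum(called_het) + sum(called_hom) + sum(called_ref)
    data.frame(
      level = cl,
      n_calls = n_calls,
      fn_rate = if (n_truth > 0) 1 - (sum(called_het) + sum(called_hom)) / n_truth else 0,
      fp_rate = if (n_calls > 0) sum(called_ref) / n_calls else 0,
      het_power = if (cfg$n_het_sites > 0) mean(called_het) else NA_real_,
      homalt_power = if (cfg$n_homalt_sites > 0) mean(called_hom) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("SimResult", "data.frame")
  out
}

#' Exact detection power at fixed depth
#'
#' Independent oracle for the simulator: with depth fixed at `coverage`
#' (no Poisson variation), the detection power is the exact binomial sum
#' over alt-read counts of `Binomial(depth, p(genotype, c, e))` times the
#' indicator that [call_genotype()] reaches the quality threshold.
#'
#' @param genotype `"ref"`, `"het"` or `"homalt"`.
#' @param contamination contaminant fraction.
#' @param coverage fixed depth.
#' @param error_rate per-base miscall probability.
#' @param qual_threshold phred call threshold.
#' @param prior_variant total prior on variant genotypes.
#' @return probability that the site is called variant.
#' @export
analytic_detection_power <- function(genotype, contamination, coverage,
                                     error_rate, qual_threshold = 40,
                                     prior_variant = 0.001) {
  depth <- as.integer(round(coverage))
  if (!is.finite(qual_threshold)) return(0)
  p <- site_alt_prob(genotype, contamination, error_rate)
  k <- 0:depth
  called <- called_variant(rep(depth, depth + 1L), k, error_rate,
                           prior_variant, qual_threshold)
  sum(stats::dbinom(k, depth, p)[called])
}
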