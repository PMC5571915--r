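# Enrichment and evaluation statistics: observed/expected ratios, odds
# ratios with exact two-tailed p-values and Woolf confidence intervals,
# sensitivity/precision, and random-surface baselines.

#' Observed/expected ratio of variants in a region
#'
#' The observed fraction of nsSNPs found in a protein region divided by the
#' fraction expected by chance, the latter estimated from the region's
#' share of all residues:
#' `(n_region / n_total_snps) / (r_region / r_total)`.
#'
#' @param n_region Variants observed in the region.
#' @param n_total_snps All variants of that class.
#' @param r_region Residues in the region.
#' @param r_total All residues.
#' @return The O/E ratio (vectorized). Zero denominators yield `NA` with a
#'   warning.
#' @examples
#' observed_expected_ratio(399, 832, 21710, 76168) # ~1.68
#' @export
observed_expected_ratio <- function(n_region, n_total_snps, r_region,
                                    r_total) {
  bad <- n_total_snps <= 0 | r_total <= 0 | r_region <= 0
  if (any(bad)) {
    warn("zero denominator in O/E ratio; returning NA")
  }
  out <- (n_region / n_total_snps) / (r_region / r_total)
  out[bad] <- NA_real_
  out
}

#' Two-tailed exact p-value for a region contingency
#'
#' Fisher's exact test on the 2x2 table
#' `[[n_i, N_i - n_i], [n_j, N_j - n_j]]`.
#'
#' @param n_i,N_i Variant and residue counts in region i.
#' @param n_j,N_j Variant and residue counts in region j.
#' @return Two-tailed p-value.
#' @export
two_tailed_p <- function(n_i, N_i, n_j, N_j) {
  .check_counts(n_i, N_i, n_j, N_j)
  fisher.test(matrix(c(n_i, N_i - n_i, n_j, N_j - n_j), nrow = 2,
                     byrow = TRUE))$p.value
}

.check_counts <- function(n_i, N_i, n_j, N_j) {
  if (N_i <= 0 || N_j <= 0) abort("region residue counts must be positive")
  if (n_i < 0 || n_j < 0 || n_i > N_i || n_j > N_j) {
    abort("variant counts must satisfy 0 <= n <= N")
  }
  invisible(TRUE)
}

#' Odds ratio of variant occurrence between two regions
#'
#' The preference of a variant class for region i over region j:
#' `OR = (P_i / (1 - P_i)) / (P_j / (1 - P_j))` with `P = n / N` the
#' per-residue variant probability in each region, equal to the
#' cross-product ratio `n_i (N_j - n_j) / (n_j (N_i - n_i))`. A zero cell
#' triggers the Haldane-Anscombe +0.5 correction, flagged in the output.
#' The confidence interval is the Woolf (log-OR normal) interval; the
#' p-value is Fisher's exact two-tailed test.
#'
#' @inheritParams two_tailed_p
#' @param conf_level Confidence level of the Woolf interval.
#' @param region_i,region_j Optional labels carried into the result.
#' @return A one-row `enrichment_result` tibble: `region_i`, `region_j`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`, `p_value`, `corrected`.
#' @examples
#' odds_ratio(183, 23779, 250, 30679) # ~0.94
#' @export
odds_ratio <- function(n_i, N_i, n_j, N_j, conf_level = 0.95,
                       region_i = "i", region_j = "j") {
  .check_counts(n_i, N_i, n_j, N_j)
  a <- n_i; b <- N_i - n_i; c_ <- n_j; d <- N_j - n_j
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (c_ * b)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  res <- tibble(
    region_i = region_i, region_j = region_j,
    odds_ratio = or,
    ci_lo = exp(log(or) - zq * se),
    ci_hi = exp(log(or) + zq * se),
    p_value = two_tailed_p(n_i, N_i, n_j, N_j),
    corrected = corrected)
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Sensitivity and precision of a residue-set prediction
#'
#' `TP = |predicted intersect truth|`, `FP = |predicted \ truth|`,
#' `FN = |truth \ predicted|`; sensitivity `TP / (TP + FN)` and precision
#' `TP / (TP + FP)`. Undefined ratios (empty truth or empty prediction)
#' are returned as `NA`, never 0.
#'
#' @param predicted,truth Character vectors of residue keys, subsets of
#'   `universe`.
#' @param universe All candidate residue keys.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `precision`.
#' @export
evaluate_prediction <- function(predicted, truth, universe) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  if (length(setdiff(predicted, universe)) > 0 ||
      length(setdiff(truth, universe)) > 0) {
    abort("predicted and truth sets must be subsets of the universe")
  }
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  if (length(truth) == 0) warn("empty truth set; sensitivity undefined")
  tibble(tp = tp, fp = fp, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Random-surface baseline prediction
#'
#' Uniformly samples a fixed fraction of the surface residues without
#' replacement, as a size-matched random control for interface
#' predictions. Reproducible by seed.
#'
#' @param surface_residues Character vector of surface residue keys.
#' @param fraction Fraction of the surface to select, in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of selected residue keys.
#' @export
random_surface_baseline <- function(surface_residues, fraction, seed) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  n <- round(fraction * length(surface_residues))
  withr::with_seed(seed, sample(surface_residues, n))
}

#' Enrichment statistics of a region census
#'
#' Derives, for one census context and variant category, the quantities
#' used to characterize variant location preferences: observed and
#' expected percentage distributions over core / interface /
#' non-interacting surface, O/E ratios per region, the interface
#' versus non-interface odds ratio, the interface hot-spot versus
#' non-interface odds ratio and hot-spot O/E, and the fraction of surface
#' residues that are at an interface.
#'
#' @param census A `region_census` tibble (e.g. [interaction_census()]).
#' @param category Variant category to analyze.
#' @return A list with elements `observed_pct`, `expected_pct` (named
#'   vectors over core/interface/non_interface), `oe` (named O/E ratios,
#'   incl. `hotspot_interface`), `or_interface` and `or_hotspot`
#'   (`enrichment_result` rows), and `surface_interface_fraction`.
#' @export
census_statistics <- function(census, category = "DISEASE") {
  rc <- function(region) census_count(census, "residues", region)
  vc <- function(region) census_count(census, category, region)
  regions <- c("core", "interface", "non_interface")
  n_tot <- vc("total")
  r_tot <- rc("total")
  observed <- vapply(regions, vc, numeric(1))
  expected <- vapply(regions, rc, numeric(1))
  oe <- vapply(regions, function(r) {
    observed_expected_ratio(vc(r), n_tot, rc(r), r_tot)
  }, numeric(1))
  oe <- c(oe, hotspot_interface = observed_expected_ratio(
    vc("hotspot_interface"), n_tot, rc("hotspot_interface"), r_tot))
  list(
    observed_pct = 100 * observed / n_tot,
    expected_pct = 100 * expected / r_tot,
    oe = oe,
    or_interface = odds_ratio(vc("interface"), rc("interface"),
                              vc("non_interface"), rc("non_interface"),
                              region_i = "interface",
                              region_j = "non_interface"),
    or_hotspot = odds_ratio(vc("hotspot_interface"), rc("hotspot_interface"),
                            vc("non_interface"), rc("non_interface"),
                            region_i = "hotspot_interface",
                            region_j = "non_interface"),
    surface_interface_fraction =
      rc("interface") / (rc("interface") + rc("non_interface")))
}
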