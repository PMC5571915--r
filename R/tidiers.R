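# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a docking run
#'
#' @param x A `docking_run`.
#' @param ... Unused.
#' @return The pose table as a tibble (one row per pose).
#' @export
tidy.docking_run <- function(x, ...) {
  as_tibble(x$poses)
}

#' Summarize a docking run
#'
#' @param x A `docking_run`.
#' @param ... Unused.
#' @return A one-row tibble: pose counts, grid settings, seed and (if
#'   rescored) the best total energy.
#' @export
glance.docking_run <- function(x, ...) {
  tibble(n_poses = nrow(x$poses),
         n_rotations = x$params$n_rotations,
         spacing = x$params$spacing,
         seed = x$params$seed,
         rescored = isTRUE(x$rescored),
         best_shape = max(x$poses$shape_score),
         best_total = if (isTRUE(x$rescored)) min(x$poses$total)
                      else NA_real_)
}

#' Tidy a NIP profile
#'
#' @param x A `nip_profile`.
#' @param ... Unused.
#' @return The per-residue table as a plain tibble.
#' @export
tidy.nip_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Summarize a NIP profile
#'
#' @param x A `nip_profile`.
#' @param ... Unused.
#' @return A one-row tibble: residue counts, hot-spot and patch sizes, the
#'   NIP cutoff and patch radius, and the number of poses used.
#' @export
glance.nip_profile <- function(x, ...) {
  tibble(n_residues = nrow(x),
         n_hotspots = sum(x$hotspot),
         n_extended = sum(x$extended_interface),
         cutoff = attr(x, "cutoff"),
         radius = attr(x, "radius"),
         n_poses_used = attr(x, "n_poses_used"))
}

#' Tidy a region census
#'
#' @param x A `region_census`.
#' @param ... Unused.
#' @return The census in wide form: one row per group, one column per
#'   region.
#' @export
tidy.region_census <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_wider(names_from = "region", values_from = "count")
}

#' Summarize an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A one-row tibble with the odds ratio, confidence bounds and
#'   p-value.
#' @export
glance.enrichment_result <- function(x, ...) {
  as_tibble(x)[, c("odds_ratio", "ci_lo", "ci_hi", "p_value", "corrected")]
}
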