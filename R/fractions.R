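#' Per-fraction normalization factors from non-normalized intensity sums
#'
#' Because each sucrose-gradient band has a fundamentally different protein
#' composition, per-run normalization of the label-free intensities is
#' replaced by per-fraction factors computed from the sums of all
#' non-normalized protein intensities of each fraction: each fraction's
#' factor is the mean of all fraction totals divided by that fraction's
#' total, so multiplying a fraction by its factor equalizes the totals. The
#' anchor (mean total) is an arbitrary convention — it cancels exactly in
#' the per-protein distributions computed downstream.
#'
#' @param table Long tibble with columns `protein`, `fraction`, `intensity`
#'   (non-negative; missing proteins recorded as zero), as produced by
#'   [gen_fraction_table()] or [read_fraction_tsv()].
#' @return Tibble with `fraction`, `total`, `factor`.
#' @export
normalization_factors <- function(table) {
  check_fraction_table(table)
  totals <- table |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(sprintf("Fraction(s) with zero total intensity: %s",
                  paste(totals$fraction[totals$total <= 0], collapse = ", ")))
  }
  totals$factor <- mean(totals$total) / totals$total
  totals
}

check_fraction_table <- function(table) {
  need <- c("protein", "fraction", "intensity")
  if (!all(need %in% names(table))) {
    abort("Fraction table needs `protein`, `fraction` and `intensity` columns.")
  }
  if (any(table$intensity < 0)) abort("Intensities must be non-negative.")
  if (dplyr::n_distinct(table$fraction) < 2L) {
    abort("At least two fractions are required.")
  }
  invisible(table)
}

#' Per-protein distribution across gradient fractions
#'
#' Applies the per-fraction normalization factors and divides each protein's
#' normalized intensities by its row sum, yielding the share of each protein
#' found in each gradient band. Proteins absent from every fraction are
#' excluded and reported in the `"excluded_proteins"` attribute.
#'
#' @inheritParams normalization_factors
#' @return Tibble with `protein`, `fraction`, `share` (each protein's shares
#'   sum to 1); extra identity columns (e.g. `archetype`) are carried along.
#' @export
fraction_distribution <- function(table) {
  factors <- normalization_factors(table)
  out <- table |>
    dplyr::left_join(factors[, c("fraction", "factor")], by = "fraction") |>
    dplyr::mutate(normalized = .data$intensity * .data$factor) |>
    dplyr::group_by(.data$protein) |>
    dplyr::mutate(row_total = sum(.data$normalized)) |>
    dplyr::ungroup()
  empty <- unique(out$protein[out$row_total == 0])
  if (length(empty)) {
    warn(sprintf("%d protein(s) with all-zero intensities excluded.",
                 length(empty)))
  }
  out <- out |>
    dplyr::filter(.data$row_total > 0) |>
    dplyr::mutate(share = .data$normalized / .data$row_total) |>
    dplyr::select(-"intensity", -"factor", -"normalized", -"row_total")
  attr(out, "excluded_proteins") <- empty
  out
}

#' Flag proteins enriched in a target gradient fraction
#'
#' A protein is called enriched when its share in the target fraction meets
#' the threshold — by default 75%, the cutoff separating specific components
#' of the PSI-LHC band from proteins spread across the gradient.
#'
#' @param dist Distribution tibble from [fraction_distribution()].
#' @param target Fraction label to test (e.g. `"PSI-LHC"`).
#' @param threshold Minimum target share for an enrichment call.
#' @return Tibble with `protein`, `target_share`, `enriched` (plus carried
#'   identity columns).
#' @export
enrichment_call <- function(dist, target, threshold = 0.75) {
  if (!target %in% as.character(unique(dist$fraction))) {
    abort(sprintf("Unknown fraction label: %s", target))
  }
  carry <- setdiff(names(dist), c("fraction", "share"))
  dist |>
    dplyr::filter(.data$fraction == target) |>
    dplyr::transmute(dplyr::across(dplyr::all_of(carry)),
                     target_share = .data$share,
                     enriched = .data$share >= threshold)
}

#' Line plot of protein distributions across gradient fractions
#'
#' @param dist Distribution tibble from [fraction_distribution()].
#' @return A ggplot object.
#' @export
plot_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(.data$fraction, .data$share,
                                     group = .data$protein)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "Gradient fraction", y = "Share of protein intensity",
                  title = "Protein distribution across gradient fractions") +
    ggplot2::theme_minimal()
}
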