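# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a characterization report
#'
#' @param x A `characterization_report`.
#' @param component Which table to return.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.characterization_report <- function(x, component = c("coverage", "sequons",
                                                          "matches", "disulfide",
                                                          "scrambling", "glycoforms",
                                                          "pi"), ...) {
  component <- match.arg(component)
  out <- switch(component,
    coverage = x$coverage,
    sequons = x$sequons,
    matches = x$matches,
    disulfide = if (inherits(x$disulfide, "disulfide_report")) x$disulfide$expected
                else x$disulfide$expected,
    scrambling = if (inherits(x$disulfide, "disulfide_report")) x$disulfide$scrambling
                 else NULL,
    glycoforms = x$glycoforms,
    pi = x$pi_summary
  )
  if (is.null(out)) {
    stop("report has no '", component, "' component (stage was not run)", call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' One-row summary of a characterization report
#'
#' @param x A `characterization_report`.
#' @param ... Unused.
#' @return A one-row tibble: coverage fraction, sequon counts, disulfide
#'   and scrambling tallies, glycoform count, pI shift.
#' @export
glance.characterization_report <- function(x, ...) {
  tibble::tibble(
    coverage = if (is.null(x$coverage)) NA_real_ else mean(x$coverage$fraction),
    n_sequons = nrow(x$sequons),
    n_occupied = sum(x$sequons$occupied %in% TRUE),
    n_disulfide_expected = if (is.null(x$disulfide)) NA_integer_
                           else nrow(x$disulfide$expected),
    n_disulfide_matched = if (inherits(x$disulfide, "disulfide_report"))
                            sum(x$disulfide$expected$matched) else NA_integer_,
    n_scrambling_hits = if (inherits(x$disulfide, "disulfide_report"))
                          nrow(x$disulfide$scrambling) else NA_integer_,
    n_glycoforms = if (is.null(x$glycoforms)) NA_integer_ else nrow(x$glycoforms),
    pi_glycosylated = x$pi_summary$pi[1],
    pi_deglycosylated = x$pi_summary$pi[2],
    pi_shift = x$pi_summary$pi[2] - x$pi_summary$pi[1]
  )
}

#' Tidy a disulfide report
#'
#' @param x A `disulfide_report`.
#' @param which `"expected"` or `"scrambling"`.
#' @param ... Unused.
#' @export
tidy.disulfide_report <- function(x, which = c("expected", "scrambling"), ...) {
  which <- match.arg(which)
  tibble::as_tibble(x[[which]])
}

#' Plot matching mass errors
#'
#' Signed mass error against MH+ for every matched peak; unmatched peaks
#' are shown on the zero line. Isotope-offset matches are highlighted.
#'
#' @param object A `match_results` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.match_results <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$status <- dplyr::case_when(
    !df$matched ~ "unmatched",
    df$isotope_offset ~ "isotope-offset match",
    TRUE ~ "matched"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed,
                                   y = ifelse(.data$matched, .data$error_da, 0),
                                   colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "observed MH+ (Da)", y = "mass error (Da)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot sequence coverage
#'
#' Covered intervals per chain as horizontal segments.
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_report <- function(object, ...) {
  iv <- purrr::map2_dfr(object$chain_id, object$intervals, function(cid, m) {
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(chain_id = cid, start = m[, "start"], end = m[, "end"])
  })
  chains <- tibble::as_tibble(object)[c("chain_id", "length", "fraction")]
  ggplot2::ggplot(chains) +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = .data$length,
                                       y = .data$chain_id, yend = .data$chain_id),
                          colour = "grey80", linewidth = 4) +
    (if (nrow(iv) > 0)
      ggplot2::geom_segment(data = iv,
                            ggplot2::aes(x = .data$start, xend = .data$end,
                                         y = .data$chain_id, yend = .data$chain_id),
                            colour = "steelblue", linewidth = 4)) +
    ggplot2::labs(x = "residue position", y = NULL,
                  title = sprintf("sequence coverage: %s",
                                  paste(sprintf("%s %.0f%%", chains$chain_id,
                                                100 * chains$fraction),
                                        collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot a PNGase F time course as a pI profile
#'
#' The mixture components at each time point, weight against pI — the
#' in-silico analogue of the capillary-electrophoresis electropherogram
#' collapsing and shifting acid-ward as glycans are released.
#'
#' @param object A `pngasef_timecourse`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pngasef_timecourse <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$weight > 1e-4, ]
  df$hours_f <- factor(paste(df$hours, "h"),
                       levels = paste(sort(unique(df$hours)), "h"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pi, ymax = .data$weight, ymin = 0)) +
    ggplot2::geom_linerange(colour = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$hours_f)) +
    ggplot2::labs(x = "isoelectric point (pI)", y = "species weight") +
    ggplot2::theme_minimal()
}

#' Plot per-site glycoform assignments
#'
#' @param object A `site_glycoforms` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.site_glycoforms <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$y <- if (all(!is.na(df$intensity))) df$intensity else 1 / (abs(df$error_da) + 0.01)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rank), y = .data$y,
                                   fill = .data$composition)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$site), scales = "free_y") +
    ggplot2::labs(x = "abundance rank", y = "intensity", fill = "composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
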