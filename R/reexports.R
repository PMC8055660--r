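#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for falffprog result objects
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (slice tSNR values, coefficients, feature rows, tau pairs), `glance()` a
#' one-row summary, `augment()` per-subject predictions.
#'
#' @param x A falffprog result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_falffprog
NULL
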