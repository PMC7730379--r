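#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reliability report
#'
#' `tidy()` returns the reliability curves, one row per pool size:
#' `n`, `r2`, `tertile_accuracy`, `quartile_accuracy` (accuracies in
#' percent). `glance()` returns a one-row summary of the run.
#'
#' @param x A `reliability_report` from [run_scenario()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy reliability_report
#' @export
tidy.reliability_report <- function(x, ...) {
  x$curves
}

#' @rdname tidy.reliability_report
#' @method glance reliability_report
#' @export
glance.reliability_report <- function(x, ...) {
  nmax <- max(x$curves$n)
  last <- x$curves[x$curves$n == nmax, ]
  first <- x$curves[x$curves$n == 1L, ]
  tibble::tibble(
    n_individuals = x$config$n_individuals,
    max_samples = x$config$max_samples,
    sample_timing = x$config$sample_timing,
    standardization = x$config$standardization,
    r2_1 = first$r2,
    r2_max = last$r2,
    tertile_accuracy_max = last$tertile_accuracy,
    quartile_accuracy_max = last$quartile_accuracy,
    icc = x$icc$icc
  )
}
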