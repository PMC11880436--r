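#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter arrange bind_rows group_by summarise
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# trapezoid integral over a uniform grid, fast path (no x vector needed)
.trapz_uniform <- function(y, dt) {
  n <- length(y)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}
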