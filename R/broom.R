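#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.unit_cell_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "gamma"),
                 estimate = c(x$a, x$b, x$gamma),
                 unit = c("nm", "nm", "degree"))
}

#' @export
glance.unit_cell_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, gamma = x$gamma, n_centres = x$n_centres)
}

#' @export
tidy.honeycomb_metrology <- function(x, ...) {
  tibble::as_tibble(x$pores)
}

#' @export
glance.honeycomb_metrology <- function(x, ...) {
  tibble::tibble(a = x$unit_cell$a, b = x$unit_cell$b,
                 gamma = x$unit_cell$gamma, chirality = x$chirality,
                 pore_d = attr(x$pores, "d_mean"),
                 pore_area = attr(x$pores, "area_mean"),
                 n_pores = nrow(x$pores),
                 n_centres = x$n_centres)
}

#' @export
tidy.dimer <- function(x, ...) x$motifs

#' @export
glance.dimer <- function(x, ...) {
  fp <- dimer_footprint(x)
  tibble::tibble(peptide = x$peptide_a$sequence$name,
                 arrangement = x$arrangement, gap = x$gap,
                 length = fp[["length"]], width = fp[["width"]],
                 n_motifs = nrow(x$motifs))
}
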