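#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.slm_result <- function(x, ...) x$loci

#' @export
glance.slm_result <- function(x, ...) x$summary

#' @export
tidy.dmr_result <- function(x, ...) x$dmrs

#' @export
glance.dmr_result <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$windows),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    context = x$params$context
  )
}

#' @export
tidy.te_clusters <- function(x, ...) x$labels

#' @export
glance.te_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n_features = nrow(x$labels))
}
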