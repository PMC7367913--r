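#' Size restrictions for matched molecular pair fragmentation
#'
#' Bundles the thresholds that confine single-cut fragmentations and the
#' resulting matched molecular pairs (MMPs) to transformations typical of
#' analog series, plus the potency-difference threshold that turns an MMP
#' into an MMP-cliff.
#'
#' @param core_to_sub_ratio Minimum ratio of core to substituent heavy-atom
#'   counts (default 2: the core must be at least twice the substituent).
#' @param max_sub_heavy Maximum substituent size in heavy atoms (default 13).
#' @param max_exchange_diff Maximum heavy-atom size difference between the
#'   two substituents exchanged in an MMP (default 8).
#' @param min_delta_pki Minimum pKi difference for a cliff (default 2.0,
#'   i.e. an at least 100-fold potency difference).
#' @return An object of class `size_rules`.
#' @examples
#' size_rules()
#' size_rules(max_sub_heavy = 10)
#' @export
size_rules <- function(core_to_sub_ratio = 2,
                       max_sub_heavy = 13L,
                       max_exchange_diff = 8L,
                       min_delta_pki = 2.0) {
  vals <- c(core_to_sub_ratio, max_sub_heavy, max_exchange_diff, min_delta_pki)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    cli::cli_abort("All size-rule thresholds must be positive and finite.")
  }
  structure(
    list(
      core_to_sub_ratio = as.numeric(core_to_sub_ratio),
      max_sub_heavy = as.integer(max_sub_heavy),
      max_exchange_diff = as.integer(max_exchange_diff),
      min_delta_pki = as.numeric(min_delta_pki)
    ),
    class = "size_rules"
  )
}

#' @export
print.size_rules <- function(x, ...) {
  cat("MMP size rules:\n")
  cat(sprintf("  core/substituent heavy-atom ratio >= %g\n", x$core_to_sub_ratio))
  cat(sprintf("  substituent heavy atoms          <= %d\n", x$max_sub_heavy))
  cat(sprintf("  exchanged-substituent size diff  <= %d\n", x$max_exchange_diff))
  cat(sprintf("  cliff potency difference (dpKi)  >= %g\n", x$min_delta_pki))
  invisible(x)
}

as_size_rules <- function(rules) {
  if (inherits(rules, "size_rules")) return(rules)
  if (is.list(rules)) return(do.call(size_rules, rules))
  cli::cli_abort("{.arg rules} must be a {.cls size_rules} object (see {.fn size_rules}).")
}
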