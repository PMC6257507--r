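`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All package errors carry a class so callers (and the pipeline) can
#' distinguish configuration problems from data-validation problems.
#' @noRd
ironmr_error <- function(msg, class) {
  stop(structure(
    class = c(class, "ironmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

VALID_ALLELES <- c("A", "C", "G", "T")

#' Is an allele pair palindromic (A/T or C/G)?
#' @noRd
is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Complement of a DNA allele
#' @noRd
allele_complement <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

#' Two-sided p-value from a normal z statistic
#' @noRd
z_pvalue <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
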