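#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test fisher.test median p.adjust pchisq
#'   phyper plogis pnorm pt qgamma qnorm quantile rbinom rgamma rnbinom
#'   rnorm runif sd setNames uniroot var vcov wilcox.test rexp
#' @importFrom utils head read.delim write.table
#' @importFrom methods as is
NULL

.log_msg <- function(...) {
  message("[lnmsig] ", sprintf(...))
}

#' Canonicalize gene identifiers
#'
#' Trims surrounding whitespace and strips a trailing version suffix
#' (everything after the first "."), preserving case. The operation is
#' idempotent.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector of canonical identifiers.
#' @export
canonical_gene_ids <- function(ids) {
  ids <- trimws(as.character(ids))
  sub("\\..*$", "", ids)
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

## Dense numeric matrix view of an expression matrix (genes x columns)
.dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}
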