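#' @useDynLib ddunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang hash
NULL

#' Stable hash of a configuration object
#'
#' Hashes the slot contents of an S4 configuration (or any R value) so that
#' pipeline artifacts can be stamped with the exact settings that produced
#' them.
#'
#' @param x an S4 config object or plain R value.
#' @return Character hash.
#' @export
configHash <- function(x) {
  if (isVirtualClass(class(x)) || !isS4(x)) return(rlang::hash(x))
  sl <- methods::slotNames(class(x))
  rlang::hash(stats::setNames(lapply(sl, function(s) methods::slot(x, s)), sl))
}
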