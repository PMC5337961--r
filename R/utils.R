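#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq pnorm qnorm sd t.test glm binomial coef logLik
#'   predict rbinom runif rnorm setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

# reverse complement of an ACGT string
revcomp <- function(seq) {
  x <- rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]])
  paste(x, collapse = "")
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

is_snp_allele <- function(a) {
  is.character(a) & nchar(a) == 1L & a %in% BASES
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
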