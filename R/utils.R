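#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor dhyper lm median model.matrix p.adjust pchisq
#'   phyper plogis predict pt qlogis quantile rbinom rnorm runif sd var
#'   wilcox.test
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib glycoreg, .registration = TRUE
NULL

SAMPLE_GROUPS <- c("TNBC", "non-TNBC", "normal")

#' Stop with a formatted message
#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Warn with a formatted message
#' @noRd
warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a child RNG seed from a base seed and a stream label
#'
#' Keeps independent stages decoupled under one user-facing seed while
#' staying inside the 32-bit integer range.
#' @noRd
child_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483563L
  as.integer(h) + 1L
}

#' Soft-thresholding operator
#' @noRd
soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Benjamini-Hochberg adjustment (thin wrapper, NA-safe)
#' @noRd
bh_adjust <- function(p) p.adjust(p, method = "BH")
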