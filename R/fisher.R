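#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is the sum, over the hypergeometric support given the
#' table's margins, of all table probabilities not exceeding the observed
#' table's probability (with a 1e-7 relative tolerance absorbing floating
#' point ties).  A table with a zero margin carries no information; p is 1
#' with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector (a, b, c, d) read row-wise
#' @return two-sided p-value in [0, 1]
#' @export
fisher_2x2 <- function(table) {
  x <- as.integer(round(as.numeric(table)))
  if (length(x) != 4L || any(x < 0L) || any(is.na(x)))
    stop("fisher_2x2 needs four non-negative counts", call. = FALSE)
  if (is.matrix(table)) x <- as.integer(t(table)) # row-wise (a, b, c, d)
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) {
    warning("zero margin: p set to 1")
    return(1)
  }
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
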