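# Shared numeric and information-theoretic helpers.

# x * log2(x) with the continuous extension plogp(0) = 0; preserves dims.
plogp <- function(x) {
  out <- x
  out[] <- 0
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# Shannon entropy (bits) of a non-negative weight vector (normalized internally).
shannon_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(plogp(p))
}

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items:
#' `AMI = (MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`, where the expected
#' mutual information `E[MI]` is taken over the hypergeometric model of
#' random contingency tables with fixed margins, and the normalizer uses
#' the arithmetic mean of the two label entropies.  Used to score recovery
#' of planted temporal regimes by network modules.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in (-1, 1]; 1 for identical partitions, about 0 for
#'   independent ones.
#' @examples
#' ami(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
#' @export
ami <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  tab <- table(a, b)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  # observed mutual information (bits -> use natural log internally, unit cancels)
  mi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + (nij / n) * log(nij * n / (ai[i] * bj[j]))
    }
  }
  ha <- -sum((ai / n) * log(ai / n))
  hb <- -sum((bj / n) * log(bj / n))
  # expected MI under the permutation (hypergeometric) model
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(ai[i] + bj[j] - n, 1)
      hi <- min(ai[i], bj[j])
      if (lo > hi) next
      nij <- lo:hi
      # P(N_ij = nij) for the hypergeometric with margins ai, bj
      lp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
        lgamma(n - ai[i] + 1) + lgamma(n - bj[j] + 1) -
        lgamma(n + 1) - lgamma(nij + 1) - lgamma(ai[i] - nij + 1) -
        lgamma(bj[j] - nij + 1) - lgamma(n - ai[i] - bj[j] + nij + 1)
      emi <- emi + sum(exp(lp) * (nij / n) * log(pmax(nij * n / (ai[i] * bj[j]), .Machine$double.xmin)))
    }
  }
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-15) return(1)  # both labelings trivial (single class)
  as.numeric((mi - emi) / denom)
}

# Weighted median of x with weights w (lower of the two middle values on ties).
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Read a delimited table, auto-detecting tab / comma / semicolon from the header.
read_table_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else if (grepl(";", header)) ";" else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
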