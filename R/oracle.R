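#' Brute-force sib-pair IBD likelihood table by parental enumeration
#'
#' Independent oracle for the closed-form likelihoods in
#' [pair_likelihoods_given_ibd()]: enumerates every ordered parental
#' genotype pair under Hardy-Weinberg (probability = product of the four
#' allele frequencies) crossed with the 16 equally likely transmission
#' patterns of a sib pair, classifies each outcome's IBD count from
#' parental-origin labels, tallies the joint probability of each ordered
#' pair of unordered sib genotypes, and divides by the IBD prior
#' (1/4, 1/2, 1/4). Enumeration is limited to markers with at most 6
#' alleles.
#'
#' @param freqs Numeric vector of allele frequencies (allele codes are
#'   1..length(freqs), or the names of `freqs`).
#' @return A 3-dimensional array `L[g1, g2, k]` of
#'   \eqn{P(g_1, g_2 \mid IBD = k-1)} indexed by unordered genotype labels
#'   `"a/b"` (a <= b).
#' @seealso [ibd_oracle()]
#' @export
ibd_oracle_table <- function(freqs) {
  k <- length(freqs)
  if (k > 6L) stop("enumeration oracle restricted to markers with <= 6 alleles")
  if (abs(sum(freqs) - 1) > 1e-9) stop("`freqs` must sum to 1")
  codes <- if (!is.null(names(freqs))) names(freqs) else as.character(seq_len(k))
  geno_lab <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "/")
  labs <- unique(as.vector(outer(codes, codes, function(i, j)
    geno_lab(match(i, codes), match(j, codes)))))
  labs <- sort(labs)
  # relabel to code-based labels for output
  code_lab <- function(lab) {
    ij <- as.integer(strsplit(lab, "/")[[1L]])
    paste(codes[ij[1L]], codes[ij[2L]], sep = "/")
  }
  joint <- array(0, dim = c(length(labs), length(labs), 3L),
                 dimnames = list(labs, labs, c("L0", "L1", "L2")))
  grid <- expand.grid(f1 = seq_len(k), f2 = seq_len(k),
                      m1 = seq_len(k), m2 = seq_len(k))
  pg <- freqs[grid$f1] * freqs[grid$f2] * freqs[grid$m1] * freqs[grid$m2]
  trans <- expand.grid(i = 1:2, j = 1:2, l = 1:2, o = 1:2)
  for (t in seq_len(nrow(trans))) {
    i <- trans$i[t]; j <- trans$j[t]; l <- trans$l[t]; o <- trans$o[t]
    ibd <- (i == l) + (j == o)
    s1p <- if (i == 1L) grid$f1 else grid$f2
    s1m <- if (j == 1L) grid$m1 else grid$m2
    s2p <- if (l == 1L) grid$f1 else grid$f2
    s2m <- if (o == 1L) grid$m1 else grid$m2
    g1 <- geno_lab(s1p, s1m)
    g2 <- geno_lab(s2p, s2m)
    tab <- rowsum(pg / 16, paste(g1, g2, sep = "|"))
    ij <- strsplit(rownames(tab), "|", fixed = TRUE)
    i1 <- match(vapply(ij, `[[`, character(1), 1L), labs)
    i2 <- match(vapply(ij, `[[`, character(1), 2L), labs)
    idx <- cbind(i1, i2, ibd + 1L)
    joint[idx] <- joint[idx] + tab[, 1L]
  }
  prior <- c(0.25, 0.5, 0.25)
  for (s in 1:3) joint[, , s] <- joint[, , s] / prior[s]
  dimnames(joint)[[1L]] <- vapply(labs, code_lab, character(1))
  dimnames(joint)[[2L]] <- dimnames(joint)[[1L]]
  joint
}

#' Oracle likelihoods for one sib-pair genotype configuration
#'
#' Convenience wrapper around [ibd_oracle_table()] returning
#' `c(L0, L1, L2)` for a single ordered pair of unordered genotypes.
#'
#' @param g1,g2 Integer allele pairs.
#' @param freqs Allele frequency vector (codes 1..k or named).
#' @return Named numeric vector `c(L0, L1, L2)`.
#' @examples
#' ibd_oracle(c(1, 2), c(1, 2), c(0.5, 0.5))  # 0.25 0.25 0.50
#' @export
ibd_oracle <- function(g1, g2, freqs) {
  tab <- ibd_oracle_table(freqs)
  codes <- if (!is.null(names(freqs))) names(freqs) else as.character(seq_along(freqs))
  lab <- function(g) {
    g <- sort(as.integer(g))
    paste(codes[g[1L]], codes[g[2L]], sep = "/")
  }
  tab[lab(g1), lab(g2), ]
}
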