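#' Gene-counting estimates of marker allele frequencies
#'
#' Every non-missing genotype contributes two allele observations; missing
#' alleles (code 0) are ignored. Sib correlation is deliberately ignored
#' (standard practice for this design; the bias is second order). External
#' frequency tables may be supplied to downstream functions instead.
#'
#' @param x An `edsp_cohort`, `edsp_ped`, or an integer genotype matrix with
#'   two columns per marker.
#' @param markers Optional list of [marker_def()] giving marker names; taken
#'   from `x` when it is a cohort.
#' @return An object of class `allele_freq_table`: a named list, one element
#'   per marker, each a named numeric vector of frequencies of the observed
#'   allele codes.
#' @examples
#' G <- rbind(c(1L, 1L), c(1L, 2L))
#' estimate_allele_frequencies(G)[[1]]  # 1 -> 0.75, 2 -> 0.25
#' @export
estimate_allele_frequencies <- function(x, markers = NULL) {
  if (inherits(x, "edsp_cohort")) {
    if (is.null(markers)) markers <- x$markers
    G <- x$genotypes
  } else if (inherits(x, "edsp_ped")) {
    G <- x$genotypes
  } else {
    G <- x
  }
  if (!is.matrix(G) || ncol(G) %% 2L != 0L) {
    stop("genotypes must form a matrix with two columns per marker")
  }
  m <- ncol(G) %/% 2L
  nm <- if (!is.null(markers)) .marker_names(.check_markers(markers))
        else paste0("M", seq_len(m))
  out <- vector("list", m)
  names(out) <- nm
  for (j in seq_len(m)) {
    a <- c(G[, 2L * j - 1L], G[, 2L * j])
    a <- a[!is.na(a) & a > 0L]
    if (length(a) == 0L) {
      stop("no observed genotypes at marker ", nm[j])
    }
    tab <- table(a)
    out[[j]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  structure(out, class = "allele_freq_table")
}

# frequency lookup by allele code; unobserved codes are an error, never
# silently smoothed
.freq_of <- function(freqs, alleles) {
  f <- freqs[as.character(alleles)]
  if (any(is.na(f))) {
    stop("genotype contains allele code(s) absent from the frequency table: ",
         paste(unique(alleles[is.na(f)]), collapse = ", "))
  }
  as.numeric(f)
}

# vectorised sib-pair genotype likelihoods given IBD state.
# a,b = sorted alleles of sib 1; c,d = sorted alleles of sib 2 (vectors).
# Returns an n x 3 matrix (L0, L1, L2).
.pair_lik_vec <- function(a, b, c_, d, freqs) {
  pa <- .freq_of(freqs, a); pb <- .freq_of(freqs, b)
  pc <- .freq_of(freqs, c_); pd <- .freq_of(freqs, d)
  P1 <- ifelse(a == b, pa^2, 2 * pa * pb)
  P2 <- ifelse(c_ == d, pc^2, 2 * pc * pd)
  L0 <- P1 * P2
  L2 <- P1 * as.numeric(a == c_ & b == d)
  # conditional P(g2 | g1, one allele shared IBD): the shared allele is a
  # uniformly chosen allele of g1, the other allele is a fresh population draw
  K_hom <- ifelse(c_ == d,
                  as.numeric(c_ == a) * pc,
                  as.numeric(c_ == a) * pd + as.numeric(d == a) * pc)
  K_het <- ifelse(c_ == d,
                  0.5 * as.numeric(c_ == a | c_ == b) * pc,
                  0.5 * (as.numeric(c_ == a | c_ == b) * pd +
                           as.numeric(d == a | d == b) * pc))
  L1 <- P1 * ifelse(a == b, K_hom, K_het)
  cbind(L0 = L0, L1 = L1, L2 = L2)
}

#' Sib-pair genotype likelihoods conditional on IBD state
#'
#' For an (ordered) pair of unordered sib genotypes at one marker, returns
#' \eqn{L_k = P(g_1, g_2 \mid \mathrm{IBD} = k)} for k = 0, 1, 2 under
#' Hardy-Weinberg equilibrium and random mating. `L2` is zero unless the
#' genotypes are identical; `L1` is zero when the pair shares no allele
#' state. These closed forms are validated exhaustively against the
#' parental-enumeration oracle [ibd_oracle()].
#'
#' @param g1,g2 Integer vectors of length 2 (unordered allele pairs; 0 =
#'   missing).
#' @param freqs Named numeric vector of allele frequencies for the marker
#'   (names are allele codes). Genotypes containing allele codes absent from
#'   `freqs` are an error.
#' @return Named numeric vector `c(L0, L1, L2)`, or `NULL` when either
#'   genotype is missing (the marker is uninformative for that pair).
#' @examples
#' f <- c("1" = 0.5, "2" = 0.5)
#' pair_likelihoods_given_ibd(c(1, 2), c(1, 2), f)  # 0.25 0.25 0.50
#' @export
pair_likelihoods_given_ibd <- function(g1, g2, freqs) {
  g1 <- sort(as.integer(g1)); g2 <- sort(as.integer(g2))
  if (length(g1) != 2L || length(g2) != 2L) {
    stop("genotypes must be allele pairs")
  }
  if (any(g1 == 0L) || any(g2 == 0L)) return(NULL)
  L <- .pair_lik_vec(g1[1L], g1[2L], g2[1L], g2[2L], freqs)
  stats::setNames(as.numeric(L[1L, ]), c("L0", "L1", "L2"))
}

#' Posterior IBD distribution for a sib pair at one marker
#'
#' Combines the conditional likelihoods with the unconditional full-sib IBD
#' prior (1/4, 1/2, 1/4): \eqn{f_k \propto \pi_k L_k}. Derived statistics:
#' `pihat = f1/2 + f2` (proportion of alleles shared IBD) and
#' `expected_shared = f1 + 2 f2` (expected number of alleles shared IBD,
#' the Haseman-Elston predictor). A monomorphic (uninformative) marker
#' returns the prior, i.e. `pihat = 0.5`.
#'
#' @inheritParams pair_likelihoods_given_ibd
#' @param prior IBD prior over 0/1/2 alleles shared (default full-sib
#'   (1/4, 1/2, 1/4)).
#' @return An object of class `ibd_posterior`: list with `f0`, `f1`, `f2`,
#'   `pihat`, `expected_shared`; or `NULL` for a missing genotype.
#' @examples
#' f <- c("1" = 0.5, "2" = 0.5)
#' ibd_posterior(c(1, 2), c(1, 2), f)  # f = (0.2, 0.4, 0.4), pihat = 0.6
#' @export
ibd_posterior <- function(g1, g2, freqs, prior = c(0.25, 0.5, 0.25)) {
  L <- pair_likelihoods_given_ibd(g1, g2, freqs)
  if (is.null(L)) return(NULL)
  w <- prior * L
  if (sum(w) <= 0) {
    stop("impossible genotype configuration: all IBD likelihoods are zero")
  }
  f <- w / sum(w)
  structure(list(f0 = f[[1L]], f1 = f[[2L]], f2 = f[[3L]],
                 pihat = f[[2L]] / 2 + f[[3L]],
                 expected_shared = f[[2L]] + 2 * f[[3L]]),
            class = "ibd_posterior")
}

#' @export
print.ibd_posterior <- function(x, ...) {
  cat(sprintf("IBD posterior: f = (%.4f, %.4f, %.4f), pihat = %.4f, E[shared] = %.4f\n",
              x$f0, x$f1, x$f2, x$pihat, x$expected_shared))
  invisible(x)
}

#' Per-marker IBD sharing profile of one sib pair
#'
#' @param g1,g2 Integer genotype rows (two entries per marker) for the two
#'   sibs.
#' @param markers List of [marker_def()] naming the markers, in genotype
#'   column order.
#' @param freqs An `allele_freq_table` (or named list of frequency vectors)
#'   covering the markers.
#' @return A data.frame with one row per marker: marker, f0, f1, f2, pihat,
#'   expected_shared, informative. Markers with missing genotypes are
#'   flagged `informative = FALSE` with `NA` posteriors and are excluded
#'   from downstream tests for that pair.
#' @export
pair_sharing_profile <- function(g1, g2, markers, freqs) {
  markers <- .check_markers(markers)
  m <- length(markers)
  nm <- .marker_names(markers)
  out <- data.frame(marker = nm, f0 = NA_real_, f1 = NA_real_, f2 = NA_real_,
                    pihat = NA_real_, expected_shared = NA_real_,
                    informative = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    post <- ibd_posterior(g1[c(2L * j - 1L, 2L * j)], g2[c(2L * j - 1L, 2L * j)],
                          freqs[[nm[j]]])
    if (!is.null(post)) {
      out[j, c("f0", "f1", "f2", "pihat", "expected_shared")] <-
        c(post$f0, post$f1, post$f2, post$pihat, post$expected_shared)
      out$informative[j] <- TRUE
    }
  }
  out
}

#' IBD sharing table for every pair and marker of a cohort
#'
#' The vectorised workhorse behind the linkage tests: computes the posterior
#' IBD distribution for each sib pair at each marker from sib genotypes
#' alone (pairwise-complete: markers with missing genotypes are flagged
#' uninformative for that pair).
#'
#' @param cohort An `edsp_cohort` (typically after [mask_parents()]).
#' @param freqs Optional `allele_freq_table`; by default frequencies are
#'   estimated from the cohort's genotyped individuals by gene counting.
#' @param pairs Optional subset of `cohort$pairs` (e.g. a [select_edsp()]
#'   result) restricting which pairs are profiled.
#' @param prior IBD prior (default (1/4, 1/2, 1/4)).
#' @return A data.frame: family_id, sib1, sib2, marker, f0, f1, f2, pihat,
#'   expected_shared, informative.
#' @export
sharing_table <- function(cohort, freqs = NULL, pairs = NULL,
                          prior = c(0.25, 0.5, 0.25)) {
  stopifnot(inherits(cohort, "edsp_cohort"))
  if (is.null(freqs)) freqs <- estimate_allele_frequencies(cohort)
  if (is.null(pairs)) pairs <- cohort$pairs
  key <- paste(cohort$individuals$family_id, cohort$individuals$individual_id)
  r1 <- match(paste(pairs$family_id, pairs$sib1), key)
  r2 <- match(paste(pairs$family_id, pairs$sib2), key)
  if (any(is.na(r1)) || any(is.na(r2))) stop("pair references unknown individuals")
  G <- cohort$genotypes
  nm <- .marker_names(cohort$markers)
  n <- length(r1)
  res <- vector("list", length(nm))
  for (j in seq_along(nm)) {
    c1 <- 2L * j - 1L; c2 <- 2L * j
    a <- pmin(G[r1, c1], G[r1, c2]); b <- pmax(G[r1, c1], G[r1, c2])
    cc <- pmin(G[r2, c1], G[r2, c2]); d <- pmax(G[r2, c1], G[r2, c2])
    ok <- a > 0L & cc > 0L
    f0 <- f1 <- f2 <- pih <- esh <- rep(NA_real_, n)
    if (any(ok)) {
      L <- .pair_lik_vec(a[ok], b[ok], cc[ok], d[ok], freqs[[nm[j]]])
      W <- sweep(L, 2L, prior, `*`)
      tot <- rowSums(W)
      if (any(tot <= 0)) {
        stop("impossible genotype configuration at marker ", nm[j])
      }
      W <- W / tot
      f0[ok] <- W[, 1L]; f1[ok] <- W[, 2L]; f2[ok] <- W[, 3L]
      pih[ok] <- W[, 2L] / 2 + W[, 3L]
      esh[ok] <- W[, 2L] + 2 * W[, 3L]
    }
    res[[j]] <- data.frame(family_id = pairs$family_id, sib1 = pairs$sib1,
                           sib2 = pairs$sib2, marker = nm[j],
                           f0 = f0, f1 = f1, f2 = f2, pihat = pih,
                           expected_shared = esh, informative = ok,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
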