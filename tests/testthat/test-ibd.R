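test_that("gene counting recovers allele frequencies", {
  G <- rbind(c(1L, 1L), c(1L, 2L))
  f <- estimate_allele_frequencies(G)
  expect_equal(unname(f[[1]]), c(0.75, 0.25))
  expect_equal(names(f[[1]]), c("1", "2"))
  # missing alleles are ignored, fully missing markers are an error
  G2 <- rbind(c(1L, 1L, 0L, 0L), c(1L, 2L, 0L, 0L))
  expect_error(estimate_allele_frequencies(G2), "no observed genotypes at marker M2")
  # simulated founders: every estimate near the generating 1/8
  ch <- simulate_families(250, trait_model(), equifreq_markers(1), seed = 67)
  founders <- ch$genotypes[ch$individuals$role == "parent", , drop = FALSE]
  est <- estimate_allele_frequencies(founders)[[1]]
  expect_length(est, 8L)
  expect_lt(max(abs(est - 0.125)), 0.02)
})

test_that("pair likelihoods match their textbook special cases", {
  f <- c("1" = 0.5, "2" = 0.5)
  expect_equal(unname(pair_likelihoods_given_ibd(c(1, 2), c(1, 2), f)),
               c(0.25, 0.25, 0.5))
  # opposite homozygotes force IBD = 0
  f2 <- c("1" = 0.3, "2" = 0.7)
  expect_equal(unname(pair_likelihoods_given_ibd(c(1, 1), c(2, 2), f2)),
               c(0.3^2 * 0.7^2, 0, 0))
  # monomorphic marker: completely uninformative
  expect_equal(unname(pair_likelihoods_given_ibd(c(1, 1), c(1, 1), c("1" = 1))),
               c(1, 1, 1))
  # missing genotype signals uninformative
  expect_null(pair_likelihoods_given_ibd(c(0, 1), c(1, 2), f))
  expect_error(pair_likelihoods_given_ibd(c(1, 3), c(1, 2), f), "absent")
})

test_that("IBD posteriors combine likelihoods with the full-sib prior", {
  f <- c("1" = 0.5, "2" = 0.5)
  post <- ibd_posterior(c(1, 2), c(1, 2), f)
  expect_equal(c(post$f0, post$f1, post$f2), c(0.2, 0.4, 0.4))
  expect_equal(post$pihat, 0.6)
  expect_equal(post$expected_shared, 1.2)
  expect_equal(post$expected_shared, 2 * post$pihat)
  # monomorphic marker returns the prior
  p0 <- ibd_posterior(c(1, 1), c(1, 1), c("1" = 1))
  expect_equal(c(p0$f0, p0$f1, p0$f2), c(0.25, 0.5, 0.25))
  expect_equal(p0$pihat, 0.5)
  # opposite homozygotes: certain IBD 0
  pz <- ibd_posterior(c(1, 1), c(2, 2), f)
  expect_equal(c(pz$f0, pz$f1, pz$f2), c(1, 0, 0))
  expect_equal(pz$pihat, 0)
  # a genotype made impossible by the frequency table is flagged
  expect_error(ibd_posterior(c(2, 2), c(2, 2), c("1" = 1, "2" = 0)),
               "impossible genotype")
})

test_that("posteriors are invariant to sib order and allele relabelling", {
  set.seed(71)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    f <- as.numeric(prop.table(runif(k) + 0.05))
    names(f) <- seq_len(k)
    g1 <- sample(k, 2, replace = TRUE)
    g2 <- if (runif(1) < 0.5) g1 else sample(k, 2, replace = TRUE)
    a <- ibd_posterior(g1, g2, f)
    b <- ibd_posterior(g2, g1, f)
    expect_equal(c(a$f0, a$f1, a$f2), c(b$f0, b$f1, b$f2), tolerance = 1e-12)
    # relabel alleles by a random permutation
    perm <- sample(k)
    f_rel <- f[order(perm)]
    names(f_rel) <- seq_len(k)
    c_ <- ibd_posterior(perm[g1], perm[g2], f_rel)
    expect_equal(c(a$f0, a$f1, a$f2), c(c_$f0, c_$f1, c_$f2), tolerance = 1e-12)
  }
})

test_that("closed-form likelihoods agree exhaustively with the enumeration oracle", {
  set.seed(73)
  for (k in 2:4) {
    for (draw in 1:2) {
      f <- as.numeric(prop.table(runif(k) + 0.1))
      names(f) <- seq_len(k)
      tab <- ibd_oracle_table(f)
      labs <- dimnames(tab)[[1]]
      for (l1 in labs) for (l2 in labs) {
        g1 <- as.integer(strsplit(l1, "/")[[1]])
        g2 <- as.integer(strsplit(l2, "/")[[1]])
        L <- pair_likelihoods_given_ibd(g1, g2, f)
        expect_lt(max(abs(L - tab[l1, l2, ])), 1e-12)
      }
      # each conditional likelihood table is a probability distribution over
      # ordered pairs of unordered genotypes
      for (s in 1:3) expect_equal(sum(tab[, , s]), 1, tolerance = 1e-12)
    }
  }
})

test_that("sharing tables are calibrated on unselected pairs", {
  ch <- mask_parents(simulate_families(1000, trait_model(),
                                       equifreq_markers(1, theta = 0),
                                       seed = 79))
  sh <- sharing_table(ch)
  expect_equal(nrow(sh), 1000L)
  expect_true(all(sh$informative))
  expect_equal(sh$expected_shared, 2 * sh$pihat, tolerance = 1e-12)
  # mean pihat near the unconditional 0.5
  expect_lt(abs(mean(sh$pihat) - 0.5), 3 * sqrt(0.125 / 1000))
  # the posterior tracks the recorded truth closely with 8-allele markers
  expect_gte(stats::cor(sh$pihat, ch$true_ibd[, "M1"] / 2), 0.8)
})

test_that("vectorised sharing equals the scalar per-pair profile", {
  ch <- mask_parents(simulate_families(25, trait_model(), equifreq_markers(3),
                                       seed = 83))
  freqs <- estimate_allele_frequencies(ch)
  sh <- sharing_table(ch, freqs = freqs)
  rows <- ch$individuals
  for (i in c(1, 7, 25)) {
    fam <- ch$pairs$family_id[i]
    g1 <- ch$genotypes[rows$family_id == fam & rows$individual_id == "3", ]
    g2 <- ch$genotypes[rows$family_id == fam & rows$individual_id == "4", ]
    prof <- pair_sharing_profile(g1, g2, ch$markers, freqs)
    got <- sh[sh$family_id == fam, c("f0", "f1", "f2", "pihat")]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(prof[c("f0", "f1", "f2", "pihat")])),
                 tolerance = 1e-12)
  }
})

test_that("missing genotypes are flagged uninformative and excluded", {
  ch <- mask_parents(simulate_families(6, trait_model(), equifreq_markers(2),
                                       seed = 89))
  # knock out sib 1's genotype at marker 1 of family 1 and all of family 2
  rows <- which(ch$individuals$family_id == "F0001" & ch$individuals$individual_id == "3")
  ch$genotypes[rows, 1:2] <- 0L
  rows2 <- which(ch$individuals$family_id == "F0002" &
                   ch$individuals$role == "offspring")
  ch$genotypes[rows2, ] <- 0L
  sh <- sharing_table(ch)
  expect_false(sh$informative[sh$family_id == "F0001" & sh$marker == "M1"])
  expect_true(sh$informative[sh$family_id == "F0001" & sh$marker == "M2"])
  expect_true(all(!sh$informative[sh$family_id == "F0002"]))
  expect_true(all(is.na(sh$pihat[!sh$informative])))
})

test_that("extreme discordant pairs share fewer alleles at a linked locus", {
  # strong QTL, fully linked marker: the selected pairs' TRUE sharing sits
  # below 0.5 (one-sided test at ~500 selected pairs)
  ch <- mask_parents(simulate_families(4000, model_qtl50(),
                                       equifreq_markers(1, theta = 0),
                                       seed = 97))
  sel <- select_edsp(ch)
  expect_gt(nrow(sel), 400L)
  idx <- match(sel$family_id, ch$pairs$family_id)
  pi_true <- ch$true_ibd[idx, "M1"] / 2
  tt <- stats::t.test(pi_true, mu = 0.5, alternative = "less")
  expect_lt(tt$p.value, 0.01)
  # and the estimated sharing shows the same deficit
  sh <- sharing_table(ch, pairs = sel)
  expect_lt(mean(sh$pihat), 0.5)
})
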