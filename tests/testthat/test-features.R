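test_that("residue profile is a one-hot encoding in fixed alphabet order", {
  rp <- residue_profile("A")
  expect_equal(unname(unlist(rp)), c(1, rep(0, 19)))
  rp3 <- residue_profile("ACD")
  expect_equal(dim(rp3), c(3, 20))
  expect_equal(unname(rowSums(rp3)), rep(1, 3))
  expect_equal(unname(which(unlist(rp3[2, ]) == 1)), 2)
  expect_error(residue_profile("ABZ"), "nonstandard")
})

test_that("physicochemical profile is a per-residue table lookup", {
  toy <- tibble::tibble(aa = c("A", "C", "D", "E", "F"),
                        f1 = 1:5, f2 = 5:1)
  p <- physiochemical_profile("ACCA", factor_table = toy)
  expect_equal(p$f1, c(1, 2, 2, 1))
  expect_equal(p[1, ], p[4, ])
  # permuting the sequence permutes rows identically
  p2 <- physiochemical_profile("CACA", factor_table = toy)
  expect_equal(p2$f1, c(2, 1, 2, 1))
  expect_error(physiochemical_profile("AW", factor_table = toy), "lacks rows")
  full <- physiochemical_profile(paste(c("A", "R", "N", "D"), collapse = ""))
  expect_equal(dim(full), c(4, 5))
})

test_that("PSSM files load in PSI-BLAST layout with logistic normalisation", {
  f <- withr::local_tempfile(fileext = ".pssm")
  scores <- matrix(2L, nrow = 4, ncol = 20)
  write_pssm(scores, "ACDE", f)
  p <- load_pssm(f, "ACDE")
  expect_equal(dim(p), c(4, 20))
  expect_true(all(abs(p - 1 / (1 + exp(-2))) < 1e-12))
  expect_equal(round(p$pssm_A[1], 4), 0.8808)
  # score 0 maps to the logistic midpoint; extremes approach the bounds
  f0 <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(matrix(0L, 2, 20), "AA", f0)
  expect_true(all(load_pssm(f0) == 0.5))
  expect_error(load_pssm(f, "ACDEF"), "rows")
  expect_error(load_pssm(withr::local_tempfile(fileext = ".x")), "no such file")
})

test_that("PSSM logistic transform is bounded by (0, 1)", {
  big <- matrix(c(-20, 20), 1, 20)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(big, "A", f)
  p <- unlist(load_pssm(f))
  expect_true(all(p > 0 & p < 1))
  expect_lt(unname(p[1]), 1e-8)
  expect_gt(unname(p[2]), 1 - 1e-8)
})

test_that("monogram is the row mean of the normalised profile", {
  p <- matrix(0.5, 3, 20)
  expect_equal(monogram(p)$mg, rep(0.5, 3))
  row <- matrix(c(1, rep(0, 19)), 1, 20)
  expect_equal(monogram(row)$mg, 0.05)
  shuffled <- p[, sample(20)]
  expect_equal(monogram(shuffled)$mg, monogram(p)$mg)
})

test_that("bigram is the forward transition expectation with self-transition
           fallback at the last residue", {
  p <- matrix(0.5, 4, 20)
  bg <- bigram(p)
  expect_true(all(abs(bg - 0.25) < 1e-12))   # (1/20) * 20 * 0.5 * 0.5
  expect_equal(dim(bg), c(4, 20))
  # closed form on an interior row: mg(i) * P(i+1, k)
  withr::with_seed(3, {
    q <- matrix(runif(60), 3, 20)
  })
  bq <- bigram(q)
  expect_equal(unname(unlist(bq[1, ])), mean(q[1, ]) * q[2, ])
  expect_equal(unname(unlist(bq[3, ])), mean(q[3, ]) * q[3, ])  # fallback
  one <- bigram(q[1, , drop = FALSE])
  expect_equal(unname(unlist(one)), mean(q[1, ]) * q[1, ])
  expect_true(all(bigram(matrix(0, 2, 20)) == 0))
})

test_that("structural profile has fixed width and clips stray probabilities", {
  ss <- tibble::tibble(H = c(0.7, 0.1), C = c(0.2, 0.8), E = c(0.1, 0.1))
  out <- structural_profile(c(30, 40), ss, ss)
  expect_equal(names(out), c("asa", "ss_H", "ss_C", "ss_E",
                             "ssb_H", "ssb_C", "ssb_E"))
  expect_equal(out$ss_H, ss$H)
  bad <- tibble::tibble(H = c(-0.01, 0.5), C = c(0.5, 0.5), E = c(0.5, 0.5))
  expect_warning(clipped <- structural_profile(c(1, 2), bad, ss), "clipping")
  expect_equal(clipped$ss_H, c(0, 0.5))
  expect_error(structural_profile(1, ss, ss), "share length")
})

test_that("flexibility profile has fixed width and tolerates a missing PSEE", {
  out <- flexibility_profile(c(0.2, 0.9), c(0.1, 0.3), c(0.2, 0.4), c(-1, 2))
  expect_equal(names(out), c("disorder", "dphi_pred", "dpsi_pred", "psee"))
  missing_psee <- flexibility_profile(c(0.2, 0.9), c(0.1, 0.3), c(0.2, 0.4))
  expect_true(all(is.na(missing_psee$psee)))
  expect_warning(flexibility_profile(c(1.2, 0.5), c(0, 0), c(0, 0)), "clipping")
  expect_error(flexibility_profile(0.5, c(0, 0), c(0, 0)), "share length")
})

assemble_toy <- function(L = 6, seed = 1, drop = NULL) {
  seqn <- withr::with_seed(seed, paste(sample(c("A", "C", "D", "E"), L, TRUE),
                                       collapse = ""))
  pssm <- withr::with_seed(seed + 1,
                           matrix(runif(L * 20), L, 20,
                                  dimnames = list(NULL, paste0("pssm_", LETTERS[1:20]))))
  pssm <- tibble::as_tibble(pssm)
  ss <- tibble::tibble(H = rep(0.5, L), C = rep(0.3, L), E = rep(0.2, L))
  blocks <- list(
    residue = residue_profile(seqn),
    physiochemical = physiochemical_profile(seqn),
    pssm = pssm,
    monogram = monogram(pssm),
    bigram = bigram(pssm),
    structural = structural_profile(rep(10, L), ss, ss),
    flexibility = flexibility_profile(rep(0.5, L), rep(0.1, L), rep(0.1, L),
                                      c(NA, rep(1, L - 1))))
  blocks[setdiff(names(blocks), drop)]
}

test_that("assembly concatenates the documented layout (77 columns)", {
  ft <- assemble_features(assemble_toy(), chain_id = "c1")
  cols <- setdiff(names(ft), c("chain_id", "residue_index"))
  expect_length(cols, 77)
  expect_equal(sum(default_feature_layout()), 77L)
  groups <- feature_groups(ft)
  expect_equal(nrow(groups), 77)
  expect_equal(unname(table(groups$group)[names(default_feature_layout())]),
               unname(default_feature_layout()), ignore_attr = TRUE)
  # dropping the bigram block gives 57 columns
  ft2 <- assemble_features(assemble_toy(drop = "bigram"))
  expect_length(setdiff(names(ft2), c("chain_id", "residue_index")), 57)
})

test_that("assembly imputes NA cells with the chain column mean", {
  ft <- assemble_features(assemble_toy(), chain_id = "c1")
  expect_false(anyNA(ft))
  expect_equal(ft$psee[1], 1)  # mean of the defined entries
  expect_error(assemble_features(list(a = residue_profile("AC"),
                                      b = residue_profile("ACD"))),
               "share the same number of rows")
})

test_that("windowing pads termini and concatenates neighbour rows", {
  ft <- assemble_features(list(x = tibble::tibble(u = as.numeric(1:3),
                                                  v = as.numeric(11:13))),
                          chain_id = "c")
  w1 <- window_features(ft, 1)
  expect_equal(as.data.frame(w1)[, c("u_0", "v_0")],
               data.frame(u_0 = as.numeric(1:3), v_0 = as.numeric(11:13)))
  w3 <- window_features(ft, 3)
  cols <- setdiff(names(w3), c("chain_id", "residue_index"))
  expect_length(cols, 6)
  expect_equal(unname(unlist(w3[1, c("u_m1", "v_m1")])), c(0, 0))  # zero pad
  expect_equal(unname(unlist(w3[2, cols])), c(1, 11, 2, 12, 3, 13))
  edge <- window_features(ft, 3, pad = "edge")
  expect_equal(unname(unlist(edge[1, c("u_m1", "v_m1")])), c(1, 11))
  expect_error(window_features(ft, 2), "odd")
  prov <- feature_groups(w3)
  expect_equal(sort(unique(prov$offset)), -1:1)
  expect_equal(prov$source_column[prov$column == "u_p1"], "u")
})

test_that("windowing is chain-local: no bleed across chain boundaries", {
  as_feat <- function(tbl) {
    structure(tbl, feature_groups = tibble::tibble(column = "f", group = "g"),
              class = c("taf_features", class(tibble::tibble())))
  }
  two <- dplyr::bind_rows(
    tibble::tibble(chain_id = "a", residue_index = 0:2, f = as.numeric(1:3)),
    tibble::tibble(chain_id = "b", residue_index = 0:2, f = as.numeric(101:103)))
  ft <- window_features(as_feat(two), 3)
  first_b <- ft[ft$chain_id == "b" & ft$residue_index == 0, ]
  expect_equal(first_b$f_m1, 0)  # padded, not residue 2 of chain a
  # locality: perturbing residue j only affects rows within the half-window
  two2 <- two
  two2$f[2] <- 999
  ft2 <- window_features(as_feat(two2), 3)
  changed <- which(rowSums(as.matrix(ft[, c("f_m1", "f_0", "f_p1")]) !=
                             as.matrix(ft2[, c("f_m1", "f_0", "f_p1")])) > 0)
  expect_equal(changed, c(1, 2, 3))
})

test_that("feature TSV round trip preserves values and group metadata", {
  ft <- assemble_features(assemble_toy(), chain_id = "c1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(ft, f)
  back <- read_features_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(ft), ignore_attr = TRUE)
  expect_equal(feature_groups(back)$group, feature_groups(ft)$group)
})
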