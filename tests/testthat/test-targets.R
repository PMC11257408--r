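design2 <- study_design("siNT", c("siKD_pool", "siKD_1"), replicates = 2)

test_that("intersect_replicates keeps only sites called in every library", {
  mkcalls <- function(positions) {
    n <- length(positions)
    data.frame(ref = rep("r", n), pos = positions, refbase = rep("C", n),
               alt = rep("U", n), depth = rep(100L, n),
               alt_count = rep(10L, n), f = rep(0.1, n), p = rep(1e-4, n),
               edit = rep("C>U", n))
  }
  calls <- list(
    "siNT:1" = mkcalls(c(5, 9, 20)), "siNT:2" = mkcalls(c(5, 9)),
    "siKD_pool:1" = mkcalls(c(5, 9)), "siKD_pool:2" = mkcalls(c(5, 9, 31)),
    "siKD_1:1" = mkcalls(c(5, 9)), "siKD_1:2" = mkcalls(c(5))) # 9 in 5 of 6
  cons <- intersect_replicates(calls, design2)
  expect_equal(cons$pos, 5)
  expect_equal(ncol(cons) - 3L, 6L) # one frequency column per library
  # a two-condition minimal design intersects over 4 libraries
  d_min <- study_design("c", "k")
  cons_min <- intersect_replicates(calls[c(1, 2)] |>
    setNames(c("c:1", "c:2")) |> c(setNames(calls[c(3, 4)], c("k:1", "k:2"))),
    d_min)
  expect_equal(cons_min$pos, c(5, 9))
  # empty call sets give empty consensus, not an error
  empty <- mkcalls(integer(0))
  cons0 <- intersect_replicates(
    setNames(rep(list(empty), 6), names(calls)), design2)
  expect_equal(nrow(cons0), 0)
})

test_that("percent_difference follows the control-anchored formula", {
  expect_equal(percent_difference(0.10, 0.05), 50)
  expect_equal(percent_difference(0.10, 0.10), 0)
  expect_equal(percent_difference(0.10, 0), 100)
  expect_equal(percent_difference(0.10, 0.15), -50) # increase is negative
  expect_error(percent_difference(0, 0.05), "undefined")
})

test_that("concordance modes implement the per-replicate and per-mean rules", {
  # control reps (0.10, 0.10); KD reps pool (0.12, 0.04), kd1 (0.05, 0.06)
  fmat <- matrix(c(0.10, 0.10, 0.12, 0.04, 0.05, 0.06), nrow = 1)
  cons <- make_consensus(fmat, design2)
  strict <- classify_targets(cons, design2, "all_replicates_decrease")
  expect_equal(nrow(strict), 0) # one KD replicate increased
  relaxed <- classify_targets(cons, design2, "mean_decrease")
  expect_equal(nrow(relaxed), 1) # KD means 0.08 and 0.055 both < 0.10
  expect_equal(relaxed$f_control_mean, 0.10)
  expect_equal(relaxed$f_kd_mean, mean(c(0.08, 0.055)))
  expect_equal(relaxed$percent_difference,
               100 * (0.10 - 0.0675) / 0.10)
})

test_that("filter and percent difference match a brute-force oracle on random matrices", {
  set.seed(314)
  for (mode in c("all_replicates_decrease", "mean_decrease")) {
    fmat <- matrix(runif(100 * 6, 0.01, 0.3), ncol = 6)
    cons <- make_consensus(fmat, design2)
    got <- classify_targets(cons, design2, mode)
    want <- naive_classify(fmat, design2, mode)
    expect_equal(got$pos, which(want$keep) - 1L)
    expect_equal(got$percent_difference, want$pd)
  }
})

test_that("tiers nest with strict thresholds at 33 and 66", {
  sites <- data.frame(percent_difference = c(66, 70, 10, 33, 100, -5))
  t <- tier_sites(sites)
  expect_equal(t$tier, c("gt33", "gt66", "all", "all", "gt66", "all"))
  expect_true(all(which(t$gt66) %in% which(t$gt33)))
  expect_true(sum(t$gt66) <= sum(t$gt33))
})

test_that("context annotation flags UC motifs and pads window ends", {
  ref <- reference_sequence("r", "AUCACCA")
  s <- annotate_context(data.frame(pos = c(2L, 5L, 0L)), ref, flank = 2)
  expect_equal(s$uc_motif, c(TRUE, FALSE, FALSE))
  expect_equal(s$context[1], "AUCAC")
  expect_equal(s$context[3], "--AUC") # upstream padded at sequence start
  expect_equal(nchar(s$context), rep(5L, 3))
})

test_that("region annotation applies the fixed precedence and finds the gene", {
  feats <- data.frame(
    gene = c("g1", "g1", "g1", "g1", "g1", "g2"),
    type = c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR", "exon"),
    start = c(0, 10, 20, 30, 40, 60),
    end = c(10, 20, 30, 40, 50, 80),
    strand = "+", coding = c(rep(TRUE, 5), FALSE))
  s <- annotate_region(data.frame(pos = c(45L, 25L, 15L, 55L, 70L, 5L)), feats)
  expect_equal(s$region, c("3'UTR", "intron", "coding exon", "intergenic",
                           "non-coding exon", "5'UTR"))
  expect_equal(s$gene, c("g1", "g1", "g1", NA, "g2", "g1"))
  # every site gets exactly one label; counts over labels sum to site count
  expect_equal(sum(table(s$region)), nrow(s))
})

test_that("planted depletion-sensitive sites are recovered end to end", {
  ref <- generate_reference(3000, seed = 7)
  planted <- plant_edit_sites(ref, 20, f_control_range = c(0.10, 0.10),
                              kd_reduction = c(siKD_pool = 0.5, siKD_1 = 0.5),
                              seed = 7)
  pileups <- simulate_pileups(ref, planted, design2, depth = 1000, seed = 7)
  calls <- lapply(pileups, call_c_to_u)
  sites <- find_candidate_targets(calls, design2, ref, mode = "mean_decrease")
  # no site invented: output within consensus within the union of calls
  union_pos <- sort(unique(unlist(lapply(calls, `[[`, "pos"))))
  expect_true(all(sites$pos %in% union_pos))
  sens <- mean(planted$position %in% sites$pos)
  expect_gte(sens, 0.9)
  n_c <- sum(ref_bases(ref) == "C") - nrow(planted)
  fp <- sum(!(sites$pos %in% planted$position)) / n_c
  expect_lte(fp, 0.05)
  # uc_motif column agrees with the reference sequence
  prev <- ifelse(sites$pos >= 1,
                 substring(ref$sequence, sites$pos, sites$pos), "")
  expect_equal(sites$uc_motif, prev == "U")
})
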