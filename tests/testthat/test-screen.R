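test_that("one_nucleolus_fraction is the fraction of single-nucleolus cells", {
  expect_equal(one_nucleolus_fraction(c(1, 1, 2, 3)), 0.5)
  expect_equal(one_nucleolus_fraction(c(2, 2, 2)), 0)
  expect_error(one_nucleolus_fraction(integer(0)), "no cells")
})

test_that("percent effect anchors the controls at 0 and 100 exactly", {
  expect_equal(percent_effect(0.192, 0.192, 0.292), 0)
  expect_equal(percent_effect(0.292, 0.192, 0.292), 100)
  expect_equal(percent_effect(0.242, 0.192, 0.292), 50)
  expect_gt(percent_effect(0.463, 0.192, 0.292), 100) # stronger than positive
  expect_error(percent_effect(0.2, 0.1, 0.1), "degenerate")
})

test_that("hit calling uses the inclusive 3-SD negative-control cutoff", {
  neg <- list(c(-2, 0, 2), c(-1, 0, 1)) # SDs 2 and 1 -> cutoffs 6 and 3
  eff <- rbind(at_cutoff = c(6, 3),     # mean 4.5 == mean cutoff 4.5 -> hit (>=)
               below = c(5, 2),
               above = c(10, 8))
  res <- call_hits(eff, neg)
  expect_equal(res$hit, c(TRUE, FALSE, TRUE))
  expect_equal(res$cutoff, rep(4.5, 3))
  rep_hits <- attr(res, "replicate_hits")
  expect_true(all(rep_hits["at_cutoff", ]))
  expect_false(any(rep_hits["below", ]))
  # degenerate SD = 0 plate: any non-negative effect is a hit
  res0 <- call_hits(rbind(t1 = c(0.5, 0.5)), list(c(0, 0), c(0, 0)))
  expect_true(res0$hit)
  expect_error(call_hits(eff, list(c(0), c(0, 1))), ">= 2")
})

test_that("percent inhibition classifies transcription vs processing defects", {
  # I computed from 5-EU medians: neg = 100, pos = 20
  r <- percent_inhibition(c(100, 20, 59.36, 30, 90), 100, 20)
  expect_equal(r$percent_inhibition[1:2], c(0, 100))
  expect_equal(r$class[2], "transcription")        # I = 100 > 80
  expect_equal(r$percent_inhibition[3], 50.8)
  expect_equal(r$class[3], "processing/maturation") # the 50-80% band
  expect_equal(r$class[4], "transcription")         # I = 87.5
  expect_equal(r$class[5], "not required")          # I = 12.5 < 50
  # boundary: exactly 80 and exactly 50 are processing/maturation (inclusive)
  rb <- percent_inhibition(c(100 - 0.8 * 80, 100 - 0.8 * 50), 100, 20)
  expect_equal(rb$class, rep("processing/maturation", 2))
  expect_error(percent_inhibition(50, 100, 100), "degenerate")
})

test_that("DNA normalization maps control G1/G2 peaks to 1 and 2", {
  set.seed(1)
  ctrl <- c(2^rnorm(4000, 10, 0.04), 2^rnorm(2000, 11, 0.04))
  norm <- normalize_dna_intensity(ctrl, ctrl)
  expect_lt(abs(attr(norm, "g1_peak") - 10), 0.05)
  expect_lt(abs(attr(norm, "g2_peak") - 11), 0.05)
  # a test-well value sitting at the control G1 peak lands at 1.0
  probe <- normalize_dna_intensity(2^attr(norm, "g1_peak"), ctrl)
  expect_equal(as.numeric(probe), 1.0, tolerance = 1e-9)
  # unimodal control cannot be normalized
  expect_error(normalize_dna_intensity(2^rnorm(2000, 10, 0.04)), "modes")
  expect_error(normalize_dna_intensity(c(-1, 2)), "positive")
})

test_that("cell-cycle binning uses the fixed half-open boundaries", {
  prof <- bin_cell_cycle(c(0.5, 1.0, 1.5, 2.0, 3.0))
  expect_equal(prof$counts, rep(1L, 5)) # one cell per phase
  expect_equal(sum(prof$fractions), 1)
  expect_equal(prof$n, 5)
  # boundary values: left-closed bins
  f <- phase_fractions(bin_cell_cycle(c(0.75, 1.25, 1.75, 2.5, 2.500001)))
  expect_equal(unname(f["G1"]), 0.2)   # 0.75 -> G1
  expect_equal(unname(f["S"]), 0.2)    # 1.25 -> S
  expect_equal(unname(f["G2/M"]), 0.4) # 1.75 and 2.5 -> G2/M
  expect_equal(unname(f[">4n"]), 0.2)  # just above 2.5
  expect_error(bin_cell_cycle(c(1, NA)), "finite")
})

test_that("phase fractions survive a generate-normalize-bin round trip", {
  truth <- c(0.05, 0.5, 0.2, 0.2, 0.05)
  cells <- simulate_dna_intensities(truth, 10000, cv = 0.05, seed = 17)
  norm <- normalize_dna_intensity(cells$intensity)
  got <- phase_fractions(bin_cell_cycle(norm))
  expect_true(all(abs(got - truth) <= 0.03))
  expect_equal(bin_cell_cycle(norm)$n, 10000) # every cell binned exactly once
})

test_that("RAMP log2 fold changes follow the ratio-of-ratios formula", {
  pw <- ramp_pathway(c("47S", "45S", "32S", "12S"))
  x <- c(`47S` = 3, `45S` = 2, `32S` = 1.5, `12S` = 0.8)
  # identity: test == control gives all zeros
  expect_equal(ramp_log2fc(x, x, pw)$log2fc, rep(0, 3))
  # 32S doubled: +1 on the edge into 32S, -1 on the edge out of it
  y <- x; y["32S"] <- 2 * x["32S"]
  lfc <- ramp_log2fc(y, x, pw)
  expect_equal(lfc$log2fc, c(0, 1, -1))
  # random intensities match direct formula evaluation, and antisymmetry holds
  set.seed(23)
  for (i in 1:20) {
    a <- setNames(runif(4, 0.1, 10), names(x))
    b <- setNames(runif(4, 0.1, 10), names(x))
    got <- ramp_log2fc(a, b, pw)$log2fc
    want <- log2((a[pw$downstream] / a[pw$upstream]) /
                 (b[pw$downstream] / b[pw$upstream]))
    expect_equal(got, unname(want))
    expect_equal(got, -ramp_log2fc(b, a, pw)$log2fc)
  }
  expect_error(ramp_log2fc(x[-1], x, pw), "missing species")
  z <- x; z["12S"] <- 0
  expect_error(ramp_log2fc(z, x, pw), "non-positive")
  expect_error(ramp_pathway("one"), ">= 2")
})

test_that("a simulated plate recovers well summaries and strong hits", {
  plate <- simulate_screen_wells(
    treatments = c(strong = 0.392, none = 0.192),
    n_neg = 16, n_pos = 16, cells_per_well = 1000, seed = 31)
  ws <- well_percent_effects(summarize_wells(plate))
  # control anchors: mean negative effect 0, mean positive effect 100
  expect_equal(mean(ws$percent_effect[ws$role == "negative"]), 0)
  expect_equal(mean(ws$percent_effect[ws$role == "positive"]), 100)
  # a treatment at twice the control separation is called a hit
  neg_eff <- list(ws$percent_effect[ws$role == "negative"])
  eff <- rbind(strong = ws$percent_effect[ws$treatment == "strong"],
               none = ws$percent_effect[ws$treatment == "none"])
  res <- call_hits(eff, neg_eff)
  expect_true(res[res$treatment == "strong", "hit"])
  expect_false(res[res$treatment == "none", "hit"])
})
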