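rep_cells <- function(cell, n) cell[rep(1, n), ]

test_that("single cells classify by the disomy/nullisomy/diploidy rules", {
  panel <- karyo_params()$probe_panel
  cases <- list(
    list(make_cell(), "euploid", character()),
    list(make_cell(`21` = 2), "aneuploid", "21:disomy"),
    list(make_cell(`13` = 0), "aneuploid", "13:nullisomy"),
    list(make_cell(`13` = 2, `18` = 0), "aneuploid",
         c("13:disomy", "18:nullisomy")),
    # diploid: every autosome 2, two sex signals in any pattern
    list(make_cell(`13` = 2, `15` = 2, `16` = 2, `17` = 2, `18` = 2,
                   `21` = 2, `22` = 2, X = 1, Y = 1), "diploid", character()),
    list(make_cell(`13` = 2, `15` = 2, `16` = 2, `17` = 2, `18` = 2,
                   `21` = 2, `22` = 2, X = 2, Y = 0), "diploid", character()),
    # sex-probe patterns
    list(make_cell(X = 0, Y = 1), "euploid", character()),
    list(make_cell(X = 1, Y = 1), "aneuploid", "XY:disomy"),
    list(make_cell(X = 2, Y = 0), "aneuploid", "XY:disomy"),
    list(make_cell(X = 0, Y = 0), "aneuploid", "XY:nullisomy"),
    # three signals anywhere, or three sex signals in total, is unscorable
    list(make_cell(`16` = 3), "unscorable", character()),
    list(make_cell(X = 2, Y = 1), "unscorable", character())
  )
  cells <- make_cells(purrr::map(cases, 1))
  cls <- classify_fish_cells(cells)
  expect_equal(cls$class, purrr::map_chr(cases, 2))
  expect_equal(cls$events, purrr::map(cases, 3))
})

test_that("specimen scoring matches a hand count and flags thresholds", {
  dis <- make_cell(`21` = 2)
  nul <- make_cell(`15` = 0)
  dip <- make_cell(`13` = 2, `15` = 2, `16` = 2, `17` = 2, `18` = 2,
                   `21` = 2, `22` = 2, X = 1, Y = 1)
  cells <- make_cells(
    rep_cells(make_cell(), 980),
    rep_cells(dis, 12),
    rep_cells(nul, 5),
    rep_cells(dip, 3)
  )
  rep <- score_fish(cells)
  expect_equal(rep$n_scorable, 1000)
  expect_equal(rep$total_aneuploidy_pct, 2.00)
  expect_equal(rep$diploidy_pct, 0.30)
  expect_true(rep$abnormal)
  per <- rep$per_chromosome
  expect_equal(per$disomy_pct[per$chrom == "21"], 1.2)
  expect_equal(per$nullisomy_pct[per$chrom == "15"], 0.5)

  # all-euploid specimen
  clean <- score_fish(make_cells(rep_cells(make_cell(), 1000)))
  expect_equal(clean$total_aneuploidy_pct, 0)
  expect_false(clean$abnormal)

  # under-powered specimen still reports, with warning and flag
  expect_warning(small <- score_fish(make_cells(rep_cells(make_cell(), 500))),
                 "underpowered")
  expect_false(small$sufficient_cells)

  # unscorable cells leave numerator and denominator
  with_bad <- make_cells(rep_cells(make_cell(), 998),
                         rep_cells(make_cell(`16` = 4), 2))
  expect_warning(rep2 <- score_fish(with_bad), "underpowered")
  expect_equal(rep2$n_scorable, 998)
  expect_equal(rep2$n_unscorable, 2)
  expect_error(score_fish(make_cells(rep_cells(make_cell(`16` = 3), 5))),
               "no scorable cells")
})

test_that("classification partitions scorable cells and obeys the union bound", {
  cells <- simulate_fish_cells(
    4000, disomy_rate = 0.01, nullisomy_rate = 0.01, diploidy_rate = 0.01,
    seed = 12)
  cls <- classify_fish_cells(cells)
  expect_equal(nrow(cls), 4000)
  expect_setequal(unique(cls$class),
                  c("euploid", "aneuploid", "diploid"))
  rep <- suppressWarnings(score_fish(cells))
  counts <- table(cls$class)
  expect_equal(rep$aneuploid_cells,
               sum(counts[c("aneuploid", "diploid")]))
  # union bound: total <= sum of per-chromosome event rates + diploidy
  expect_lte(rep$total_aneuploidy_pct,
             sum(rep$per_chromosome$disomy_pct,
                 rep$per_chromosome$nullisomy_pct) + rep$diploidy_pct + 1e-9)
})

test_that("known per-chromosome rates are recovered within 3 binomial SE", {
  n <- 10000
  cells <- simulate_fish_cells(
    n, disomy_rate = c("21" = 0.02, "18" = 0.005),
    nullisomy_rate = c("13" = 0.01), diploidy_rate = 0.004, seed = 99)
  rep <- score_fish(cells)
  per <- rep$per_chromosome
  # denominators shrink slightly because diploid cells preempt events
  expect_lt(abs(per$disomy_pct[per$chrom == "21"] - 2),
            3 * binom_se_pct(0.02, n) + 0.4 * 2 / 100)
  expect_lt(abs(per$nullisomy_pct[per$chrom == "13"] - 1),
            3 * binom_se_pct(0.01, n) + 0.4 * 1 / 100)
  expect_lt(abs(rep$diploidy_pct - 0.4), 3 * binom_se_pct(0.004, n))
})

test_that("raising the abnormality threshold never flags more specimens", {
  cells <- simulate_fish_cells(2000, disomy_rate = 0.008, seed = 5)
  for (thr in c(0.5, 1.0, 1.6, 2.5, 5)) {
    lo <- score_fish(cells, karyo_params(fish_abnormal_threshold_pct = thr))
    hi <- score_fish(cells,
                     karyo_params(fish_abnormal_threshold_pct = thr + 1))
    expect_true(lo$abnormal >= hi$abnormal)
  }
})

test_that("replicate reconciliation pools counts and flags discordance", {
  slide <- function(n_ab, n = 1000) {
    make_cells(rep_cells(make_cell(), n - n_ab),
               rep_cells(make_cell(`21` = 2), n_ab))
  }
  r1 <- score_fish(slide(20))  # 2.0%
  r2 <- score_fish(slide(24))  # 2.4%
  pooled <- reconcile_fish_replicates(r1, r2)
  expect_true(pooled$concordant)
  expect_equal(pooled$n_scorable, 2000)
  expect_equal(pooled$total_aneuploidy_pct, 100 * 44 / 2000)
  per <- pooled$per_chromosome
  expect_equal(per$disomy_n[per$chrom == "21"], 44L)

  r3 <- score_fish(slide(10))  # 1.0%
  r4 <- score_fish(slide(60))  # 6.0%
  expect_warning(disc <- reconcile_fish_replicates(r3, r4), "discordant")
  expect_false(disc$concordant)

  # identical replicates: pooled total equals each replicate's total
  same <- reconcile_fish_replicates(r1, score_fish(slide(20)))
  expect_equal(same$total_aneuploidy_pct, r1$total_aneuploidy_pct)

  # panel mismatch is an error
  small_panel <- c("X", "Y", "21")
  other <- suppressWarnings(score_fish(
    simulate_fish_cells(100, panel = small_panel, seed = 1),
    karyo_params(probe_panel = small_panel)))
  expect_error(reconcile_fish_replicates(r1, other), "panel")
})
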