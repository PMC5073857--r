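test_that("midranks handle ties by averaging and sum to N(N+1)/2", {
  expect_equal(rankValues(c(3, 1, 1, 2)), c(4, 1.5, 1.5, 3))
  expect_equal(rankValues(5), 1)
  expect_equal(rankValues(c(2, 2, 2)), c(2, 2, 2))
  expect_equal(rankValues(c(3, 1, 1, 2), "descending"), c(1, 3.5, 3.5, 2))
  set.seed(11)
  for (i in 1:20) {
    x <- sample(1:6, sample(1:30, 1), replace = TRUE)
    n <- length(x)
    expect_equal(sum(rankValues(x)), n * (n + 1) / 2)
    expect_equal(sum(rankValues(x, "descending")), n * (n + 1) / 2)
  }
  expect_error(rankValues(numeric(0)), "empty")
  expect_error(rankValues(c(1, Inf)), "finite")
})

test_that("the E-rank score is (P/MAF)/(Kr*Kt) exactly", {
  expect_equal(eScore(0.05, 0.5, 1, 1), 0.1, tolerance = 1e-12)
  expect_equal(eScore(1e-6, 0.1, 10, 5), 2e-7, tolerance = 1e-12)
  expect_warning(s <- eScore(0.01, 0, 1, 1), "unrankable")
  expect_true(is.na(s))
  expect_warning(s0 <- eScore(0, 0.2, 1, 1), "clamped")
  expect_gt(s0, 0)
  expect_error(eScore(1.5, 0.2, 1, 1), "0, 1")
  expect_error(eScore(0.05, 0.2, 0.5, 1), ">= 1")
})

test_that("the score is monotone in each argument separately", {
  grid <- seq(0.1, 1, length.out = 10)
  base <- eScore(0.01, 0.25, 5, 5)
  expect_true(all(diff(vapply(grid * 0.05, eScore, numeric(1),
                              maf = 0.25, kR = 5, kT = 5)) > 0))
  expect_true(all(diff(vapply(grid * 0.5, function(m)
    eScore(0.01, m, 5, 5), numeric(1))) < 0))
  expect_true(all(diff(vapply(1:10, function(k)
    eScore(0.01, 0.25, k, 5), numeric(1))) < 0))
  expect_true(all(diff(vapply(1:10, function(k)
    eScore(0.01, 0.25, 5, k), numeric(1))) < 0))
  expect_gt(base, 0)
})

test_that("rank directions promote conserved sites", {
  # identical P and MAF; X conserved (rate 0, span 1), Y not
  recs <- data.frame(rsid = c("rsX", "rsY"),
                     p_value = c(1e-6, 1e-6), maf = c(0.2, 0.2),
                     evol_rate = c(0, 3), evol_span = c(1, 0.2))
  rk <- rankedTable(computeRankings(recs))
  x <- rk[rk$rsid == "rsX", ]; y <- rk[rk$rsid == "rsY", ]
  expect_gt(x$k_r * x$k_t, y$k_r * y$k_t)
  expect_lt(x$e_score, y$e_score)
  expect_equal(x$e_rank_ordinal, 1L)
  expect_equal(y$e_rank_ordinal, 2L)
})

test_that("three-record hand oracle orders records as expected", {
  recs <- data.frame(
    rsid = c("rsA", "rsB", "rsC"),
    p_value = c(1e-8, 1e-8, 1e-3), maf = rep(0.3, 3),
    evol_rate = c(0.0, 2.0, 0.0), evol_span = c(1.0, 0.2, 1.0))
  # hand evaluation: Kr desc over (0,2,0) -> (2.5, 1, 2.5);
  # Kt asc over (1, .2, 1) -> (2.5, 1, 2.5)
  rk <- rankedTable(computeRankings(recs))
  rk <- rk[match(c("rsA", "rsB", "rsC"), rk$rsid), ]
  expect_equal(rk$k_r, c(2.5, 1, 2.5))
  expect_equal(rk$k_t, c(2.5, 1, 2.5))
  expect_equal(rk$e_score,
               c(1e-8 / 0.3 / 6.25, 1e-8 / 0.3, 1e-3 / 0.3 / 6.25))
  expect_equal(rk$e_rank_ordinal, c(1L, 2L, 3L))
})

test_that("a singleton record gets all ranks equal to 1", {
  rk <- rankedTable(computeRankings(data.frame(
    rsid = "rs1", p_value = 0.01, maf = 0.2,
    evol_rate = 0.5, evol_span = 0.7)))
  expect_equal(rk$k_r, 1)
  expect_equal(rk$k_t, 1)
  expect_equal(rk$p_rank, 1L)
  expect_equal(rk$e_rank_ordinal, 1L)
  expect_equal(rk$rank_diff, 0L)
})

test_that("unrankable records are excluded with reasons, not guessed", {
  recs <- toyRankable()
  recs$maf[2] <- 0
  recs$evol_rate[4] <- NA
  rs <- computeRankings(recs)
  expect_equal(nrow(rankedTable(rs)), 3L)
  ex <- excludedTable(rs)
  expect_setequal(ex$rsid, c("rs1002", "rs1004"))
  expect_setequal(ex$reason,
                  c("MAF missing or zero", "undefined evolutionary rate"))
  allbad <- recs[c(2, 4), ]
  expect_error(computeRankings(allbad), "no rankable")
})

test_that("ordinal ranks are permutations and scale-invariant in P", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    recs <- data.frame(rsid = sprintf("rs%03d", sample.int(999, n)),
                       p_value = stats::runif(n, 1e-9, 0.05),
                       maf = stats::runif(n, 0.05, 0.5),
                       evol_rate = stats::rexp(n),
                       evol_span = stats::runif(n))
    rk <- rankedTable(computeRankings(recs))
    expect_setequal(rk$p_rank, seq_len(n))
    expect_setequal(rk$e_rank_ordinal, seq_len(n))
    expect_equal(sum(rk$rank_diff), 0)
    # multiplying every P by a common constant preserves the E ordering
    recs2 <- recs
    recs2$p_value <- recs2$p_value * 0.01
    rk2 <- rankedTable(computeRankings(recs2))
    expect_equal(rk2$e_rank_ordinal[match(rk$rsid, rk2$rsid)],
                 rk$e_rank_ordinal)
  }
})

test_that("identical evolutionary context collapses E-rank onto P-rank", {
  set.seed(33)
  n <- 40
  recs <- data.frame(rsid = sprintf("rs%04d", sample.int(9999, n)),
                     p_value = stats::runif(n, 1e-8, 0.05),
                     maf = 0.25, evol_rate = 0.5, evol_span = 0.8)
  rk <- rankedTable(computeRankings(recs))
  expect_equal(rk$e_rank_ordinal, rk$p_rank)
  expect_true(all(rk$rank_diff == 0L))
})

test_that("with P and MAF fixed the E order follows decreasing Kr*Kt", {
  set.seed(44)
  n <- 15
  recs <- data.frame(rsid = sprintf("rs%02d", 1:n),
                     p_value = 1e-4, maf = 0.3,
                     evol_rate = stats::rexp(n),
                     evol_span = stats::runif(n))
  rk <- rankedTable(computeRankings(recs))
  o <- order(rk$e_rank_ordinal)
  kk <- (rk$k_r * rk$k_t)[o]
  expect_true(all(diff(kk) <= 0))
})
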