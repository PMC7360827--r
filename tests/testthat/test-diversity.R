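test_that("frequency_table returns observed-level proportions", {
  ft <- frequency_table(c(rep(1L, 75), rep(2L, 40)))
  expect_equal(ft$level, c(1L, 2L))
  expect_equal(round_half_up(ft$p, 3), c(0.652, 0.348))
  expect_equal(sum(ft$p), 1)

  expect_equal(frequency_table(7L)$p, 1)
  expect_equal(frequency_table(rep(1:4, each = 10))$p, rep(0.25, 4))
  expect_error(frequency_table(NA_integer_), "non-missing")
})

test_that("shannon_index reproduces hand-checked two-level indices", {
  expect_equal(round_half_up(shannon_index(c(green = 75, purple = 40)), 3),
               0.646)
  expect_equal(round_half_up(shannon_index(c(acute = 96, obtuse = 19)), 3),
               0.448)
  expect_equal(shannon_index(c(10, 0, 0)), 0)
  expect_equal(shannon_index(c(5, 5)), log(2))
  expect_equal(shannon_index(rep(3, 7)), log(7))
  expect_error(shannon_index(c(0, 0)), "positive")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
})

test_that("H' is bounded by ln(non-empty classes), equality at uniform", {
  set.seed(11)
  for (i in 1:50) {
    counts <- rpois(sample(2:10, 1), lambda = 5)
    if (sum(counts) == 0) next
    h <- shannon_index(counts)
    k <- sum(counts > 0)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
    if (k == 1) expect_equal(h, 0)
  }
})

test_that("merging two classes never increases H'", {
  set.seed(12)
  for (i in 1:50) {
    counts <- rpois(sample(3:10, 1), lambda = 4) + 1
    pick <- sample(length(counts), 2)
    merged <- c(counts[-pick], sum(counts[pick]))
    expect_lte(shannon_index(merged), shannon_index(counts) + 1e-12)
  }
})

test_that("coefficient_of_variation is sample sd over mean", {
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  set.seed(13)
  x <- rlnorm(20)
  expect_equal(coefficient_of_variation(3.7 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(5), ">= 2")
})

test_that("class binning follows the half-s.d. boundary rules", {
  b <- assign_classes(rep(4.2, 5))
  expect_equal(b$assignments, rep(6L, 5))
  expect_equal(shannon_index(b$counts), 0)

  set.seed(14)
  x <- c(rnorm(30, 10, 2), -1000, 1000)
  bb <- assign_classes(x)
  expect_true(all(bb$assignments %in% 1:10))
  expect_equal(length(bb$boundaries), 9)
  expect_true(all(diff(bb$boundaries) > 0))
  expect_equal(bb$boundaries[5], bb$mean)
  # the appended points lie far beyond the realized X -/+ 2s tails
  expect_lt(-1000, bb$mean - 2 * bb$sd)
  expect_gt(1000, bb$mean + 2 * bb$sd)
  expect_equal(unname(bb$assignments[31]), 1L)
  expect_equal(unname(bb$assignments[32]), 10L)

  expect_error(assign_classes(1), ">= 2")
})

test_that("a fixed 12-value vector reproduces the frozen oracle labels", {
  vals <- c(4.1, 5.0, 5.2, 5.9, 6.3, 6.6, 7.0, 7.4, 8.1, 8.8, 9.9, 12.0)
  frozen <- c(3L, 4L, 4L, 4L, 5L, 5L, 5L, 6L, 6L, 7L, 8L, 10L)
  expect_equal(oracle_bin(vals), frozen)  # oracle agrees with its freeze
  expect_equal(assign_classes(vals)$assignments, frozen)
})

test_that("binning matches the boundary-enumeration oracle on 200 random vectors", {
  set.seed(15)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    x <- switch(sample(3, 1),
                rnorm(n, runif(1, -5, 5), runif(1, 0.1, 10)),
                rlnorm(n, 1, 0.6),
                runif(n, 0, 100))
    expect_identical(assign_classes(x)$assignments, oracle_bin(x))
  }
})

test_that("values exactly on the +/-2s boundaries use the strict tail rule", {
  # {-2, 0 x7, 2} has mean 0 and sample sd exactly 1 in floating point,
  # so its extremes sit exactly on X - 2s and X + 2s
  v <- c(-2, rep(0, 7), 2)
  b <- assign_classes(v)
  expect_equal(b$mean, 0)
  expect_equal(b$sd, 1)
  expect_equal(b$boundaries[1], -2)
  expect_equal(b$boundaries[9], 2)
  expect_equal(unname(b$assignments[1]), 2L)  # x = X - 2s: not class 1
  expect_equal(unname(b$assignments[9]), 9L)  # x = X + 2s: class 9
  expect_equal(oracle_bin(v), b$assignments)
})

test_that("quantitative class occupancy tracks normal tail masses", {
  set.seed(16)
  counts1 <- replicate(50, {
    b <- assign_classes(rnorm(115))
    unname(b$counts["1"])
  })
  p_hat <- sum(counts1) / (50 * 115)
  p_true <- pnorm(-2)
  se <- sqrt(p_true * (1 - p_true) / (50 * 115))
  expect_lt(abs(p_hat - p_true), 4 * se + 0.005)
})

test_that("symmetric samples give symmetric class counts", {
  set.seed(17)
  z <- rnorm(57)
  b <- assign_classes(c(z, -z))
  counts <- b$counts
  for (j in 1:5) {
    expect_lte(abs(counts[[j]] - counts[[11 - j]]), 1)
  }
})

test_that("quantitative trait diversity composes binning, H' and CV", {
  q <- quantitative_trait_diversity(rep(7, 10))
  expect_equal(q$h, 0)
  expect_equal(q$cv, 0)

  set.seed(18)
  x <- rnorm(115, 50, 8)
  q2 <- quantitative_trait_diversity(x)
  expect_equal(q2$h, shannon_index(assign_classes(x)$counts))
  expect_equal(q2$cv, sd(x) / mean(x))
  expect_lte(q2$h, log(10))
})

test_that("organ aggregation is the arithmetic mean of member traits", {
  expect_equal(round_half_up(
    organ_diversity(c(1.836, 1.814, 1.283, 1.055, 1.012)), 3), 1.400)
  expect_equal(round_half_up(organ_diversity(c(2.023, 1.858)), 3), 1.941)
  expect_equal(organ_diversity(1.206), 1.206)
  expect_error(organ_diversity(numeric()), "at least one")
})

test_that("diversity_report aggregates per trait, organ, and region", {
  lab <- simulate_collection(simulation_config(seed = 19))
  rep <- diversity_report(lab$collection)
  expect_equal(nrow(rep$per_trait), 29)
  expect_equal(rep$overall_mean, mean(rep$per_trait$h))
  # organ means recompute from the per-trait table
  for (i in seq_len(nrow(rep$per_organ))) {
    sub <- rep$per_trait[rep$per_trait$organ == rep$per_organ$organ[i] &
                         rep$per_trait$kind == rep$per_organ$kind[i], ]
    expect_equal(rep$per_organ$h[i], mean(sub$h))
  }
  expect_true(all(is.na(rep$per_trait$cv[rep$per_trait$kind ==
                                           "qualitative"])))
  expect_true(all(rep$per_trait$cv[rep$per_trait$kind == "quantitative"]
                  >= 0))
  expect_setequal(rep$per_region$region,
                  unique(lab$collection$region[!is.na(lab$collection$region)]))

  td <- tidy(rep)
  expect_equal(nrow(td), 29)
  g <- glance(rep)
  expect_equal(g$n_qualitative, 16)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("degenerate collections give zero diversity everywhere", {
  col <- as_collection(tibble::tibble(
    id = paste0("a", 1:6), region = rep(c("I", "II"), each = 3),
    HSW = rep(30, 6), GH = rep(1L, 6), SSC = rep(2L, 6)))
  rep <- diversity_report(col)
  expect_true(all(rep$per_trait$h == 0))
  expect_equal(rep$overall_mean, 0)
})

test_that("two identical regions get identical per-region means", {
  base <- tibble::tibble(HSW = c(20, 30, 40, 25), GH = c(1L, 2L, 1L, 2L),
                         SL = c(1, 1.2, 1.4, 1.1))
  col <- as_collection(dplyr::bind_cols(
    tibble::tibble(id = paste0("a", 1:8),
                   region = rep(c("I", "III"), each = 4)),
    dplyr::bind_rows(base, base)))
  rep <- diversity_report(col)
  expect_equal(rep$per_region$h[1], rep$per_region$h[2])
})

test_that("a trait with fewer than two observations is a named error", {
  col <- as_collection(tibble::tibble(
    id = c("a1", "a2"), HSW = c(30, 31), GH = c(1L, NA)))
  expect_error(diversity_report(col), "GH")
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(1.9405, 3), 1.941)
  expect_equal(round_half_up(1.0615, 3), 1.062)
  expect_equal(round_half_up(-1.0615, 3), -1.062)
  expect_equal(round_half_up(45.217, 1), 45.2)
})
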