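test_that("standardize z-scores every included trait column", {
  lab <- simulate_collection(simulation_config(n_andean = 15,
                                               n_mesoamerican = 15,
                                               introgression_fraction = 0,
                                               seed = 21))
  z <- standardize(lab$collection)
  m <- beandiv:::st_matrix(z)
  expect_equal(unname(colMeans(m)), rep(0, ncol(m)), tolerance = 1e-9)
  expect_equal(unname(apply(m, 2, sd)), rep(1, ncol(m)), tolerance = 1e-9)

  # idempotent: standardizing the z-scores changes nothing
  z2 <- scale(m)
  expect_equal(unname(z2[, ]), unname(m), tolerance = 1e-9)
})

test_that("constant trait columns become zeros with a warning", {
  col <- as_collection(tibble::tibble(
    id = paste0("a", 1:4), HSW = c(20, 30, 40, 50), GH = rep(1L, 4)))
  expect_warning(z <- standardize(col), "GH")
  expect_equal(unname(beandiv:::st_matrix(z)[, "GH"]), rep(0, 4))
})

test_that("rows with missing included-trait values are dropped with a message", {
  col <- as_collection(tibble::tibble(
    id = paste0("a", 1:4), HSW = c(20, NA, 40, 50), SL = c(1, 1.2, 1.4, 2)))
  expect_message(z <- standardize(col), "1 accession")
  expect_equal(nrow(z), 3)
  expect_equal(attr(z, "dropped_ids"), "a2")
})

test_that("euclidean distances match hand values and a brute-force oracle", {
  m <- matrix(c(0, 0, 3, 4, 0, 0), ncol = 2, byrow = TRUE)
  d <- as.matrix(euclidean_distances(m))
  expect_equal(d[1, 2], 5)       # 3-4-5 triangle
  expect_equal(d[1, 3], 0)       # identical rows
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)

  set.seed(22)
  x <- matrix(rnorm(15), nrow = 5)
  dd <- as.matrix(euclidean_distances(x))
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(dd[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
    }
  }
  expect_equal(dd, t(dd))
})

test_that("upgma reproduces forced merge orders on block matrices", {
  # two leaves at distance 4
  two <- matrix(c(0, 4, 4, 0), 2)
  hc <- upgma(two)
  expect_equal(hc$height, 4)

  # blocks (A,B)@2, (C,D)@3, cross distances all 10
  m <- matrix(10, 4, 4)
  diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 2
  m[3, 4] <- m[4, 3] <- 3
  hc4 <- upgma(m)
  expect_equal(sort(hc4$height), c(2, 3, 10))

  expect_error(upgma(matrix(1, 2, 3)), "square")
  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(upgma(asym), "symmetric")
})

test_that("upgma matches the naive cubic oracle on random instances up to 12 leaves", {
  set.seed(23)
  for (n in 3:12) {
    for (rep in 1:3) {
      x <- matrix(rnorm(n * 4), nrow = n)
      dmat <- as.matrix(dist(x))
      hc <- upgma(dmat)
      expect_equal(hc$height, oracle_upgma_heights(dmat),
                   tolerance = 1e-10)
      # monotone heights: no inversions
      expect_true(all(diff(hc$height) >= -1e-12))
    }
  }
})

test_that("cophenetic distances are ultrametric and attain merge heights", {
  set.seed(24)
  x <- matrix(rnorm(10 * 3), nrow = 10)
  hc <- upgma(dist(x))
  cp <- as.matrix(stats::cophenetic(hc))
  expect_setequal(round(unique(cp[upper.tri(cp)]), 10),
                  round(hc$height, 10))
  for (t in 1:50) {
    ijk <- sample(10, 3)
    d3 <- sort(c(cp[ijk[1], ijk[2]], cp[ijk[1], ijk[3]],
                 cp[ijk[2], ijk[3]]))
    expect_equal(d3[2], d3[3], tolerance = 1e-10)
  }
})

test_that("permuting accession order changes no merge height or partition", {
  set.seed(25)
  x <- matrix(rnorm(9 * 4), nrow = 9)
  rownames(x) <- paste0("a", 1:9)
  hc <- upgma(dist(x))
  perm <- sample(9)
  hcp <- upgma(dist(x[perm, ]))
  expect_equal(sort(hc$height), sort(hcp$height), tolerance = 1e-12)

  g <- cut_dendrogram(hc, 3)
  gp <- cut_dendrogram(hcp, 3)
  joined <- dplyr::inner_join(g, gp, by = "id")
  expect_equal(ari(joined$group.x, joined$group.y), 1)
})

test_that("cut_dendrogram handles boundary k and orders labels by size", {
  set.seed(26)
  x <- matrix(rnorm(8 * 3), nrow = 8)
  rownames(x) <- paste0("a", 1:8)
  hc <- upgma(dist(x))
  expect_equal(length(unique(cut_dendrogram(hc, 1)$group)), 1)
  allk <- cut_dendrogram(hc, 8)
  expect_equal(length(unique(allk$group)), 8)
  g3 <- cut_dendrogram(hc, 3)
  sizes <- as.integer(table(g3$group)[paste0("G", 1:3)])
  expect_true(all(diff(sizes) <= 0))
  expect_error(cut_dendrogram(hc, 0), "between 1")
  expect_error(cut_dendrogram(hc, 9), "between 1")
})

test_that("a two-pool synthetic collection is recovered exactly at k = 2", {
  lab <- simulate_collection(simulation_config(n_andean = 30,
                                               n_mesoamerican = 30,
                                               introgression_fraction = 0,
                                               seed = 27))
  z <- standardize(lab$collection)
  g <- cut_dendrogram(upgma(euclidean_distances(z)), 2)
  joined <- dplyr::inner_join(g, lab$truth, by = "id")
  expect_equal(ari(joined$group, joined$true_pool), 1)
})

test_that("summarize_groups profiles quantitative and qualitative traits", {
  col <- tiny_collection()
  one <- summarize_groups(col, tibble::tibble(id = col$id, group = "G1"))
  hsw <- one[one$trait == "HSW", ]
  expect_equal(hsw$mean, mean(col$HSW))
  expect_equal(hsw$sd, sd(col$HSW))
  gh <- one[one$trait == "GH", ]
  expect_equal(gh$modal_level, 1L)  # tie 2-2 broken toward smallest level
  expect_equal(gh$modal_freq, 0.5)

  # a group of identical accessions: sd 0, modal frequency 1
  dup <- as_collection(tibble::tibble(
    id = c("x1", "x2", "x3"), HSW = rep(33, 3), SSC = rep(2L, 3)))
  prof <- summarize_groups(dup, tibble::tibble(id = dup$id, group = "G1"))
  expect_equal(prof$sd[prof$trait == "HSW"], 0)
  expect_equal(prof$modal_freq[prof$trait == "SSC"], 1)

  expect_error(
    summarize_groups(col, tibble::tibble(id = "nope", group = "G1")),
    "unknown accession")
})

test_that("group means track the generating archetype means", {
  lab <- simulate_collection(simulation_config(n_andean = 40,
                                               n_mesoamerican = 40,
                                               introgression_fraction = 0,
                                               seed = 28))
  prof <- summarize_groups(lab$collection,
                           dplyr::rename(lab$truth, group = "true_pool"))
  arch <- cached_archetypes()
  for (pool in c("Andean", "Mesoamerican")) {
    a <- if (pool == "Andean") arch$andean else arch$mesoamerican
    row <- prof[prof$group == pool & prof$trait == "HSW", ]
    se <- a$quantitative$HSW$sd / sqrt(40)
    expect_lt(abs(row$mean - a$quantitative$HSW$mean), 3.5 * se)
  }
})

test_that("newick export round-trips through ape", {
  skip_if_not_installed("ape")
  set.seed(29)
  x <- matrix(rnorm(6 * 3), nrow = 6)
  rownames(x) <- paste0("acc", 1:6)
  hc <- upgma(dist(x))
  nwk <- as_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("acc", 1:6))
  expect_equal(ape::Ntip(phy), 6)
})
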