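toy_table <- function(counts, kitome = NULL, copies = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("ASV", seq_len(ncol(counts)))
  asv_table(counts,
            taxonomy = rep("Bacteria;unclassified", ncol(counts)),
            kitome = kitome %||% rep(0, ncol(counts)),
            meta = data.frame(sample = rownames(counts),
                              copies_per_g = copies %||% rep(1, nrow(counts))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("kitome subtraction clamps at zero and is exact otherwise", {
  tab <- toy_table(rbind(c(100, 45, 10), c(50, 45, 0)), kitome = c(20, 45, 5))
  corr <- kitome_correct(tab)
  expect_equal(unname(corr$corrected),
               rbind(c(80, 0, 5), c(30, 0, 0)))
  expect_equal(sum(corr$clamped), 1L)   # the 0 - 5 cell
  # a zero kitome leaves counts untouched (idempotence)
  clean <- toy_table(corr$corrected)
  expect_equal(kitome_correct(clean)$corrected, corr$corrected)
  # per-column arithmetic oracle on a seeded random table
  set.seed(8)
  m <- matrix(rpois(60, 30), nrow = 6)
  kit <- rpois(10, 10)
  got <- kitome_correct(toy_table(m, kitome = kit))$corrected
  expect_equal(unname(colSums(got)),
               colSums(pmax(sweep(m, 2, kit), 0)))
})

test_that("relative abundances are proportions summing to one", {
  tab <- toy_table(rbind(c(30, 10), c(0, 7), c(0, 0)))
  p <- relative_abundance(kitome_correct(tab))
  expect_equal(unname(p["s1", ]), c(0.75, 0.25))
  expect_equal(unname(p["s2", ]), c(0, 1))
  expect_equal(attr(p, "dropped"), "s3")
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_error(relative_abundance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("reads-first reactor averaging differs from averaging proportions", {
  tab <- generate_asv_table(seed = 17)
  reads_first <- reactor_mean_abundance(tab)
  props <- relative_abundance(kitome_correct(tab))
  prop_first <- colMeans(props)
  expect_equal(sum(reads_first), 1)
  # the two orders of operation genuinely disagree on heterogeneous grids
  expect_gt(max(abs(reads_first - prop_first)), 1e-4)
  # oracle for the reads-first path
  oracle <- pmax(colMeans(tab$counts) - tab$kitome, 0)
  expect_equal(reads_first, oracle / sum(oracle))
})

test_that("presence is confirmed only above the kitome read count", {
  tab <- toy_table(rbind(c(42, 100), c(38, 100)), kitome = c(45, 0))
  expect_false(confirm_presence(tab, "ASV1", c("s1", "s2")))  # mean 40 < 45
  expect_true(confirm_presence(tab, "ASV2", c("s1", "s2")))
  # a tie is not confirmation
  tie <- toy_table(rbind(c(45), c(45)), kitome = 45)
  expect_false(confirm_presence(tie, "ASV1", c("s1", "s2")))
  expect_error(confirm_presence(tab, "ASV9", "s1"), "unknown taxon")
  expect_error(confirm_presence(tab, "ASV1", character(0)), "non-empty")
})

test_that("the Hellinger transform maps proportions to the unit sphere", {
  expect_equal(hellinger(rbind(c(1, 0, 0))), rbind(c(1, 0, 0)))
  expect_equal(hellinger(rbind(rep(0.25, 4))), rbind(rep(0.5, 4)))
  set.seed(5)
  p <- relative_abundance(matrix(rpois(50, 20), 5))
  h <- hellinger(p)
  expect_equal(unname(rowSums(h^2)), rep(1, 5))
  # monotone within a row: ranking preserved
  expect_equal(order(p[1, ]), order(h[1, ]))
  expect_error(hellinger(rbind(c(-0.1, 1.1))), ">= 0")
})

test_that("PCA matches an independent eigendecomposition", {
  set.seed(6)
  x <- matrix(rnorm(80), nrow = 8)
  ord <- pca_ordination(x, n_components = 3)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  frac_oracle <- ev$values / sum(ev$values)
  expect_equal(ord$explained, frac_oracle[1:3], tolerance = 1e-10)
  xc <- scale(x, center = TRUE, scale = FALSE)
  scores_oracle <- xc %*% ev$vectors[, 1:3]
  for (k in 1:3) {
    expect_equal(abs(ord$scores[, k]), abs(scores_oracle[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_true(all(diff(ord$explained) <= 1e-12))
})

test_that("degenerate and constructed ordinations behave as expected", {
  dup <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  ord <- pca_ordination(dup)
  expect_true(ord$degenerate)
  expect_equal(ord$explained, c(0, 0))

  # two clusters separated along one axis dominate PC1
  x <- rbind(matrix(rnorm(20, 0, 0.1), 5), matrix(rnorm(20, 5, 0.1), 5))
  ord2 <- pca_ordination(x)
  expect_gt(ord2$explained[1], ord2$explained[2])
  expect_warning(pca_ordination(matrix(rnorm(6), 3), n_components = 5),
                 "truncated")
  expect_error(pca_ordination(matrix(1, 1, 3)), "2 samples")
})

test_that("column biomass tests gate the variance and test one-sided", {
  grid_cols <- rep(c("OL", "CL", "C", "CR", "OR"), each = 7)
  # near-identical values: nothing significant
  set.seed(9)
  flat <- data.frame(column = grid_cols,
                     copies_per_g = 1e8 * (1 + rnorm(35, 0, 1e-6)))
  res <- column_biomass_tests(flat)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p > 0.05))

  # pooled-t p-value equals the closed form from the t distribution
  set.seed(10)
  x <- rnorm(7, 5, 1)
  y <- rnorm(7, 6, 1)
  dat <- data.frame(column = c(rep("OL", 7), rep("C", 7)),
                    copies_per_g = c(x, y))
  dat <- rbind(dat, data.frame(column = c(rep("CL", 7), rep("CR", 7), rep("OR", 7)),
                               copies_per_g = rnorm(21, 6, 1)))
  res2 <- column_biomass_tests(dat)
  row <- res2[res2$column == "OL", ]
  sp <- sqrt(((7 - 1) * var(x) + (7 - 1) * var(y)) / 12)
  t_oracle <- (mean(x) - mean(y)) / (sp * sqrt(2 / 7))
  if (row$variant == "pooled") {
    expect_equal(row$t, t_oracle, tolerance = 1e-10)
    expect_equal(row$p, pt(t_oracle, 12), tolerance = 1e-10)
  }

  # a strongly enriched centre is detected in all four comparisons
  set.seed(11)
  strong <- data.frame(column = grid_cols,
                       copies_per_g = rnorm(35, 1e8, 1e7) +
                         ifelse(grid_cols == "C", 5e7, 0))
  expect_true(all(column_biomass_tests(strong)$p < 0.05))

  short <- data.frame(
    column = c("C", "C", "OL", rep(c("CL", "CR", "OR"), each = 2)),
    copies_per_g = c(1, 2, 3, rnorm(6, 2)))
  expect_warning(res3 <- column_biomass_tests(short), "OL.*skipped")
  expect_equal(nrow(res3), 3L)
  expect_false("OL" %in% res3$column)
})

test_that("the hotspot taxon is confirmed in the central column of generated grids", {
  hits <- 0L
  for (seed in 1:40) {
    tab <- generate_asv_table(seed = seed)
    centre <- tab$meta$sample[tab$meta$column == "C"]
    hits <- hits + confirm_presence(tab, tab$hotspot$taxon, centre)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("spatial interpolation reproduces nodes and planes exactly", {
  const <- matrix(5, 7, 5)
  m <- spatial_map(const, nx = 9, ny = 13)
  expect_true(all(abs(m$field - 5) < 1e-12))

  set.seed(12)
  vals <- matrix(runif(35), 7, 5)
  m2 <- spatial_map(vals, nx = 41, ny = 61)
  # node coordinates are present in the output raster (multiples of 0.1)
  for (col in 0:4) for (row in 1:7) {
    i <- which(abs(m2$y - row) < 1e-9)
    j <- which(abs(m2$x - col) < 1e-9)
    expect_equal(m2$field[i, j], vals[row, col + 1], tolerance = 1e-12)
  }

  # a linear ramp interpolates to the same plane everywhere
  ramp <- outer(1:7, 0:4, function(r, c) 2 * c + 0.5 * r)
  m3 <- spatial_map(ramp, nx = 21, ny = 31)
  plane <- outer(m3$y, m3$x, function(y, x) 2 * x + 0.5 * y)
  expect_equal(m3$field, plane, tolerance = 1e-10)

  holey <- vals
  holey[sample(35, 20)] <- NA
  expect_error(spatial_map(holey), "50 %")
  one_miss <- vals
  one_miss[3, 3] <- NA
  m4 <- spatial_map(one_miss, nx = 9, ny = 13)
  expect_false(anyNA(m4$field))
})
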