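# Reader, filters and PCA utility.

write_fixture <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, path, sep = if (ext == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  path
}

fixture_df <- function() {
  data.frame(
    individual = c("t1", "t2", "t3"), genotype = c("g1", "g1", "g2"),
    garden = "s1", block = c("b1", "b2", "b1"), year = 2021,
    growth_cm = c(12.5, 40, 0), dead = c(FALSE, FALSE, TRUE),
    garden_MCMT = -2.5, home_MCMT = c(-12, -12, -18),
    PC1 = c(0.1, 0.1, -0.2), PC2 = c(-0.3, -0.3, 0.4),
    PC3 = c(0.05, 0.05, 0.2),
    ancestry = c(0.2, 0.2, 0.9)
  )
}

test_that("reader parses records and applies the dead-tree zero coding", {
  df <- fixture_df()
  df$growth_cm[3] <- 7   # dead tree with nonzero recorded growth
  tb <- read_phenotype_table(write_fixture(df), dialect = "mini")
  expect_s3_class(tb, "phenotype_tables")
  expect_equal(nrow(tb$phenotypes), 3)
  expect_identical(tb$phenotypes$growth_cm[tb$phenotypes$dead], 0)
  expect_equal(nrow(tb$genotypes), 2)
  expect_identical(sort(tb$genotypes$genotype), c("g1", "g2"))
  # identifiers verbatim
  expect_identical(tb$phenotypes$individual, c("t1", "t2", "t3"))
  # tab dialect reads identically
  tb2 <- read_phenotype_table(write_fixture(df, "tsv"))
  expect_equal(tb2$phenotypes$growth_cm, tb$phenotypes$growth_cm)
})

test_that("reader reports schema and parse errors precisely", {
  df <- fixture_df()
  expect_error(read_phenotype_table(write_fixture(df[-2])), "genotype")
  df2 <- fixture_df(); df2$growth_cm <- c("12.5", "oops", "0")
  expect_error(read_phenotype_table(write_fixture(df2)), "row")
  df3 <- fixture_df(); df3$individual[2] <- "t1"
  expect_error(read_phenotype_table(write_fixture(df3)), "duplicate")
  # column mapping renames on the way in
  df4 <- fixture_df(); names(df4)[1] <- "tree_id"
  tb <- read_phenotype_table(write_fixture(df4),
                             col_map = c(individual = "tree_id"))
  expect_identical(tb$phenotypes$individual, c("t1", "t2", "t3"))
})

test_that("missing growth is flagged, not dropped, by the reader", {
  df <- fixture_df(); df$growth_cm[2] <- NA
  tb <- read_phenotype_table(write_fixture(df))
  expect_equal(nrow(tb$phenotypes), 3)
  expect_identical(tb$phenotypes$missing_growth, c(FALSE, TRUE, FALSE))
  ds <- filter_records(tb)
  expect_equal(ds$report$n_missing_growth_removed, 1)
})

test_that("filters remove negative growth and outliers, and balance", {
  study <- simulate_study(sim_config(seed = 2, n_genotypes = 8,
                                     n_gardens = 5))
  tb <- study$tables
  ds <- filter_records(tb)
  r <- ds$report
  expect_equal(r$n_input,
               r$n_output + r$n_year_excluded +
                 r$n_outlier_genotype_removed +
                 r$n_missing_growth_removed + r$n_negative_growth_removed)
  expect_true(r$n_negative_growth_removed > 0)
  expect_true(all(ds$data$growth_cm >= 0))

  # a single injected negative row is counted exactly once
  tb2 <- tb
  tb2$phenotypes$growth_cm[tb2$phenotypes$growth_cm >= 0][1] <- -5
  tb2$phenotypes$dead[tb2$phenotypes$growth_cm == -5] <- FALSE
  ds2 <- filter_records(tb2)
  expect_equal(ds2$report$n_negative_growth_removed,
               r$n_negative_growth_removed + 1)

  # no negatives and no outliers: identity
  tb3 <- tb
  tb3$phenotypes <- tb3$phenotypes[tb3$phenotypes$growth_cm >= 0, ]
  ds3 <- filter_records(tb3, outlier_genotypes = character(0))
  expect_equal(ds3$report$n_output, ds3$report$n_input)

  # outlier genotypes flagged in the table are excluded by default
  tb4 <- tb
  tb4$genotypes$outlier[1:2] <- TRUE
  ds4 <- filter_records(tb4)
  expect_false(any(ds4$data$genotype %in% tb4$genotypes$genotype[1:2]))
  expect_true(ds4$report$n_outlier_genotype_removed > 0)

  # year subsetting
  ds5 <- filter_records(tb, years = 2021)
  expect_true(all(ds5$data$year == 2021))

  expect_error(filter_records(tb, years = 1900), "no data")
})

test_that("written analysis table round-trips value-for-value", {
  study <- simulate_study(sim_config(seed = 3, n_genotypes = 6,
                                     n_gardens = 4))
  ds <- filter_records(study$tables)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_analysis_table(ds, csv, js)
  back <- utils::read.csv(csv)
  for (cn in c("growth_cm", "garden_MCMT", "home_MCMT", "PC1", "y", "g_s")) {
    expect_equal(back[[cn]], ds$data[[cn]], tolerance = 1e-12)
  }
  rep <- jsonlite::read_json(js)
  expect_equal(rep$n_output, ds$report$n_output)
})

test_that("SNP PCA matches a dense eigendecomposition and fixes signs", {
  set.seed(1)
  m <- matrix(sample(0:2, 6 * 20, replace = TRUE), nrow = 6)
  sc <- pca_genotype_matrix(m, k = 3)
  # oracle: eigendecomposition of the covariance of centered columns
  mc <- scale(m[, apply(m, 2, var) > 0], center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(mc))
  for (j in 1:3) {
    oracle <- as.numeric(mc %*% ev$vectors[, j])
    expect_equal(abs(sc[, j]), abs(oracle), tolerance = 1e-8)
  }
  expect_equal(ncol(pca_genotype_matrix(m, k = 0)), 0)
  expect_error(pca_genotype_matrix(m, k = 6), "exceeds")
})

test_that("PCA separates fixed divergent populations on PC1", {
  m <- rbind(matrix(0, 4, 30), matrix(2, 4, 30))
  m <- cbind(m, matrix(1, 8, 5))   # constant sites to drop
  expect_warning(sc <- pca_genotype_matrix(m, k = 1), "constant")
  expect_equal(length(unique(round(sc[1:4, 1], 10))), 1)
  expect_equal(length(unique(round(sc[5:8, 1], 10))), 1)
  expect_true(sign(sc[1, 1]) != sign(sc[5, 1]))
})
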