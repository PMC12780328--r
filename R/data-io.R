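# Reading, validating and filtering the study tables.
#
# The analyzed table has one row per tree x year with growth increment (cm),
# a death indicator, identifiers (individual, genotype, garden, block, year),
# the garden-year MCMT, and per-genotype covariates (home MCMT, genomic PCs,
# ancestry). Dead trees are coded growth = 0: that coding is what the
# zero-inflated likelihood consumes.

.required_cols <- c(
  "individual", "genotype", "garden", "block", "year",
  "growth_cm", "dead", "garden_MCMT", "home_MCMT",
  "PC1", "PC2", "PC3", "ancestry"
)

#' Read a phenotype-climate-genetics table
#'
#' Reads a delimited text file (comma or tab, autodetected from the
#' extension) with one row per tree x year, checks the schema, applies the
#' dead-tree coding (growth set to 0 for trees marked dead), and splits the
#' table into phenotype records, per-genotype info and per-garden-year
#' climate info. Identifiers are kept verbatim as character strings.
#'
#' @param path file path (`.csv` comma-separated, `.tsv`/`.txt` tab).
#' @param dialect `"mini"` (the 17-garden trial) or `"maxi"` (the
#'   544-genotype evaluation gardens); recorded on the result, the schema is
#'   identical.
#' @param col_map optional named character vector mapping required column
#'   names to the names used in the file, e.g. `c(individual = "tree_id")`.
#' @return an object of class `phenotype_tables`: a list with `phenotypes`,
#'   `genotypes`, `gardens` data frames and the `dialect`.
#' @export
read_phenotype_table <- function(path, dialect = c("mini", "maxi"),
                                 col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        stop("column mapping refers to absent column: ", col_map[[std]])
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  num_cols <- c("year", "growth_cm", "garden_MCMT", "home_MCMT",
                "PC1", "PC2", "PC3", "ancestry")
  for (cn in num_cols) {
    v <- raw[[cn]]
    blank <- is.na(v) | v == "" | toupper(v) == "NA"
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(parsed))
    if (length(bad)) {
      stop("unparseable numeric in column '", cn, "' at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    raw[[cn]] <- parsed
  }
  raw$dead <- .parse_logical(raw$dead)
  # structural-zero coding: a tree marked dead grows 0 by definition
  raw$growth_cm[raw$dead] <- 0
  raw$missing_growth <- is.na(raw$growth_cm)

  dup <- duplicated(raw[c("individual", "year")])
  if (any(dup)) {
    stop("duplicate (individual, year) rows, e.g. row ", which(dup)[1])
  }

  pheno_cols <- c("individual", "genotype", "garden", "block", "year",
                  "growth_cm", "dead", "missing_growth")
  geno_cols <- intersect(c("genotype", "home_MCMT", "PC1", "PC2", "PC3",
                           "ancestry", "lat", "lon", "outlier",
                           grep("^home_", names(raw), value = TRUE)),
                         names(raw))
  gard_cols <- intersect(c("garden", "year", "garden_MCMT", "garden_lat",
                           "garden_lon",
                           grep("^garden_", names(raw), value = TRUE)),
                         names(raw))
  genotypes <- unique(raw[geno_cols])
  if (anyDuplicated(genotypes$genotype)) {
    stop("genotype covariates are not constant within genotype")
  }
  if ("outlier" %in% names(genotypes)) {
    genotypes$outlier <- .parse_logical(genotypes$outlier)
  } else {
    genotypes$outlier <- FALSE
  }
  bad_anc <- !is.na(genotypes$ancestry) &
    (genotypes$ancestry < 0 | genotypes$ancestry > 1)
  if (any(bad_anc)) stop("ancestry proportion outside [0, 1]")
  gardens <- unique(raw[gard_cols])
  if (anyDuplicated(gardens[c("garden", "year")])) {
    stop("garden climate is not constant within garden-year")
  }
  structure(
    list(phenotypes = raw[c(pheno_cols,
                            setdiff(names(raw), c(pheno_cols, geno_cols,
                                                  gard_cols)))],
         genotypes = genotypes, gardens = gardens, dialect = dialect),
    class = "phenotype_tables"
  )
}

.parse_logical <- function(v) {
  if (is.logical(v)) return(v)
  out <- rep(NA, length(v))
  out[toupper(v) %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[toupper(v) %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) stop("unparseable logical value: ",
                       v[which(is.na(out))[1]])
  out
}

#' Assemble phenotype tables from in-memory data frames
#'
#' Convenience constructor used by the synthetic-data generator and by
#' tests: takes the three tables already split and returns the same object
#' `read_phenotype_table()` produces.
#'
#' @param phenotypes,genotypes,gardens data frames with the reader's columns.
#' @param dialect `"mini"` or `"maxi"`.
#' @return a `phenotype_tables` object.
#' @export
phenotype_tables <- function(phenotypes, genotypes, gardens,
                             dialect = "mini") {
  if (!"missing_growth" %in% names(phenotypes)) {
    phenotypes$missing_growth <- is.na(phenotypes$growth_cm)
  }
  if (!"outlier" %in% names(genotypes)) genotypes$outlier <- FALSE
  structure(list(phenotypes = phenotypes, genotypes = genotypes,
                 gardens = gardens, dialect = dialect),
            class = "phenotype_tables")
}

#' Filter records and build the analysis dataset
#'
#' Applies the pre-analysis filters: keep only requested measurement years,
#' drop all records of outlier genotypes, drop records with missing growth,
#' and drop negative growth increments (herbivory / measurement error).
#' Joins genotype and garden covariates, scales the numeric covariates
#' without centering, and log1p-transforms growth. The returned filter
#' report balances exactly: `n_input = n_output + removals`.
#'
#' @param tables a `phenotype_tables` object.
#' @param outlier_genotypes character vector of genotype ids to exclude;
#'   defaults to the genotypes flagged `outlier` in the table.
#' @param years integer vector of calendar years to keep (default: all).
#' @return an `analysis_dataset`: list with `data` (joined, filtered rows
#'   with scaled covariate columns and the transformed response `y`),
#'   `scaling` (named divisors), `transform`, `report`, and the observed
#'   garden MCMT range.
#' @export
filter_records <- function(tables, outlier_genotypes = NULL, years = NULL) {
  stopifnot(inherits(tables, "phenotype_tables"))
  ph <- tables$phenotypes
  if (is.null(outlier_genotypes)) {
    outlier_genotypes <- tables$genotypes$genotype[tables$genotypes$outlier]
  }
  n_input <- nrow(ph)

  keep_year <- if (is.null(years)) rep(TRUE, nrow(ph)) else ph$year %in% years
  n_year_excluded <- sum(!keep_year)
  ph <- ph[keep_year, , drop = FALSE]

  is_outlier <- ph$genotype %in% outlier_genotypes
  n_outlier_removed <- sum(is_outlier)
  ph <- ph[!is_outlier, , drop = FALSE]

  n_missing <- sum(ph$missing_growth)
  ph <- ph[!ph$missing_growth, , drop = FALSE]

  neg <- ph$growth_cm < 0
  neg_by_year <- if (any(neg)) table(ph$year[neg]) else table(integer(0))
  n_negative <- sum(neg)
  ph <- ph[!neg, , drop = FALSE]

  if (nrow(ph) == 0) stop("no data left after filtering")

  gt <- tables$genotypes[!tables$genotypes$genotype %in% outlier_genotypes, ,
                         drop = FALSE]
  unknown_g <- setdiff(ph$genotype, gt$genotype)
  if (length(unknown_g)) {
    stop("records reference unknown genotype(s): ",
         paste(utils::head(unknown_g, 5), collapse = ", "))
  }
  joined <- merge(ph, gt, by = "genotype", sort = FALSE)
  joined <- merge(joined, tables$gardens, by = c("garden", "year"),
                  sort = FALSE)
  if (nrow(joined) != nrow(ph)) {
    stop("garden MCMT missing for some (garden, year) present in records")
  }
  if (anyNA(joined$garden_MCMT) || anyNA(joined$home_MCMT)) {
    stop("missing MCMT values after join")
  }
  # stable order so that fits are reproducible regardless of input order
  joined <- joined[order(joined$garden, joined$block, joined$individual,
                         joined$year), , drop = FALSE]
  rownames(joined) <- NULL

  scaling <- c(
    garden_MCMT = scale_no_center(joined$garden_MCMT)$divisor,
    home_MCMT = scale_no_center(joined$home_MCMT)$divisor,
    PC1 = scale_no_center(joined$PC1)$divisor,
    PC2 = scale_no_center(joined$PC2)$divisor,
    PC3 = scale_no_center(joined$PC3)$divisor
  )
  joined$g_s <- joined$garden_MCMT / scaling[["garden_MCMT"]]
  joined$h_s <- joined$home_MCMT / scaling[["home_MCMT"]]
  joined$pc1_s <- joined$PC1 / scaling[["PC1"]]
  joined$pc2_s <- joined$PC2 / scaling[["PC2"]]
  joined$pc3_s <- joined$PC3 / scaling[["PC3"]]
  joined$y <- transform_growth(joined$growth_cm)

  report <- list(
    n_input = n_input,
    n_year_excluded = n_year_excluded,
    n_outlier_genotype_removed = n_outlier_removed,
    n_missing_growth_removed = n_missing,
    n_negative_growth_removed = n_negative,
    n_negative_growth_by_year = as.list(neg_by_year),
    n_output = nrow(joined)
  )
  structure(
    list(data = joined, scaling = scaling, transform = "log1p",
         report = report,
         garden_mcmt_range = range(joined$garden_MCMT)),
    class = "analysis_dataset"
  )
}

#' Write the prepared analysis table and its filter report
#'
#' @param dataset an `analysis_dataset`.
#' @param csv_path output CSV path for the filtered analysis table.
#' @param report_path optional JSON path for the filter report.
#' @export
write_analysis_table <- function(dataset, csv_path, report_path = NULL) {
  stopifnot(inherits(dataset, "analysis_dataset"))
  utils::write.csv(dataset$data, csv_path, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(dataset$report, report_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(csv_path)
}

#' @export
print.analysis_dataset <- function(x, ...) {
  r <- x$report
  cat("Analysis dataset:", r$n_output, "measurements of",
      length(unique(x$data$individual)), "trees,",
      length(unique(x$data$genotype)), "genotypes,",
      length(unique(x$data$garden)), "gardens\n")
  cat("  removed:", r$n_negative_growth_removed, "negative growth,",
      r$n_outlier_genotype_removed, "outlier-genotype,",
      r$n_missing_growth_removed, "missing,",
      r$n_year_excluded, "other-year records\n")
  cat("  zero fraction:", round(mean(x$data$y == 0), 3),
      " garden MCMT range:", paste(round(x$garden_mcmt_range, 1),
                                   collapse = " to "), "\n")
  invisible(x)
}
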