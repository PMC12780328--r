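# Model specifications and design matrices.
#
# The full model's fixed part, on scaled covariates, is
#   y ~ G + G^2 + H + H^2 + G^2H^2 + G^2H + GH^2 + GH
#       + PC1 + PC2 + PC3 + PC1*G + PC1*G^2 + PC2*G + PC2*G^2
#       + PC3*G + PC3*G^2
# with G the garden MCMT, H the home MCMT and PC1-3 the genomic PCs; the
# zero-inflation (mortality, logit link) part uses the same formula.
# Random intercepts: block nested in garden, genotype, year, individual.

.term_defs <- list(
  G      = function(d) d$g_s,
  G2     = function(d) d$g_s^2,
  H      = function(d) d$h_s,
  H2     = function(d) d$h_s^2,
  G2H2   = function(d) d$g_s^2 * d$h_s^2,
  G2H    = function(d) d$g_s^2 * d$h_s,
  GH2    = function(d) d$g_s * d$h_s^2,
  GH     = function(d) d$g_s * d$h_s,
  PC1    = function(d) d$pc1_s,
  PC2    = function(d) d$pc2_s,
  PC3    = function(d) d$pc3_s,
  `PC1:G`  = function(d) d$pc1_s * d$g_s,
  `PC1:G2` = function(d) d$pc1_s * d$g_s^2,
  `PC2:G`  = function(d) d$pc2_s * d$g_s,
  `PC2:G2` = function(d) d$pc2_s * d$g_s^2,
  `PC3:G`  = function(d) d$pc3_s * d$g_s,
  `PC3:G2` = function(d) d$pc3_s * d$g_s^2
)

# variable set of each term, used for the marginality (type II) logic;
# the squared covariates are distinct constructed variables, as they would
# be in an I(x^2) formula
.term_var_sets <- list(
  G = "G", G2 = "G2", H = "H", H2 = "H2",
  G2H2 = c("G2", "H2"), G2H = c("G2", "H"),
  GH2 = c("G", "H2"), GH = c("G", "H"),
  PC1 = "PC1", PC2 = "PC2", PC3 = "PC3",
  `PC1:G` = c("PC1", "G"), `PC1:G2` = c("PC1", "G2"),
  `PC2:G` = c("PC2", "G"), `PC2:G2` = c("PC2", "G2"),
  `PC3:G` = c("PC3", "G"), `PC3:G2` = c("PC3", "G2")
)
.term_vars <- function(term) {
  if (term == "(Intercept)") return(character(0))
  .term_var_sets[[term]]
}

.climate_terms <- c("G", "G2", "H", "H2", "G2H2", "G2H", "GH2", "GH")
.genetic_terms <- c("PC1", "PC2", "PC3",
                    "PC1:G", "PC1:G2", "PC2:G", "PC2:G2",
                    "PC3:G", "PC3:G2")
.default_random <- c("block", "genotype", "year", "individual")

#' Construct a model specification
#'
#' @param cond_terms fixed-effect terms of the conditional (growth) part,
#'   from the catalog `G, G2, H, H2, G2H2, G2H, GH2, GH, PC1..PC3,
#'   PCk:G, PCk:G2`; an intercept is always included.
#' @param zi_terms fixed terms of the zero-inflation (mortality) part, or
#'   `NULL` to suppress zero inflation (plain Gaussian mixed model).
#' @param random random-intercept factors, a subset of
#'   `c("block", "genotype", "year", "individual")` (`block` is nested in
#'   garden).
#' @param zi_random random factors of the zero-inflation part (default:
#'   same factors, separate variances).
#' @param name optional label.
#' @return a `model_spec` object.
#' @export
model_spec <- function(cond_terms, zi_terms = cond_terms,
                       random = .default_random,
                       zi_random = random, name = "custom") {
  check_terms <- function(tt) {
    bad <- setdiff(tt, names(.term_defs))
    if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  }
  check_terms(cond_terms)
  if (!is.null(zi_terms)) check_terms(zi_terms)
  bad_rf <- setdiff(c(random, zi_random), .default_random)
  if (length(bad_rf)) stop("unknown random factor(s): ",
                           paste(bad_rf, collapse = ", "))
  structure(list(name = name, cond_terms = cond_terms, zi_terms = zi_terms,
                 random = random,
                 zi_random = if (is.null(zi_terms)) character(0) else zi_random),
            class = "model_spec")
}

#' The study's model catalog
#'
#' `full` carries environment (garden MCMT, quadratic), home climate and
#' its interactions with garden MCMT, and the genomic PCs with their
#' garden-MCMT interactions. `genetics_only` drops the home-MCMT terms;
#' `climate_only` drops the genomic PCs. All three keep the quadratic
#' garden-MCMT response, and `full` is the union of the other two.
#'
#' @param name one of `"full"`, `"genetics_only"`, `"climate_only"`.
#' @param random random factors (see [model_spec()]).
#' @return a `model_spec`.
#' @export
make_model <- function(name = c("full", "genetics_only", "climate_only"),
                       random = .default_random) {
  if (!is.character(name) || !name[1] %in%
      c("full", "genetics_only", "climate_only")) {
    stop("unknown model name; catalog: full, genetics_only, climate_only")
  }
  name <- match.arg(name)
  terms <- switch(
    name,
    full = c(.climate_terms, .genetic_terms),
    genetics_only = c("G", "G2", .genetic_terms),
    climate_only = .climate_terms
  )
  model_spec(terms, zi_terms = terms, random = random, name = name)
}

#' Build design matrices for a model specification
#'
#' Evaluates the fixed-effect term columns (products of scaled covariates)
#' and the sparse random-intercept incidence matrix, one column block per
#' grouping factor.
#'
#' @param dataset an `analysis_dataset` (or any data frame carrying the
#'   scaled covariate columns and identifiers).
#' @param spec a `model_spec`.
#' @return a `design` object: `X` (conditional fixed design), `X_zi`,
#'   `Z` (sparse incidence), `rf` (per-column factor index and level names),
#'   `y`, `zero` indicator, and row metadata.
#' @export
build_design <- function(dataset, spec) {
  df <- if (inherits(dataset, "analysis_dataset")) dataset$data else dataset
  X <- .fixed_matrix(df, spec$cond_terms)
  X_zi <- if (is.null(spec$zi_terms)) NULL else .fixed_matrix(df, spec$zi_terms)
  rf_all <- union(spec$random, spec$zi_random)
  Zinfo <- .random_incidence(df, rf_all)
  y <- df$y
  structure(list(
    X = X, X_zi = X_zi, Z = Zinfo$Z, rf = Zinfo$rf,
    random = spec$random, zi_random = spec$zi_random,
    y = y, zero = y == 0, n = length(y), spec = spec,
    meta = df[intersect(c("individual", "genotype", "garden", "block",
                          "year"), names(df))]
  ), class = "zigmm_design")
}

.fixed_matrix <- function(df, terms) {
  cols <- c(list(`(Intercept)` = rep(1, nrow(df))),
            lapply(.term_defs[terms], function(f) f(df)))
  X <- do.call(cbind, cols)
  colnames(X) <- c("(Intercept)", terms)
  X
}

.random_incidence <- function(df, factors) {
  if (length(factors) == 0) {
    return(list(Z = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         dims = c(nrow(df), 0)),
                rf = list(factor_of_col = integer(0), factors = character(0),
                          levels = list())))
  }
  blocks <- lapply(factors, function(f) {
    v <- switch(f,
                block = interaction(df$garden, df$block, drop = TRUE,
                                    sep = ":"),
                genotype = factor(df$genotype),
                year = factor(df$year),
                individual = factor(df$individual))
    if (nlevels(v) < 2) {
      stop("random factor '", f, "' has fewer than 2 levels")
    }
    v
  })
  names(blocks) <- factors
  Zs <- lapply(blocks, function(v) {
    Matrix::sparseMatrix(i = seq_along(v), j = as.integer(v),
                         x = 1, dims = c(length(v), nlevels(v)))
  })
  Z <- do.call(cbind, Zs)
  list(Z = Z,
       rf = list(
         factor_of_col = rep(seq_along(factors),
                             vapply(blocks, nlevels, 1L)),
         factors = factors,
         levels = lapply(blocks, levels)
       ))
}
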