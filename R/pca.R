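#' PCA of a genotype-by-site SNP matrix
#'
#' Column-centered principal component analysis of a biallelic dosage
#' matrix (entries 0/1/2, no missing data), the standard summary of
#' population structure used as genotype covariates. Constant (fixed)
#' sites carry no information and are dropped with a warning. Score signs
#' are made reproducible by forcing the largest-magnitude loading of each
#' component to be positive.
#'
#' @param snp_matrix numeric matrix, genotypes in rows, sites in columns.
#' @param k number of components to return (`k = 0` gives a 0-column score
#'   matrix).
#' @return matrix of PC scores (genotypes x k) with an attribute
#'   `explained` giving the proportion of variance per component.
#' @export
pca_genotype_matrix <- function(snp_matrix, k) {
  stopifnot(is.matrix(snp_matrix), k >= 0)
  if (anyNA(snp_matrix)) stop("SNP matrix has missing entries")
  keep <- apply(snp_matrix, 2, function(col) stats::var(col) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant site(s) dropped before PCA")
    snp_matrix <- snp_matrix[, keep, drop = FALSE]
  }
  max_k <- min(dim(snp_matrix)) - 1L
  if (k > max_k) stop("k exceeds min(dim) - 1 = ", max_k)
  if (k == 0) {
    out <- matrix(numeric(0), nrow = nrow(snp_matrix), ncol = 0)
    attr(out, "explained") <- numeric(0)
    return(out)
  }
  pc <- stats::prcomp(snp_matrix, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load_j <- pc$rotation[, j]
    if (load_j[which.max(abs(load_j))] < 0) scores[, j] <- -scores[, j]
  }
  attr(scores, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}
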