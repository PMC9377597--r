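# Anderson-Rubin factor scoring from a fixed bifactor loadings matrix.
#
# Given item responses and externally estimated loadings, compute factor
# scores whose sample covariance is the identity, preserving the
# orthogonality of the bifactor solution. With Z the item z-scores, R their
# correlation matrix, L the loadings and Psi = diag(1 - communality):
#
#   W = Psi^-1 L (L' Psi^-1 R Psi^-1 L)^(-1/2),   scores = Z W
#
# where the inverse square root is the symmetric (eigen) one. Because the
# sample R appears inside the whitening term, cov(scores) = I holds exactly
# in-sample, not just in the population model.

# symmetric inverse square root of a positive-definite matrix
.inv_sqrtm <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(e$values < tol)) {
    stop("matrix is numerically singular in Anderson-Rubin weight computation",
         call. = FALSE)
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Anderson-Rubin factor scores
#'
#' Items present in the loadings but absent from the response matrix are
#' dropped by row-subsetting the loadings before the weights are computed,
#' so reduced questionnaire batteries can be scored against a full
#' loadings matrix. Items are standardised with the current sample's
#' moments.
#'
#' @param responses Participants x items numeric matrix; colnames are item
#'   ids matching the loadings rownames.
#' @param loadings Items x factors loadings matrix with rownames (item
#'   ids) and colnames (factor labels).
#' @return Participants x factors matrix of standardized scores whose
#'   sample covariance is the identity.
#' @export
anderson_rubin_scores <- function(responses, loadings) {
  responses <- as.matrix(responses)
  loadings <- as.matrix(loadings)
  .check(!is.null(colnames(responses)) && !is.null(rownames(loadings)),
         "responses need colnames and loadings need rownames (item ids)")
  .check(nrow(responses) > ncol(loadings),
         "need more participants than factors")
  items <- intersect(colnames(responses), rownames(loadings))
  .check(length(items) > ncol(loadings),
         "no (or too few) items shared between responses and loadings")
  l <- loadings[items, , drop = FALSE]
  h2 <- rowSums(l^2)
  .check(all(h2 < 1), "item communalities must be below 1")
  z <- scale(responses[, items, drop = FALSE])
  sds <- attr(z, "scaled:scale")
  if (any(sds == 0)) {
    stop("constant item(s): ", paste(items[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(z)
  psi_inv <- diag(1 / (1 - h2), length(h2))
  a <- psi_inv %*% l
  w <- a %*% .inv_sqrtm(t(a) %*% r %*% a)
  scores <- z %*% w
  colnames(scores) <- colnames(loadings)
  rownames(scores) <- rownames(responses)
  scores
}
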