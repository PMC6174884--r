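#' Encode per-strain genotypes as an alternate-allele dosage matrix
#'
#' Builds the union of variant keys across strains and codes each
#' (variant, strain) cell as alternate-allele dosage: 0/0 -> 0, 0/1 -> 1,
#' 1/1 -> 2. A key absent from a strain's calls but covered there (depth
#' >= \code{minDepth} in its coverage track) is homozygous reference (0);
#' absent and uncovered -- or absent with no coverage track supplied -- is
#' missing (\code{NA}). Allele frequencies (dosage / 2, the fallback when
#' per-allele depths are unavailable) are attached as attribute
#' \code{"af"}.
#'
#' @param variantSets named list of variant data.frames, one per strain.
#' @param coverage optional named list of coverage tracks matching
#'   \code{variantSets}.
#' @param minDepth depth at which an uncalled site counts as covered
#'   (default 5).
#' @return A numeric matrix, rows = variant keys, columns = strains, with
#'   attribute \code{"af"}.
#' @export
encodeGenotypes <- function(variantSets, coverage = NULL, minDepth = 5L) {
  stopifnot(is.list(variantSets), !is.null(names(variantSets)))
  strains <- names(variantSets)
  keyList <- lapply(variantSets, variantKey)
  keys <- unique(unlist(keyList, use.names = FALSE))
  code <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)
  mat <- matrix(NA_real_, nrow = length(keys), ncol = length(strains),
                dimnames = list(keys, strains))
  if (!length(keys)) {
    attr(mat, "af") <- mat
    return(mat)
  }
  keyPos <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  for (s in strains) {
    idx <- match(keyList[[s]], keys)
    mat[idx, s] <- unname(code[variantSets[[s]]$genotype])
    absent <- which(is.na(mat[, s]))
    if (length(absent) && !is.null(coverage[[s]])) {
      depth <- depthAt(coverage[[s]], keyPos[absent, 1L],
                       as.integer(keyPos[absent, 2L]))
      mat[absent[!is.na(depth) & depth >= minDepth], s] <- 0
    }
  }
  attr(mat, "af") <- mat / 2
  mat
}

#' Pairwise strain similarity from a genotype matrix
#'
#' Pearson correlation and Euclidean distance between two strains'
#' dosage columns, over sites where both are non-missing
#' (pairwise-complete deletion). The allele-frequency correlation uses
#' the matrix's \code{"af"} attribute the same way.
#'
#' @param matrix genotype matrix from \code{\link{encodeGenotypes}}.
#' @param pair character vector of two strain names (default: first two
#'   columns).
#' @return A list of class \code{SimilarityResult}: \code{pair},
#'   \code{pearson}, \code{euclidean}, \code{nSitesUsed},
#'   \code{afPearson}, and \code{flag} (\code{"ok"},
#'   \code{"too_few_sites"} or \code{"zero_variance"}; degenerate inputs
#'   leave the undefined statistics \code{NA}).
#' @export
pairwiseSimilarity <- function(matrix, pair = colnames(matrix)[1:2]) {
  stopifnot(length(pair) == 2L, all(pair %in% colnames(matrix)))
  a <- matrix[, pair[1L]]; b <- matrix[, pair[2L]]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  res <- list(pair = pair, pearson = NA_real_, euclidean = NA_real_,
              nSitesUsed = n, afPearson = NA_real_, flag = "ok")
  if (n < 2L) {
    res$flag <- "too_few_sites"
    return(structure(res, class = "SimilarityResult"))
  }
  res$euclidean <- sqrt(sum((a[ok] - b[ok])^2))
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    res$flag <- "zero_variance"
  } else {
    res$pearson <- cor(a[ok], b[ok])
  }
  af <- attr(matrix, "af")
  if (!is.null(af)) {
    fa <- af[, pair[1L]]; fb <- af[, pair[2L]]
    fok <- !is.na(fa) & !is.na(fb)
    if (sum(fok) >= 2L && stats::sd(fa[fok]) > 0 && stats::sd(fb[fok]) > 0)
      res$afPearson <- cor(fa[fok], fb[fok])
  }
  structure(res, class = "SimilarityResult")
}

#' @export
print.SimilarityResult <- function(x, ...) {
  cat("Similarity ", x$pair[1L], " vs ", x$pair[2L], ": r = ",
      format(x$pearson, digits = 4), ", d = ",
      format(x$euclidean, digits = 6), " over ", x$nSitesUsed, " sites",
      if (x$flag != "ok") paste0(" [", x$flag, "]"), "\n", sep = "")
  invisible(x)
}

#' All-pairs similarity table
#'
#' Computes \code{\link{pairwiseSimilarity}} for every strain pair and
#' lays the results out with Pearson correlations in the lower triangle
#' and Euclidean distances in the upper triangle.
#'
#' @param matrix genotype matrix from \code{\link{encodeGenotypes}}.
#' @return A list: \code{table} (the mixed-triangle data.frame) and
#'   \code{pairs} (one \code{SimilarityResult} per pair).
#' @export
similarityMatrix <- function(matrix) {
  strains <- colnames(matrix)
  k <- length(strains)
  tab <- base::matrix("", k, k, dimnames = list(strains, strains))
  pairs <- list()
  if (k >= 2L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    res <- pairwiseSimilarity(matrix, c(strains[i], strains[j]))
    pairs[[paste(strains[i], strains[j], sep = "-")]] <- res
    tab[j, i] <- formatC(res$pearson, digits = 2, format = "f")
    tab[i, j] <- formatC(res$euclidean, digits = 2, format = "f")
  }
  list(table = as.data.frame(tab), pairs = pairs)
}
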