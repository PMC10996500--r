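#' Genotype dosage matrix from phased genomes
#'
#' Collapses haplotype pairs into derived-allele dosages (0/1/2) over
#' the sites segregating among the requested samples.
#'
#' @param genomes a `hap_genomes` object.
#' @param samples sample ids to include (default all).
#' @param polymorphic_only drop sites fixed (0 or 2 in everyone) in the
#'   selected sample set (default TRUE).
#' @return integer matrix, samples in rows, sites in columns; column
#'   names are the 1-based site positions.
#' @export
dosage_matrix <- function(genomes, samples = names(genomes$haps),
                          polymorphic_only = TRUE) {
  haps <- genomes$haps[samples]
  if (any(vapply(haps, is.null, logical(1)))) stop("unknown sample id(s)")
  pos <- sort(unique(unlist(lapply(haps, function(h) c(h$h1, h$h2)))))
  X <- matrix(0L, nrow = length(haps), ncol = length(pos),
              dimnames = list(samples,
                              format(pos + 1, scientific = FALSE,
                                     trim = TRUE)))
  for (i in seq_along(haps)) {
    X[i, ] <- (pos %in% haps[[i]]$h1) + (pos %in% haps[[i]]$h2)
  }
  if (polymorphic_only && ncol(X) > 0) {
    cs <- colSums(X)
    X <- X[, cs > 0L & cs < 2L * nrow(X), drop = FALSE]
  }
  X
}

#' Beta allele-sharing kinship estimator
#'
#' For each pair of individuals the allele-matching proportion over
#' sites is \eqn{M_{ij} = \frac{1}{S}\sum_s [x_i x_j +
#' (2-x_i)(2-x_j)]/4} (dosages \eqn{x} in 0/1/2), then rescaled as
#' \eqn{\beta_{ij} = (M_{ij} - \bar M)/(1 - \bar M)} where \eqn{\bar M}
#' is the mean matching proportion over all distinct pairs of the
#' reference set. On this scale the average reference pair sits at 0
#' and a parent-child pair from unrelated founders is expected at 0.25.
#' The estimator is stable in small samples because the rescaling uses
#' the sample's own mean sharing rather than allele-frequency
#' estimates.
#'
#' @param X dosage matrix, individuals x sites, values in 0/1/2
#'   (see [dosage_matrix()]).
#' @param reference ids (or logical/integer index into rows of `X`)
#'   defining the reference population whose mean pairwise sharing sets
#'   the zero point; default all individuals. Passing the pedigree
#'   founders anchors estimates to the founder generation, the scale on
#'   which path-counting expectations are defined.
#' @return symmetric numeric matrix of kinship estimates with a
#'   `reference_mean_matching` attribute; diagonal holds self-sharing
#'   on the same scale.
#' @export
kinship_matrix_beta <- function(X, reference = rownames(X)) {
  if (nrow(X) < 2) stop("need at least two individuals")
  if (ncol(X) < 1) stop("need at least one polymorphic site")
  cs <- colSums(X)
  if (all(cs == 0L | cs == 2L * nrow(X))) {
    stop("all sites are monomorphic; the sharing scale is undefined")
  }
  S <- ncol(X)
  Xn <- X
  M <- (Xn %*% t(Xn) + (2 - Xn) %*% t(2 - Xn)) / (4 * S)
  if (is.character(reference)) reference <- match(reference, rownames(X))
  Mr <- M[reference, reference, drop = FALSE]
  mbar <- mean(Mr[upper.tri(Mr)])
  if (!is.finite(mbar) || mbar >= 1) {
    stop("reference pairs share all alleles; the sharing scale is undefined")
  }
  K <- (M - mbar) / (1 - mbar)
  attr(K, "reference_mean_matching") <- mbar
  K
}

#' Compare estimated and expected kinship over a pedigree
#'
#' Groups pairs by relationship label and reports the mean estimated
#' kinship against the path-counting expectation, then fits an
#' ordinary-least-squares regression of estimates on expectations over
#' related pairs (pairs with a common ancestor) and reports its
#' r-squared. Unrelated pairs can optionally be included in the
#' regression.
#'
#' @param relationships relationship table from [all_pairwise()] on the
#'   same pedigree.
#' @param kinship kinship matrix from [kinship_matrix_beta()]; pairs
#'   whose members are absent from the matrix (e.g. implicit founders
#'   withheld from the VCF) are dropped.
#' @param include_unrelated include pairs without a common ancestor in
#'   the regression (default FALSE).
#' @return list of class `kinship_validation`: `table` (per-label rows:
#'   `label`, `expected`, `mean_observed`, `n_pairs`), `slope`,
#'   `intercept`, `r_squared`, `n_pairs`, `pairs` (per-pair data used
#'   for the fit).
#' @export
compare_observed_expected <- function(relationships, kinship,
                                      include_unrelated = FALSE) {
  ids <- rownames(kinship)
  rel <- relationships[relationships$id_a %in% ids &
                         relationships$id_b %in% ids, , drop = FALSE]
  if (nrow(rel) == 0) stop("no pedigree pair is covered by the kinship matrix")
  rel$observed <- kinship[cbind(match(rel$id_a, ids), match(rel$id_b, ids))]
  related <- !is.na(rel$grt)
  use <- if (include_unrelated) rep(TRUE, nrow(rel)) else related
  pairs <- rel[use, c("id_a", "id_b", "label", "expected_kinship",
                      "observed")]
  labs <- unique(pairs$label)
  tab <- do.call(rbind, lapply(labs, function(l) {
    p <- pairs[pairs$label == l, ]
    data.frame(label = l, expected = p$expected_kinship[1],
               mean_observed = mean(p$observed), n_pairs = nrow(p),
               stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$expected), ]
  rownames(tab) <- NULL
  fit <- stats::lm(observed ~ expected_kinship, data = pairs)
  structure(list(table = tab,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_pairs = nrow(pairs),
                 pairs = pairs),
            class = "kinship_validation")
}

#' @export
print.kinship_validation <- function(x, ...) {
  cat(sprintf(
    "<kinship_validation> %d pairs; slope %.3f, intercept %.4f, r^2 %.3f\n",
    x$n_pairs, x$slope, x$intercept, x$r_squared))
  print(x$table, row.names = FALSE)
  invisible(x)
}
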