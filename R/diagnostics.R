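#' Standardized item response residuals at the EAP trait estimates
#'
#' `z_ij = (y_ij - P_ij) / sqrt(P_ij (1 - P_ij))` with
#' `P_ij = icc_probability(theta_i, a_j, b_j)`. Probabilities numerically
#' equal to 0 or 1 are clamped at `eps` (and counted) to keep the residuals
#' finite.
#'
#' @param m a [response_matrix()]
#' @param bank fitted `item_bank`
#' @param theta `theta_estimates` for the same respondents
#' @param eps clamping bound for extreme probabilities
#' @return object of class `irt_residuals`: list with `z` (n x J residuals),
#'   `p` (n x J model probabilities), `n_clamped`.
#' @export
standardized_residuals <- function(m, bank, theta, eps = 1e-10) {
  Y <- m$responses
  idx <- match(colnames(Y), bank$items$label)
  if (anyNA(idx)) stop("item/bank mismatch")
  a <- bank$items$a[idx]
  b <- bank$items$b[idx]
  th <- theta$theta
  if (length(th) != nrow(Y)) stop("theta/respondent mismatch")
  P <- stats::plogis(outer(th, b, "-") * rep(a, each = nrow(Y)))
  n_clamped <- sum(P < eps | P > 1 - eps)
  P <- clamp(P, eps, 1 - eps)
  z <- (Y - P) / sqrt(P * (1 - P))
  dimnames(z) <- dimnames(P) <- list(NULL, colnames(Y))
  structure(list(z = z, p = P, n_clamped = n_clamped),
            class = "irt_residuals")
}

#' Infit and outfit mean-square item fit statistics
#'
#' Outfit is the unweighted mean of squared standardized residuals per item;
#' infit weights them by the binomial information `W_ij = P_ij (1 - P_ij)`.
#' Both are ~1 for a well-fitting item; the conventional acceptance band is
#' 0.7 to 1.3.
#'
#' @param res an `irt_residuals` object
#' @param range acceptance band for the in-range flag
#' @return data.frame with per-item `infit`, `outfit` and `in_range`.
#' @export
infit_outfit <- function(res, range = c(0.7, 1.3)) {
  z2 <- res$z^2
  W <- res$p * (1 - res$p)
  tw <- colSums(W)
  if (any(tw == 0)) stop("zero total information weight for an item")
  outfit <- colMeans(z2)
  infit <- colSums(W * z2) / tw
  data.frame(item = seq_len(ncol(z2)), label = colnames(z2),
             infit = infit, outfit = outfit,
             in_range = infit >= range[1] & infit <= range[2] &
                        outfit >= range[1] & outfit <= range[2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal component analysis of the standardized residuals
#'
#' Eigen-decomposition of the J x J residual correlation matrix. Under a
#' correctly specified unidimensional model the residuals carry no common
#' structure and all eigenvalues sit near 1; a dominant first component
#' signals a violated unidimensionality assumption.
#'
#' @param res an `irt_residuals` object
#' @param dominance_ratio the first component is called dominant when its
#'   eigenvalue exceeds this multiple of the second.
#' @return list with `eigenvalues` (descending), `loadings` (first
#'   component), `unidimensional` verdict.
#' @export
residual_pca <- function(res, dominance_ratio = 2) {
  z <- res$z
  if (nrow(z) <= ncol(z)) stop("need more respondents than items")
  R <- stats::cor(z)
  if (any(!is.finite(R))) warning("rank-deficient or constant residual columns")
  e <- eigen(R, symmetric = TRUE)
  list(eigenvalues = e$values,
       loadings = stats::setNames(e$vectors[, 1], colnames(z)),
       unidimensional = e$values[1] < dominance_ratio * e$values[2])
}

#' Local independence screening via residual Spearman correlations
#'
#' Spearman correlations between all residual column pairs, optionally also
#' within each category of a covariate. Pairs with `|r|` at or above the flag
#' threshold violate local independence; for each flagged pair the
#' later-indexed item is recommended for removal (configurable rule).
#'
#' @param res an `irt_residuals` object
#' @param flag_threshold absolute correlation at which a pair is flagged
#'   (0.4, the level conventionally called strong).
#' @param groups optional per-respondent category labels for sub-group
#'   correlation tables.
#' @return list with `correlations` (J x J Spearman matrix), `flagged`
#'   (data.frame of flagged pairs), `removal_recommendation` (item indices),
#'   `by_group` (named list of sub-group matrices, if requested).
#' @export
local_independence <- function(res, flag_threshold = 0.4, groups = NULL) {
  z <- res$z
  if (any(apply(z, 2, stats::sd) == 0)) stop("constant residual column")
  R <- stats::cor(z, method = "spearman")
  J <- ncol(z)
  pairs <- which(upper.tri(R) & abs(R) >= flag_threshold, arr.ind = TRUE)
  flagged <- data.frame(item_a = pairs[, 1], item_b = pairs[, 2],
                        label_a = colnames(z)[pairs[, 1]],
                        label_b = colnames(z)[pairs[, 2]],
                        r = R[pairs], row.names = NULL,
                        stringsAsFactors = FALSE)
  removal <- sort(unique(pmax(flagged$item_a, flagged$item_b)))
  by_group <- NULL
  if (!is.null(groups)) {
    by_group <- lapply(split(seq_len(nrow(z)), groups), function(i) {
      stats::cor(z[i, , drop = FALSE], method = "spearman")
    })
  }
  list(correlations = R, flagged = flagged,
       removal_recommendation = removal, by_group = by_group,
       flag_threshold = flag_threshold)
}

#' Full IRT condition report
#'
#' Bundles item fit (infit/outfit against the 0.7--1.3 band), residual PCA
#' unidimensionality screening, and the local-independence correlation screen
#' into one report with a removal recommendation.
#'
#' @param m a [response_matrix()]
#' @param bank fitted `item_bank`
#' @param theta `theta_estimates` (computed from `bank` if NULL)
#' @param flag_threshold local-dependence flag level
#' @param covariate optional covariate name for per-group correlation tables
#' @return object of class `diagnostics_report`
#' @export
irt_diagnostics <- function(m, bank, theta = NULL, flag_threshold = 0.4,
                            covariate = NULL) {
  if (is.null(theta)) theta <- eap_scores(m, bank)
  res <- standardized_residuals(m, bank, theta)
  fit <- infit_outfit(res)
  pca <- residual_pca(res)
  grp <- if (!is.null(covariate)) m$groups[[covariate]]
  li <- local_independence(res, flag_threshold = flag_threshold, groups = grp)
  structure(list(item_fit = fit, residual_pca = pca,
                 local_independence = li,
                 removal_recommendation = li$removal_recommendation),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("IRT condition report\n")
  print(x$item_fit, digits = 3, row.names = FALSE)
  cat(sprintf("residual PCA eigenvalues: %s\n",
              paste(round(x$residual_pca$eigenvalues, 2), collapse = ", ")))
  cat(sprintf("unidimensionality: %s\n",
              if (x$residual_pca$unidimensional) "no dominant residual component"
              else "dominant residual component detected"))
  if (nrow(x$local_independence$flagged)) {
    cat("locally dependent pairs:\n")
    print(x$local_independence$flagged, digits = 3, row.names = FALSE)
    cat("removal recommendation: item(s)",
        paste(x$removal_recommendation, collapse = ", "), "\n")
  } else cat("no locally dependent pairs flagged\n")
  invisible(x)
}
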