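#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = J/(J-1) * (1 - sum(var_j) / var(total))`, computed on the
#' direction-aligned (post-reversal) item codes.
#'
#' @param m a [response_matrix()] or plain numeric matrix.
#' @param items optional subset of item indices.
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(m, items = NULL) {
  Y <- if (inherits(m, "response_matrix")) m$responses else as.matrix(m)
  if (!is.null(items)) Y <- Y[, items, drop = FALSE]
  J <- ncol(Y)
  if (J < 2) stop("alpha needs at least two items")
  vt <- stats::var(rowSums(Y))
  if (vt == 0) stop("zero total-score variance")
  (J / (J - 1)) * (1 - sum(apply(Y, 2, stats::var)) / vt)
}

#' Chi-square comparison of item endorsement across groups
#'
#' Pearson chi-square on each item's yes/no x group contingency table of raw
#' (pre-reversal) counts, without continuity correction by default.
#'
#' @param m a [response_matrix()]
#' @param covariate grouping covariate name.
#' @param correct apply Yates continuity correction (2x2 tables only).
#' @param alpha significance level for the flag.
#' @return data.frame with per-item `chisq`, `p`, `significant`.
#' @export
chi2_endorsement <- function(m, covariate, correct = FALSE, alpha = 0.05) {
  grp <- m$groups[[covariate]]
  if (is.null(grp)) stop(sprintf("covariate '%s' not declared", covariate))
  if (length(unique(grp)) < 2) stop("need at least two groups")
  Y <- raw_responses(m)
  res <- lapply(seq_len(ncol(Y)), function(j) {
    tab <- table(factor(Y[, j], levels = 0:1), grp)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      stop(sprintf("empty contingency margin for item %d", j))
    }
    ch <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    data.frame(item = j, label = m$item_labels[j],
               chisq = unname(ch$statistic), p = ch$p.value,
               significant = ch$p.value < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Multiple correspondence analysis of binary item responses
#'
#' Correspondence analysis of the complete disjunctive (indicator) table:
#' each binary item contributes a "yes" and a "no" category column. Returns
#' eigenvalues (principal inertias), percentages of variance, weighted
#' category loadings (whose squared column sums are the eigenvalues, the
#' representation the varimax-type rotation operates on), category principal
#' coordinates, and per-category and per-item contributions to each
#' dimension. Item-level contributions aggregate an item's two categories.
#'
#' @param m a [response_matrix()] or plain 0/1 matrix.
#' @param n_keep number of dimensions marked as retained (scree-plot choice;
#'   the source analysis retained 4).
#' @param benzecri also report Benzecri-adjusted inertia percentages.
#' @return object of class `mca_result`.
#' @export
mca_fit <- function(m, n_keep = 4, benzecri = FALSE) {
  Y <- if (inherits(m, "response_matrix")) m$responses else as.matrix(m)
  labels <- colnames(Y) %||% paste0("item", seq_len(ncol(Y)))
  n <- nrow(Y); J <- ncol(Y)
  if (n <= 2 * J) stop("need more respondents than twice the item count")
  if (any(colMeans(Y) %in% c(0, 1))) stop("constant item column")
  if (n_keep < 2) stop("n_keep must be at least 2")
  # complete disjunctive table: yes then no category per item
  Z <- cbind(Y, 1 - Y)
  cat_names <- c(paste0(labels, ":yes"), paste0(labels, ":no"))
  cat_item <- rep(seq_len(J), 2)
  ord <- order(cat_item)
  Z <- Z[, ord]; cat_names <- cat_names[ord]; cat_item <- cat_item[ord]
  N <- sum(Z)
  P <- Z / N
  r <- rowSums(P)
  cmass <- colSums(P)
  S <- (P - tcrossprod(r, cmass)) / sqrt(tcrossprod(r, cmass))
  sv <- svd(S)
  keep <- which(sv$d > 1e-10)
  eig <- sv$d[keep]^2
  ndim <- length(eig)
  # weighted loadings B: B[k, s] = sqrt(mass_k) * principal coordinate;
  # colSums(B^2) == eigenvalues, so contributions are B^2 / eigenvalue
  B <- sv$v[, keep, drop = FALSE] %*% diag(sv$d[keep], ndim)
  rownames(B) <- cat_names
  coords <- B / sqrt(cmass)
  contrib_cat <- sweep(B^2, 2, eig, "/")
  contrib_item <- rowsum(contrib_cat, cat_item)
  rownames(contrib_item) <- labels
  total_inertia <- sum(eig)
  pct <- 100 * eig / total_inertia
  adj <- NULL
  if (benzecri) {
    lam <- eig[eig > 1 / J]
    lam_adj <- ((J / (J - 1)) * (lam - 1 / J))^2
    adj <- 100 * lam_adj / sum(lam_adj)
  }
  structure(list(eigenvalues = eig, pct_var = pct, benzecri_pct = adj,
                 loadings = B, coords = coords, cat_mass = cmass,
                 contrib_cat = contrib_cat, contrib_item = contrib_item,
                 category = cat_names, category_item = cat_item,
                 item_labels = labels, total_inertia = total_inertia,
                 n_keep = min(n_keep, ndim), rotated = FALSE),
            class = "mca_result")
}

#' Varimax-type rotation of the retained MCA dimensions
#'
#' Orthogonal rotation of the retained block of weighted category loadings
#' maximising the varimax squared-loading-variance criterion (the rotation
#' principle proposed for multiple correspondence analysis). The rotated
#' dimensions' variances (squared loading column sums) are recomputed and
#' reordered descending; their total equals the unrotated retained total, and
#' contributions are recomputed against the rotated variances.
#'
#' @param res an `mca_result` with at least 2 retained dimensions.
#' @return an `mca_result` with `rotated = TRUE` and the rotation matrix in
#'   `$rotation`.
#' @export
rotate_mca <- function(res) {
  k <- res$n_keep
  if (k < 2) stop("rotation needs at least two retained dimensions")
  Bk <- res$loadings[, seq_len(k), drop = FALSE]
  rot <- stats::varimax(Bk, normalize = FALSE, eps = 1e-10)
  Br <- Bk %*% rot$rotmat
  vr <- colSums(Br^2)
  ord <- order(vr, decreasing = TRUE)
  Br <- Br[, ord, drop = FALSE]
  vr <- vr[ord]
  res$loadings[, seq_len(k)] <- Br
  res$eigenvalues[seq_len(k)] <- vr
  res$pct_var[seq_len(k)] <- 100 * vr / res$total_inertia
  res$coords <- res$loadings / sqrt(res$cat_mass)
  res$contrib_cat[, seq_len(k)] <- sweep(Br^2, 2, vr, "/")
  res$contrib_item <- rowsum(res$contrib_cat, res$category_item)
  rownames(res$contrib_item) <- res$item_labels
  res$rotated <- TRUE
  res$rotation <- rot$rotmat[, ord, drop = FALSE]
  res
}

#' Item-contribution table for retained MCA dimensions
#'
#' Per-item contributions (an item's two categories summed) to each retained
#' dimension, with a display version that blanks entries below the threshold
#' while the full values stay available machine-readably.
#'
#' @param res an `mca_result` (rotated or not).
#' @param display_threshold contributions below this are blanked in the
#'   display matrix (0.2, the conventional reporting cut).
#' @return list with `values` (numeric item x dimension matrix, columns
#'   summing to 1 over all items), `display` (character matrix with
#'   sub-threshold entries blank), `pct_var` of the retained dimensions.
#' @export
contribution_table <- function(res, display_threshold = 0.2) {
  k <- res$n_keep
  vals <- res$contrib_item[, seq_len(k), drop = FALSE]
  colnames(vals) <- paste0("dim", seq_len(k))
  disp <- matrix("", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  show <- vals >= display_threshold
  disp[show] <- sprintf("%.3f", vals[show])
  list(values = vals, display = disp, pct_var = res$pct_var[seq_len(k)],
       display_threshold = display_threshold)
}
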