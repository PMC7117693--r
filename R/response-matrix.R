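#' Construct a respondent-by-item response matrix
#'
#' The single input container of the analysis pipeline: an `n x J` matrix of
#' binary item codes (1 = "yes" as the question was asked), one or more
#' grouping covariates (area, gender, age band, ...), and a record of which
#' items have been direction-reversed so that descriptive tables can always be
#' produced on the raw coding while model-based analyses use the aligned one.
#'
#' @param responses numeric/integer matrix or data.frame of 0/1 codes, one
#'   column per item. No missing values are allowed; complete-case filtering
#'   belongs to [load_responses()].
#' @param groups named list (or data.frame) of per-respondent category labels,
#'   one element per covariate; each must have one value per row of
#'   `responses`.
#' @param item_labels character vector of item names; defaults to column names.
#' @param respondent_id optional identifiers; defaults to row numbers.
#' @param reversed_items integer indices of items already direction-flipped.
#' @return an object of class `response_matrix`.
#' @seealso [load_responses()], [reverse_items()], [epices_score()]
#' @export
response_matrix <- function(responses, groups = list(), item_labels = NULL,
                            respondent_id = NULL, reversed_items = integer()) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (anyNA(responses)) {
    stop("response codes contain missing values; apply complete-case filtering first")
  }
  if (!all(responses %in% c(0L, 1L))) {
    stop("all response codes must be 0 or 1")
  }
  n <- nrow(responses)
  J <- ncol(responses)
  if (is.null(item_labels)) {
    item_labels <- colnames(responses) %||% paste0("item", seq_len(J))
  }
  if (length(item_labels) != J) stop("item_labels must have one entry per item column")
  colnames(responses) <- item_labels
  if (is.null(respondent_id)) respondent_id <- as.character(seq_len(n))
  groups <- as.list(groups)
  for (g in names(groups)) {
    groups[[g]] <- as.character(groups[[g]])
    if (length(groups[[g]]) != n) {
      stop(sprintf("covariate '%s' must have one label per respondent", g))
    }
    if (anyNA(groups[[g]])) stop(sprintf("covariate '%s' has missing labels", g))
  }
  reversed_items <- sort(unique(as.integer(reversed_items)))
  if (length(reversed_items) && (min(reversed_items) < 1L || max(reversed_items) > J)) {
    stop("reversed_items out of range")
  }
  structure(
    list(responses = responses, item_labels = item_labels, groups = groups,
         respondent_id = as.character(respondent_id),
         reversed_items = reversed_items),
    class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d respondents x %d items\n",
              nrow(x$responses), ncol(x$responses)))
  if (length(x$groups)) {
    cat("covariates:", paste(names(x$groups), collapse = ", "), "\n")
  }
  if (length(x$reversed_items)) {
    cat("reversed items:", paste(x$reversed_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Number of respondents / items
#' @param m a `response_matrix`
#' @return integer
#' @export
n_respondents <- function(m) nrow(m$responses)

#' @rdname n_respondents
#' @export
n_items <- function(m) ncol(m$responses)

#' Subset a response matrix
#'
#' @param m a `response_matrix`
#' @param respondents logical/integer selector of rows (default all)
#' @param items integer selector of item columns (default all)
#' @return a `response_matrix` with reversal bookkeeping remapped to the kept
#'   items.
#' @export
subset_responses <- function(m, respondents = NULL, items = NULL) {
  if (is.null(respondents)) respondents <- seq_len(n_respondents(m))
  if (is.null(items)) items <- seq_len(n_items(m))
  items <- as.integer(items)
  rev_kept <- match(intersect(m$reversed_items, items), items)
  response_matrix(m$responses[respondents, items, drop = FALSE],
                  groups = lapply(m$groups, function(g) g[respondents]),
                  item_labels = m$item_labels[items],
                  respondent_id = m$respondent_id[respondents],
                  reversed_items = rev_kept)
}

#' Read a response table from CSV
#'
#' Items are parsed from `0/1/yes/no` codes (case-insensitive). Rows with any
#' missing or blank item answer are dropped (complete-case rule) and the count
#' of dropped rows is reported; a cell that parses as none of the accepted
#' codes is an error naming its row and column.
#'
#' @param path CSV file with a header row; one column per item plus one column
#'   per covariate.
#' @param covariates names of the grouping columns.
#' @param id_column optional name of a respondent-identifier column.
#' @param verbose report the number of incomplete rows dropped.
#' @return a `response_matrix`
#' @export
load_responses <- function(path, covariates = character(), id_column = NULL,
                           verbose = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  item_cols <- setdiff(names(raw), c(covariates, id_column))
  if (!all(covariates %in% names(raw))) {
    stop(sprintf("covariate column(s) missing: %s",
                 paste(setdiff(covariates, names(raw)), collapse = ", ")))
  }
  if (!length(item_cols)) stop("no item columns found")
  parse_item <- function(x, col) {
    v <- tolower(trimws(x))
    out <- rep(NA_integer_, length(v))
    out[v %in% c("1", "yes")] <- 1L
    out[v %in% c("0", "no")] <- 0L
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(sprintf("unparseable response '%s' at row %d, column '%s'",
                   x[bad[1]], bad[1], col))
    }
    out
  }
  Y <- vapply(item_cols, function(cl) parse_item(raw[[cl]], cl),
              integer(nrow(raw)))
  Y <- matrix(Y, nrow = nrow(raw), dimnames = list(NULL, item_cols))
  complete <- stats::complete.cases(Y)
  n_drop <- sum(!complete)
  if (!any(complete)) stop("no complete rows after filtering")
  if (n_drop > 0) {
    msg(sprintf("dropped %d incomplete row(s); %d complete respondents kept",
                n_drop, sum(complete)), verbose = verbose)
  }
  ids <- if (!is.null(id_column)) raw[[id_column]][complete] else NULL
  response_matrix(Y[complete, , drop = FALSE],
                  groups = lapply(stats::setNames(covariates, covariates),
                                  function(cl) raw[[cl]][complete]),
                  respondent_id = ids)
}

#' Write a response table to CSV
#'
#' Inverse of [load_responses()]: loading the written file reproduces the
#' matrix (current coding; reversal state is not serialized).
#'
#' @param m a `response_matrix`
#' @param path output CSV path
#' @export
write_responses <- function(m, path) {
  df <- as.data.frame(m$responses)
  for (g in names(m$groups)) df[[g]] <- m$groups[[g]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reverse the coding direction of selected items
#'
#' Flips codes `x -> 1 - x` for the listed items and updates the reversal
#' record by symmetric difference, so applying the same reversal twice is the
#' identity. For the EPICES questionnaire, items 1 and 5 are reversed before
#' any model-based analysis so that code 0 denotes the higher-precariousness
#' answer on every item (descriptive tables keep the raw coding).
#'
#' @param m a `response_matrix`
#' @param items integer item indices to flip
#' @return a `response_matrix`
#' @export
reverse_items <- function(m, items) {
  items <- as.integer(items)
  if (length(items) && (min(items) < 1L || max(items) > n_items(m))) {
    stop("item index out of range")
  }
  m$responses[, items] <- 1L - m$responses[, items]
  # symmetric difference: reversing twice restores the original state
  m$reversed_items <- sort(union(setdiff(m$reversed_items, items),
                                 setdiff(items, m$reversed_items)))
  m
}

#' Recover the raw ("as asked") coding of a response matrix
#' @param m a `response_matrix`
#' @return integer matrix with all reversals undone
#' @export
raw_responses <- function(m) {
  Y <- m$responses
  if (length(m$reversed_items)) {
    Y[, m$reversed_items] <- 1L - Y[, m$reversed_items]
  }
  Y
}

#' Scoring configuration for a weighted questionnaire sum score
#'
#' Holds per-item weights, the direction of the "precarious" answer on the raw
#' coding, an additive constant and the categorisation cut-offs. The published
#' EPICES weights belong to the original 2006 validation paper and are not
#' reproduced here; [epices_unit_config()] provides a clearly-labelled
#' placeholder preset with equal weights summing to 100.
#'
#' @param weights numeric vector, one weight per item.
#' @param precarious_answer character vector of "yes"/"no": which raw answer
#'   scores the weight.
#' @param constant additive constant.
#' @param cutoffs score thresholds for dichotomisation (EPICES: 30.17, 48.5).
#' @param range declared attainable score range, checked at scoring time.
#' @return an object of class `score_config`
#' @export
score_config <- function(weights, precarious_answer, constant = 0,
                         cutoffs = c(30.17, 48.5), range = c(0, 100)) {
  weights <- as.numeric(weights)
  precarious_answer <- match.arg(precarious_answer, c("yes", "no"),
                                 several.ok = TRUE)
  if (length(precarious_answer) != length(weights)) {
    stop("one precarious_answer direction needed per weight")
  }
  structure(list(weights = weights, precarious_answer = precarious_answer,
                 constant = constant, cutoffs = sort(cutoffs), range = range),
            class = "score_config")
}

#' Placeholder unit-weight EPICES scoring preset
#'
#' Equal weights of 100/J per item (J = 11 by default), zero constant, range
#' 0--100, cut-offs 30.17 and 48.5. On the raw coding the precarious answer is
#' "yes" for items 1 and 5 and "no" elsewhere. This is a placeholder for the
#' proprietary published weights, which users should supply via
#' [score_config_from_yaml()].
#'
#' @param n_items number of items (11 for the full questionnaire).
#' @return a `score_config`
#' @export
epices_unit_config <- function(n_items = 11) {
  dir <- rep("no", n_items)
  dir[intersect(c(1L, 5L), seq_len(n_items))] <- "yes"
  score_config(weights = rep(100 / n_items, n_items), precarious_answer = dir)
}

#' Read / write a scoring configuration as YAML
#' @param path YAML file
#' @return a `score_config`
#' @export
score_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  score_config(weights = y$weights, precarious_answer = y$precarious_answer,
               constant = y$constant %||% 0,
               cutoffs = unlist(y$cutoffs) %||% c(30.17, 48.5),
               range = unlist(y$range) %||% c(0, 100))
}

#' @rdname score_config_from_yaml
#' @param cfg a `score_config`
#' @export
score_config_to_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Compute the weighted deprivation sum score and its dichotomisations
#'
#' `score = constant + sum_j weight_j * I(precarious answer on item j)`,
#' evaluated on the raw coding (reversal state is undone internally, so the
#' score is invariant to the matrix's reversal bookkeeping). EPICES runs from 0
#' (no precariousness) to 100 (extreme precariousness). One indicator column
#' `score > cutoff` is returned per configured cut-off; because the cut-offs
#' are ordered, the higher indicator always implies the lower one.
#'
#' @param m a `response_matrix`
#' @param cfg a `score_config`; defaults to the unit-weight preset.
#' @return data.frame with `respondent_id`, `score`, and one logical column
#'   per cutoff (named `above_<cutoff>`).
#' @export
epices_score <- function(m, cfg = epices_unit_config(n_items(m))) {
  J <- n_items(m)
  if (length(cfg$weights) != J) {
    stop(sprintf("score_config has %d weights but matrix has %d items",
                 length(cfg$weights), J))
  }
  Y <- raw_responses(m)
  prec <- Y
  flip <- cfg$precarious_answer == "no"
  prec[, flip] <- 1L - prec[, flip]
  score <- cfg$constant + as.numeric(prec %*% cfg$weights)
  if (min(score) < cfg$range[1] - 1e-9 || max(score) > cfg$range[2] + 1e-9) {
    stop("computed scores fall outside the declared range; check weights")
  }
  out <- data.frame(respondent_id = m$respondent_id, score = score,
                    stringsAsFactors = FALSE)
  for (ct in cfg$cutoffs) out[[paste0("above_", ct)]] <- score > ct
  out
}

#' Descriptive endorsement table (raw coding)
#'
#' Percentage of "yes" answers per item, for the whole sample and for every
#' category of every declared covariate, computed on the raw (pre-reversal)
#' coding, with a chi-square significance flag per covariate at alpha = 0.05.
#'
#' @param m a `response_matrix`
#' @param alpha significance level for the chi-square subgroup comparison.
#' @param correct apply Yates continuity correction (default off).
#' @return data.frame, one row per item.
#' @export
endorsement_table <- function(m, alpha = 0.05, correct = FALSE) {
  Y <- raw_responses(m)
  out <- data.frame(item = seq_len(ncol(Y)), label = m$item_labels,
                    stringsAsFactors = FALSE)
  for (g in names(m$groups)) {
    for (lev in sort(unique(m$groups[[g]]))) {
      out[[paste0(g, ":", lev)]] <-
        round(100 * colMeans(Y[m$groups[[g]] == lev, , drop = FALSE]), 1)
    }
  }
  out[["whole_sample"]] <- round(100 * colMeans(Y), 1)
  for (g in names(m$groups)) {
    chi <- chi2_endorsement(m, g, correct = correct, alpha = alpha)
    out[[paste0("sig_", g)]] <- chi$significant
  }
  out
}

#' Attach a covariate to a response matrix
#'
#' @param m a `response_matrix`
#' @param name covariate name
#' @param labels per-respondent category labels
#' @return the updated `response_matrix`
#' @export
add_covariate <- function(m, name, labels) {
  labels <- as.character(labels)
  if (length(labels) != n_respondents(m)) {
    stop(sprintf("covariate '%s' must have one label per respondent", name))
  }
  if (anyNA(labels)) stop(sprintf("covariate '%s' has missing labels", name))
  m$groups[[name]] <- labels
  m
}
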