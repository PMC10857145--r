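#' Criterion specification for multi-criteria ranking
#'
#' @param name Criterion name (e.g. `"nutrition"`, `"taste"`, `"cost"`,
#'   `"convenience"`).
#' @param direction `"benefit"` if larger raw values are better, `"cost"`
#'   if smaller are better.
#' @param weight Non-negative relative weight; weights are normalized to
#'   sum to one inside [topsis_score()].
#' @return A list of class `criterion_spec`.
#' @export
criterion_spec <- function(name, direction = c("benefit", "cost"), weight = 1) {
  direction <- match.arg(direction)
  if (!is.numeric(weight) || weight < 0 || !is.finite(weight)) {
    stop_mealrl("`weight` must be a finite non-negative number")
  }
  structure(list(name = name, direction = direction, weight = weight),
            class = "criterion_spec")
}

# Saaty's random consistency index for matrix orders 1..9.
AHP_RANDOM_INDEX <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

#' Criterion weights from a pairwise comparison matrix (AHP)
#'
#' Derives criterion weights as the normalized principal eigenvector of a
#' positive reciprocal pairwise comparison matrix, computed by power
#' iteration, together with Saaty's consistency ratio (CR). Entry
#' `a[p, q]` states how many times more important criterion `p` is than
#' criterion `q`; the matrix must satisfy `a[q, p] = 1 / a[p, q]`.
#'
#' @param pairwise Square positive reciprocal matrix, order 2 to 9.
#' @param strict If `TRUE`, a consistency ratio above 0.1 is an error;
#'   otherwise a warning.
#' @param tol Power-iteration convergence tolerance.
#' @return List with `weights` (sums to 1), `lambda_max`, `ci` and `cr`.
#' @examples
#' ahp_weights(matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3, byrow = TRUE))
#' @export
ahp_weights <- function(pairwise, strict = FALSE, tol = 1e-10) {
  A <- as.matrix(pairwise)
  n <- nrow(A)
  if (n != ncol(A)) stop_mealrl("pairwise matrix must be square")
  if (n < 2 || n > 9) stop_mealrl("pairwise matrix order must be between 2 and 9")
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop_mealrl("pairwise matrix entries must be positive and finite")
  }
  if (max(abs(diag(A) - 1)) > 1e-9 || max(abs(A * t(A) - 1)) > 1e-9) {
    stop_mealrl("pairwise matrix must be reciprocal (a[q,p] = 1/a[p,q], unit diagonal)")
  }
  w <- rep(1 / n, n)
  for (iter in seq_len(1000L)) {
    w_new <- as.numeric(A %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  lambda_max <- mean((A %*% w) / w)
  ci <- (lambda_max - n) / (n - 1)
  cr <- if (n <= 2) 0 else ci / AHP_RANDOM_INDEX[n]
  # tiny negative CI from round-off on perfectly consistent matrices
  if (abs(cr) < 1e-12) cr <- abs(cr)
  if (cr > 0.1) {
    msg <- sprintf("pairwise comparisons are inconsistent (CR = %.3f > 0.1)", cr)
    if (strict) stop_mealrl(msg) else warning(msg, call. = FALSE)
  }
  list(weights = w, lambda_max = lambda_max, ci = ci, cr = cr)
}

#' Vector-normalize a decision matrix
#'
#' Divides each criterion column of the raw decision matrix by its
#' Euclidean norm, so that every criterion contributes on a comparable
#' scale regardless of units.
#'
#' @param A Numeric matrix, m alternatives by n criteria, non-negative.
#' @return Matrix of the same shape with unit-Euclidean-norm columns
#'   (all-zero columns are returned unchanged; [topsis_score()] drops them).
#' @export
topsis_normalize <- function(A) {
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop_mealrl("decision matrix must be finite")
  if (any(A < 0)) stop_mealrl("decision matrix must be non-negative")
  norms <- sqrt(colSums(A^2))
  scale_by <- ifelse(norms > 0, norms, 1)
  sweep(A, 2L, scale_by, "/")
}

#' TOPSIS closeness scores and ranking
#'
#' Ranks alternatives by relative closeness to the ideal solution:
#' the raw matrix is vector-normalized, weighted, the positive ideal
#' (best observed value per criterion, respecting benefit/cost direction)
#' and negative ideal are formed, and each alternative is scored
#' \eqn{S_i = d_{iw} / (d_{iw} + d_{ib})} from its Euclidean distances to
#' the worst (`d_iw`) and best (`d_ib`) ideals. Higher is better.
#'
#' @param A Raw decision matrix (m alternatives x n criteria),
#'   non-negative.
#' @param criteria List of [criterion_spec()] (length n), or a numeric
#'   weight vector (all criteria then treated as benefit).
#' @return List with `scores` (length m, in `[0, 1]`), `ranking`
#'   (alternative indices, best first, ties kept in input order), and the
#'   intermediate `weighted` matrix, `ideal_best`, `ideal_worst`.
#' @details Alternatives identical to every other (so that
#'   `d_iw + d_ib = 0`) score 0.5, the indifference point. All-zero
#'   criterion columns are dropped with a warning and the remaining
#'   weights renormalized.
#' @export
topsis_score <- function(A, criteria) {
  A <- as.matrix(A)
  if (is.numeric(criteria)) {
    criteria <- lapply(seq_along(criteria), function(j) {
      criterion_spec(paste0("c", j), "benefit", criteria[[j]])
    })
  }
  if (length(criteria) != ncol(A)) {
    stop_mealrl("need one criterion spec per decision-matrix column")
  }
  w <- vapply(criteria, `[[`, numeric(1), "weight")
  dirs <- vapply(criteria, `[[`, character(1), "direction")
  if (sum(w) <= 0) stop_mealrl("criterion weights must not all be zero")

  zero_cols <- colSums(as.matrix(A)^2) == 0
  if (any(zero_cols)) {
    warning(sprintf("dropping %d all-zero criterion column(s); weights renormalized",
                    sum(zero_cols)), call. = FALSE)
    A <- A[, !zero_cols, drop = FALSE]
    w <- w[!zero_cols]
    dirs <- dirs[!zero_cols]
    if (ncol(A) == 0L) {
      m <- nrow(A)
      return(list(scores = rep(0.5, m), ranking = seq_len(m),
                  weighted = A, ideal_best = numeric(0), ideal_worst = numeric(0)))
    }
  }
  w <- w / sum(w)

  Tm <- sweep(topsis_normalize(A), 2L, w, "*")
  benefit <- dirs == "benefit"
  ideal_best <- ifelse(benefit, apply(Tm, 2L, max), apply(Tm, 2L, min))
  ideal_worst <- ifelse(benefit, apply(Tm, 2L, min), apply(Tm, 2L, max))
  d_ib <- sqrt(rowSums(sweep(Tm, 2L, ideal_best)^2))
  d_iw <- sqrt(rowSums(sweep(Tm, 2L, ideal_worst)^2))
  denom <- d_iw + d_ib
  scores <- ifelse(denom > 0, d_iw / denom, 0.5)
  ranking <- order(-scores)  # stable: ties keep input order
  list(scores = scores, ranking = ranking, weighted = Tm,
       ideal_best = ideal_best, ideal_worst = ideal_worst)
}

#' Per-meal preference score over a candidate set
#'
#' Builds the decision matrix for a candidate meal set from named
#' criterion extractor functions, derives weights (directly, or from an
#' AHP pairwise matrix in the profile), and returns each meal's TOPSIS
#' closeness score as its preference score `p` in `[0, 1]`.
#'
#' @param catalogue Candidate meal tibble (see [read_meal_catalogue()]).
#' @param profile User profile; `criteria_prefs` may hold either
#'   `weights` (named numeric) or `pairwise` (matrix for [ahp_weights()]),
#'   plus optional `directions`.
#' @param extractors Named list of functions, each mapping the catalogue to
#'   a non-negative numeric vector of raw criterion values. Defaults cover
#'   nutrition (PV), cost and convenience (from attribute columns when
#'   present). A `taste` extractor is typically supplied from CF
#'   predictions.
#' @return Numeric vector of preference scores, one per catalogue row.
#' @export
preference_score <- function(catalogue, profile = NULL, extractors = NULL) {
  if (nrow(catalogue) == 0L) stop_mealrl("empty candidate set")
  extractors <- extractors %||% default_criterion_extractors(profile)
  if (nrow(catalogue) == 1L) {
    message("single-candidate set: preference score is 1 by convention")
    return(1)
  }
  A <- sapply(extractors, function(f) as.numeric(f(catalogue)))
  A <- matrix(A, nrow = nrow(catalogue),
              dimnames = list(NULL, names(extractors)))
  criteria <- resolve_criteria(names(extractors), profile)
  topsis_score(A, criteria)$scores
}

default_criterion_extractors <- function(profile = NULL) {
  ex <- list(
    nutrition = function(cat) catalogue_pv(cat, profile)
  )
  ex$cost <- function(cat) {
    if ("cost" %in% names(cat)) as.numeric(cat$cost) else rep(1, nrow(cat))
  }
  ex$convenience <- function(cat) {
    if ("prep_minutes" %in% names(cat)) as.numeric(cat$prep_minutes) else rep(1, nrow(cat))
  }
  ex
}

# Turn a profile's criteria_prefs into criterion_spec list for given names.
resolve_criteria <- function(crit_names, profile = NULL) {
  prefs <- profile$criteria_prefs
  cost_like <- c("cost", "convenience", "prep_minutes", "price")
  dirs <- setNames(ifelse(crit_names %in% cost_like, "cost", "benefit"), crit_names)
  if (!is.null(prefs$directions)) {
    dirs[names(prefs$directions)] <- unlist(prefs$directions)
  }
  w <- setNames(rep(1, length(crit_names)), crit_names)
  if (!is.null(prefs$pairwise)) {
    pw <- as.matrix(prefs$pairwise)
    if (nrow(pw) != length(crit_names)) {
      stop_mealrl("AHP pairwise matrix order must match the number of criteria")
    }
    w[] <- ahp_weights(pw)$weights
  } else if (!is.null(prefs$weights)) {
    got <- intersect(names(prefs$weights), crit_names)
    w[got] <- unlist(prefs$weights)[got]
  }
  lapply(crit_names, function(nm) criterion_spec(nm, dirs[[nm]], w[[nm]]))
}
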