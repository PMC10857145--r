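#' Read a meal catalogue
#'
#' Reads a meal table from CSV or JSON. Required columns: `meal_id`,
#' `name`, `meal_type` (one of breakfast/lunch/dinner) and the seven
#' nutrient columns of [nutrient_names()]. Extra columns (e.g. `cost`,
#' `prep_minutes`, `contains_gluten`) are kept as attribute columns.
#' Rows with non-numeric or negative nutrient values are skipped with a
#' warning; a missing required column is a hard error.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A tibble with one row per valid meal and an attribute
#'   `n_skipped` counting dropped rows.
#' @export
read_meal_catalogue <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop_mealrl("no such file: ", path)
  raw <- if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  required <- c("meal_id", "name", "meal_type", nutrient_names())
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop_mealrl("catalogue is missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  validate_catalogue(raw)
}

validate_catalogue <- function(raw) {
  nut <- nutrient_names()
  vals <- lapply(raw[nut], function(x) suppressWarnings(as.numeric(x)))
  bad_num <- Reduce(`|`, lapply(vals, function(x) is.na(x) | x < 0 | !is.finite(x)))
  bad_type <- !(raw$meal_type %in% c("breakfast", "lunch", "dinner"))
  bad <- bad_num | bad_type
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d malformed catalogue row(s)", n_skipped),
            call. = FALSE)
  }
  out <- raw[!bad, , drop = FALSE]
  for (nm in nut) out[[nm]] <- as.numeric(out[[nm]])
  out$meal_id <- as.character(out$meal_id)
  if (anyDuplicated(out$meal_id)) stop_mealrl("duplicate meal_id in catalogue")
  fib_high <- out$fiber_g > out$carbohydrate_g
  if (any(fib_high)) {
    message(sprintf("note: %d meal(s) report fiber above total carbohydrate",
                    sum(fib_high)))
  }
  out <- tibble::as_tibble(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a meal catalogue to CSV
#'
#' Inverse of [read_meal_catalogue()]; round-trips exactly.
#'
#' @param catalogue Meal tibble.
#' @param path Output CSV path.
#' @export
write_meal_catalogue <- function(catalogue, path) {
  readr::write_csv(catalogue, path, progress = FALSE)
  invisible(path)
}

#' Read user-meal rating interactions
#'
#' Reads a CSV with columns `user_id`, `meal_id`, `rating` and optional
#' `timestamp`. Ratings are coerced to integers; rows whose rating is not
#' in 1..5 are rejected with a warning. Duplicate (user, meal) pairs keep
#' only the latest timestamp: the most recent rating is taken as the
#' user's current opinion.
#'
#' @param path CSV path.
#' @param dedup Deduplicate (user, meal) pairs keeping the latest
#'   timestamp (default `TRUE`).
#' @return Tibble of interactions with attribute `n_rejected`.
#' @export
read_interactions <- function(path, dedup = TRUE) {
  if (!file.exists(path)) stop_mealrl("no such file: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("user_id", "meal_id", "rating")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop_mealrl("interactions are missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  if (!"timestamp" %in% names(raw)) raw$timestamp <- seq_len(nrow(raw))
  r <- suppressWarnings(as.numeric(raw$rating))
  bad <- is.na(r) | r < 1 | r > 5 | r != round(r)
  if (any(bad)) {
    warning(sprintf("rejected %d interaction(s) with out-of-range rating",
                    sum(bad)), call. = FALSE)
  }
  out <- raw[!bad, , drop = FALSE]
  out$rating <- as.integer(round(as.numeric(out$rating)))
  out$user_id <- as.character(out$user_id)
  out$meal_id <- as.character(out$meal_id)
  if (dedup) out <- dedup_interactions(out)
  out <- tibble::as_tibble(out)
  attr(out, "n_rejected") <- sum(bad)
  out
}

# Keep the latest rating per (user, meal) pair, by timestamp then row order.
dedup_interactions <- function(interactions) {
  ord <- order(interactions$timestamp, seq_len(nrow(interactions)))
  x <- interactions[ord, , drop = FALSE]
  keep <- !duplicated(x[c("user_id", "meal_id")], fromLast = TRUE)
  out <- x[keep, , drop = FALSE]
  out[order(match(paste(out$user_id, out$meal_id),
                  paste(interactions$user_id, interactions$meal_id))), ,
      drop = FALSE]
}

#' Write interactions to CSV
#' @param interactions Interaction tibble.
#' @param path Output CSV path.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_csv(interactions, path, progress = FALSE)
  invisible(path)
}

#' Keep only meals rated by enough distinct users
#'
#' Drops meals with fewer than `min_raters` *distinct* raters (repeat
#' ratings by the same user count once), together with their
#' interactions. Mirrors the common preprocessing rule of requiring at
#' least 10 feedback interactions from distinct users per recipe.
#'
#' @param interactions Interaction tibble.
#' @param catalogue Meal tibble.
#' @param min_raters Minimum number of distinct raters (default 10).
#' @return List with filtered `interactions` and `catalogue`.
#' @export
filter_min_distinct_raters <- function(interactions, catalogue, min_raters = 10) {
  if (min_raters < 1) stop_mealrl("`min_raters` must be >= 1")
  counts <- tapply(interactions$user_id, interactions$meal_id,
                   function(u) length(unique(u)))
  keep_ids <- names(counts)[counts >= min_raters]
  cat_out <- catalogue[catalogue$meal_id %in% keep_ids, , drop = FALSE]
  int_out <- interactions[interactions$meal_id %in% keep_ids, , drop = FALSE]
  message(sprintf("kept %d/%d meals with >= %d distinct raters",
                  nrow(cat_out), nrow(catalogue), min_raters))
  list(interactions = int_out, catalogue = cat_out)
}

#' Random train/test split of interactions
#'
#' Uniform per-interaction split: each interaction lands in the training
#' set independently of its user. Disjoint, exhaustive and reproducible
#' for a fixed seed.
#'
#' @param interactions Interaction tibble.
#' @param train_frac Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_interactions <- function(interactions, train_frac = 0.7, seed = 1) {
  if (!(train_frac > 0 && train_frac < 1)) {
    stop_mealrl("`train_frac` must be in (0, 1)")
  }
  n <- nrow(interactions)
  n_train <- round(n * train_frac)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = interactions[sort(idx), , drop = FALSE],
       test = interactions[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' User profile constructor
#'
#' @param user_id Identifier.
#' @param demographics Named list (age, sex, weight_kg, height_cm, ...).
#' @param hard_constraints Character vector of constraint tags; each must
#'   name an entry of the constraint registry (see
#'   [hard_constraint_registry()]).
#' @param nutrient_targets Named list overriding [default_membership_specs()]
#'   entries, each a `membership_spec` or length-4 numeric `(a, b, c, d)`.
#' @param criteria_prefs List with either `weights` (named numeric) or
#'   `pairwise` (AHP comparison matrix), plus optional `directions`.
#' @return Object of class `user_profile`.
#' @export
user_profile <- function(user_id, demographics = list(),
                         hard_constraints = character(),
                         nutrient_targets = list(),
                         criteria_prefs = list()) {
  known <- names(hard_constraint_registry())
  unknown <- setdiff(hard_constraints, known)
  if (length(unknown) > 0L) {
    stop_mealrl("unknown hard constraint(s): ", paste(unknown, collapse = ", "),
                "; known tags: ", paste(known, collapse = ", "))
  }
  structure(
    list(user_id = as.character(user_id), demographics = demographics,
         hard_constraints = hard_constraints,
         nutrient_targets = nutrient_targets,
         criteria_prefs = criteria_prefs),
    class = "user_profile"
  )
}

#' Read a user profile from JSON
#' @param path JSON file path.
#' @return A [user_profile()].
#' @export
read_user_profile <- function(path) {
  if (!file.exists(path)) stop_mealrl("no such file: ", path)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  pw <- x$criteria_prefs$pairwise
  if (!is.null(pw) && !is.matrix(pw)) {
    x$criteria_prefs$pairwise <- do.call(rbind, lapply(pw, unlist))
  }
  user_profile(
    user_id = x$user_id %||% "anonymous",
    demographics = x$demographics %||% list(),
    hard_constraints = unlist(x$hard_constraints) %||% character(),
    nutrient_targets = x$nutrient_targets %||% list(),
    criteria_prefs = x$criteria_prefs %||% list()
  )
}

#' Registry of hard dietary constraints
#'
#' Named predicates over catalogue rows. Numeric cut-offs are package
#' configuration, documented here: `low_sodium` means at most 600 mg
#' sodium per meal, `low_sugar` at most 15 g sugar, `low_calorie` at most
#' 500 kcal. `gluten_free` requires a `contains_gluten` attribute column
#' and keeps meals where it is false or absent (`NA`).
#'
#' @return Named list of predicate functions `catalogue -> logical`.
#' @export
hard_constraint_registry <- function() {
  list(
    gluten_free = function(cat) {
      if (!"contains_gluten" %in% names(cat)) return(rep(TRUE, nrow(cat)))
      g <- cat$contains_gluten
      is.na(g) | !(g %in% c(TRUE, "true", "TRUE", 1))
    },
    vegetarian = function(cat) {
      if (!"vegetarian" %in% names(cat)) return(rep(TRUE, nrow(cat)))
      cat$vegetarian %in% c(TRUE, "true", "TRUE", 1)
    },
    low_sodium = function(cat) cat$sodium_mg <= 600,
    low_sugar = function(cat) cat$sugar_g <= 15,
    low_calorie = function(cat) cat$calories <= 500
  )
}

#' Filter a catalogue by a user's hard constraints
#'
#' Keeps only meals passing every constraint tag in the profile; row
#' order is preserved. Unknown tags are an error listing the known tags.
#'
#' @param catalogue Meal tibble.
#' @param profile A [user_profile()] (or a character vector of tags).
#' @return Filtered tibble.
#' @export
apply_hard_constraints <- function(catalogue, profile) {
  tags <- if (is.character(profile)) profile else profile$hard_constraints
  registry <- hard_constraint_registry()
  unknown <- setdiff(tags, names(registry))
  if (length(unknown) > 0L) {
    stop_mealrl("unknown hard constraint(s): ", paste(unknown, collapse = ", "),
                "; known tags: ", paste(names(registry), collapse = ", "))
  }
  keep <- rep(TRUE, nrow(catalogue))
  for (tag in tags) keep <- keep & registry[[tag]](catalogue)
  catalogue[keep, , drop = FALSE]
}
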