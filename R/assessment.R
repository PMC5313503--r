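# ---------------------------------------------------------------------------
# Scoring and qualitative "beyond the score" assessment: a respondent's
# clinical state is the set of endorsed items together with the attribute
# profile they imply (the union of the endorsed items' intents).
# ---------------------------------------------------------------------------

#' Construct a response pattern
#'
#' @param endorsed vector of item ids answered affirmatively.
#' @param subject_id optional subject identifier.
#' @param group optional group label, `"clinical"` or `"nonclinical"`.
#' @return An object of class `response_pattern`.
#' @export
response_pattern <- function(endorsed, subject_id = NA_character_, group = NA_character_) {
  if (anyDuplicated(endorsed)) endorsed <- unique(endorsed)
  if (!is.na(group) && !group %in% c("clinical", "nonclinical")) {
    stop_input("group must be 'clinical' or 'nonclinical'")
  }
  structure(
    list(subject_id = as.character(subject_id),
         endorsed = sort(as.integer(endorsed)), group = group),
    class = "response_pattern"
  )
}

#' @export
print.response_pattern <- function(x, ...) {
  cat("Response pattern", if (!is.na(x$subject_id)) paste0("[", x$subject_id, "]"),
      "-", length(x$endorsed), "items endorsed\n")
  invisible(x)
}

.as_pattern <- function(pattern) {
  if (inherits(pattern, "response_pattern")) pattern else response_pattern(pattern)
}

#' Total questionnaire score
#'
#' The score is simply the number of items answered affirmatively (0..41 for
#' the built-in instrument).
#'
#' @param pattern a `response_pattern` or a vector of endorsed item ids.
#' @param ctx the `clinical_context` the pattern refers to.
#' @return Integer count of endorsed items.
#' @export
score <- function(pattern, ctx = queds_context()) {
  pattern <- .as_pattern(pattern)
  .item_index(ctx, pattern$endorsed)  # validates ids
  length(pattern$endorsed)
}

#' Per-factor subscale scores
#'
#' Counts of endorsed items within each factor.  The factors must partition
#' the context's items, so the components always sum to the total score.
#'
#' @inheritParams score
#' @param factors named list of item-id vectors partitioning the context.
#' @return Named integer vector, one count per factor.
#' @export
subscale_scores <- function(pattern, factors = queds_factors(), ctx = queds_context()) {
  pattern <- .as_pattern(pattern)
  all_ids <- sort(as.integer(unlist(factors)))
  if (!identical(all_ids, sort(as.integer(ctx$items$id)))) {
    stop_input("factors must partition the context's items")
  }
  .item_index(ctx, pattern$endorsed)
  vapply(factors, function(ids) sum(pattern$endorsed %in% ids), integer(1))
}

#' Derive a clinical state from a response pattern
#'
#' The attribute profile is the union of the intents of the endorsed items:
#' an affirmative answer to an item is taken as evidence of every criterion
#' that item investigates.
#'
#' @param ctx a `clinical_context`.
#' @param pattern a `response_pattern` or vector of endorsed item ids.
#' @return An object of class `clinical_state` with components `endorsed`
#'   (item ids) and `profile` (attribute ids, in context column order).
#' @export
clinical_state <- function(ctx, pattern) {
  pattern <- .as_pattern(pattern)
  idx <- .item_index(ctx, pattern$endorsed)
  profile <- if (length(idx)) {
    ctx$attributes$id[colSums(ctx$incidence[idx, , drop = FALSE]) > 0L]
  } else character(0)
  structure(
    list(subject_id = pattern$subject_id, endorsed = pattern$endorsed,
         profile = profile),
    class = "clinical_state"
  )
}

#' @export
print.clinical_state <- function(x, ...) {
  cat("Clinical state", if (!is.na(x$subject_id)) paste0("[", x$subject_id, "]"), "\n")
  cat("  endorsed items (", length(x$endorsed), "): ",
      paste(x$endorsed, collapse = ", "), "\n", sep = "")
  cat("  attribute profile (", length(x$profile), "): ",
      paste(x$profile, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare two clinical states attribute-wise
#'
#' Decomposes the two attribute profiles into shared criteria and criteria
#' unique to each respondent — the qualitative comparison that separates
#' patients with identical scores.
#'
#' @param s1,s2 `clinical_state` objects over the same context.
#' @return An object of class `state_comparison` with components `shared`,
#'   `only_first` and `only_second` (disjoint attribute-id vectors whose
#'   union is the union of the two profiles).
#' @export
compare_states <- function(s1, s2) {
  structure(
    list(shared = intersect(s1$profile, s2$profile),
         only_first = setdiff(s1$profile, s2$profile),
         only_second = setdiff(s2$profile, s1$profile),
         subjects = c(s1$subject_id, s2$subject_id)),
    class = "state_comparison"
  )
}

#' @export
print.state_comparison <- function(x, ...) {
  lab <- function(i, fallback) {
    if (!is.na(x$subjects[i])) x$subjects[i] else fallback
  }
  cat("State comparison:", lab(1, "first"), "vs", lab(2, "second"), "\n")
  cat("  shared:     ", paste(x$shared, collapse = ", "), "\n")
  cat("  only", lab(1, "first"), ": ", paste(x$only_first, collapse = ", "), "\n")
  cat("  only", lab(2, "second"), ": ", paste(x$only_second, collapse = ", "), "\n")
  invisible(x)
}

#' Consistency of a pattern with a clinical structure
#'
#' Checks whether an observed response pattern is one of the structure's
#' admissible states and, if not, how far it is from the nearest state in
#' symmetric-difference distance.  Ties among nearest states are broken by
#' the lexicographically smallest sorted item-id list.
#'
#' @param structure a `clinical_structure`.
#' @param pattern a `response_pattern` or vector of endorsed item ids.
#' @return List with components `is_state`, `min_distance` and `nearest`.
#' @export
pattern_consistency <- function(structure, pattern) {
  pattern <- .as_pattern(pattern)
  endorsed <- pattern$endorsed
  .item_index(structure$context, endorsed)
  dists <- vapply(structure$states, function(s) {
    length(setdiff(endorsed, s)) + length(setdiff(s, endorsed))
  }, integer(1))
  dmin <- min(dists)
  cand <- structure$states[dists == dmin]
  # lexicographic order on the sorted id lists; shorter prefix wins ties
  keyfun <- function(s) paste(sprintf("%06d", s), collapse = ",")
  nearest <- cand[[order(vapply(cand, keyfun, character(1)))[1L]]]
  list(is_state = dmin == 0L, min_distance = dmin, nearest = nearest)
}

# --- responses file I/O ----------------------------------------------------

#' Read / write respondent 0/1 response tables
#'
#' The CSV dialect has one row per subject and columns
#' `subject_id,group,I1..In` with 0/1 cells; `group` may be empty.
#'
#' @param path file path.
#' @param ctx the context whose items the columns must match.
#' @return `read_responses()` returns a list of `response_pattern` objects;
#'   the 0/1 matrix is attached as attribute `"matrix"` (subjects x items)
#'   and group labels as attribute `"groups"`.
#' @export
read_responses <- function(path, ctx = queds_context()) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!("subject_id" %in% names(df))) {
    stop_input("malformed responses CSV: missing 'subject_id' header in ", path)
  }
  item_cols <- paste0("I", ctx$items$id)
  missing <- setdiff(item_cols, names(df))
  if (length(missing)) {
    stop_input("responses CSV lacks item column(s): ",
               paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop_input("duplicate subject id(s) in ", path)
  }
  for (cc in item_cols) {
    bad <- which(!(df[[cc]] %in% c("0", "1")))
    if (length(bad)) {
      stop_input("malformed cell for subject ", df$subject_id[bad[1]],
                 ", column ", cc, ": '", df[[cc]][bad[1]], "' is not 0/1")
    }
  }
  mat <- vapply(item_cols, function(cc) as.integer(df[[cc]]),
                integer(nrow(df)))
  mat <- matrix(mat, nrow = nrow(df),
                dimnames = list(df$subject_id, item_cols))
  groups <- if ("group" %in% names(df)) {
    ifelse(df$group %in% c("clinical", "nonclinical"), df$group, NA_character_)
  } else rep(NA_character_, nrow(df))
  patterns <- lapply(seq_len(nrow(df)), function(i) {
    response_pattern(ctx$items$id[mat[i, ] == 1L], df$subject_id[i], groups[i])
  })
  names(patterns) <- df$subject_id
  attr(patterns, "matrix") <- mat
  attr(patterns, "groups") <- groups
  patterns
}

#' @rdname read_responses
#' @param responses 0/1 matrix (subjects x items) with subject-id rownames,
#'   or a list of `response_pattern`s as returned by `read_responses()`.
#' @param groups optional per-subject group labels.
#' @export
write_responses <- function(responses, path, groups = NULL, ctx = queds_context()) {
  if (is.list(responses) && !is.matrix(responses)) {
    mat <- attr(responses, "matrix")
    if (is.null(mat)) {
      mat <- t(vapply(responses, function(p)
        as.integer(ctx$items$id %in% p$endorsed), integer(nrow(ctx$items))))
      rownames(mat) <- vapply(responses, function(p) p$subject_id, character(1))
    }
    if (is.null(groups)) {
      groups <- vapply(responses, function(p) p$group, character(1))
    }
  } else {
    mat <- responses
  }
  if (is.null(groups)) groups <- rep("", nrow(mat))
  groups[is.na(groups)] <- ""
  df <- data.frame(subject_id = rownames(mat) %||% seq_len(nrow(mat)),
                   group = groups, stringsAsFactors = FALSE)
  colnames(mat) <- paste0("I", ctx$items$id)
  utils::write.csv(cbind(df, as.data.frame(mat)), path, row.names = FALSE)
  invisible(path)
}
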