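# ---------------------------------------------------------------------------
# Deterministic adaptive administration over a clinical structure.
#
# The candidate set starts as the whole state family.  Each question is the
# unasked item whose answer splits the remaining candidates most evenly
# (half-split); the answer eliminates every candidate inconsistent with it.
# With an error-free responder the session terminates on the respondent's
# true state, usually after far fewer questions than there are items.
# ---------------------------------------------------------------------------

#' Select the next item to ask
#'
#' Returns the unasked item minimizing the absolute difference between the
#' number of candidate states containing it and the number lacking it
#' (half-split rule).  Items contained in all candidates or in none are
#' uninformative and never selected; ties are broken by the smallest item
#' id.
#'
#' @param candidate_states list of item-id vectors (at least two).
#' @param asked_items item ids already asked.
#' @return One item id.
#' @export
next_question <- function(candidate_states, asked_items = integer(0)) {
  if (length(candidate_states) < 2L) {
    stop_input("need at least two candidate states")
  }
  all_items <- sort(unique(unlist(candidate_states)))
  pool <- setdiff(all_items, asked_items)
  n <- length(candidate_states)
  counts <- vapply(pool, function(q)
    sum(vapply(candidate_states, function(s) q %in% s, logical(1))), integer(1))
  informative <- counts > 0L & counts < n
  if (!any(informative)) {
    stop_compute("no informative item remains among ", n,
                 " candidates (duplicate states?)")
  }
  pool <- pool[informative]
  balance <- abs(2L * counts[informative] - n)
  pool[which.min(balance)]  # which.min takes the first = smallest id
}

#' Run an adaptive assessment session
#'
#' With an error-free responder the elimination loop alone recovers the true
#' state.  A responder who deviates from every state cannot be detected by
#' elimination (every informative question leaves a non-empty candidate
#' set), so detection is opt-in: with `verify = TRUE` the remaining items
#' are administered after convergence and any contradiction triggers the
#' exhaustive fallback.
#'
#' @param structure a `clinical_structure`.
#' @param responder either an item set (the respondent's true state, from
#'   which an error-free 0/1 oracle is built) or a function mapping an item
#'   id to 0/1.
#' @param verify administer the unasked items after convergence and check
#'   them against the inferred state (costs the adaptivity saving).
#' @return An object of class `session_transcript` with components `asked`
#'   (data frame of item/answer in order), `inferred` (data frame of items
#'   not asked, with answers read off the final state), `final_state`,
#'   `n_asked` and `consistent`.  If verification finds the responder
#'   inconsistent with the structure, all items end up administered,
#'   `final_state` is the observed endorsed set (generally not a state),
#'   and `consistent` is FALSE.
#' @export
run_session <- function(structure, responder, verify = FALSE) {
  if (!is.function(responder)) {
    truth <- as.integer(responder)
    responder <- function(item) as.integer(item %in% truth)
  }
  items <- as.integer(structure$context$items$id)
  candidates <- structure$states
  asked <- integer(0)
  answers <- integer(0)
  consistent <- TRUE
  while (length(candidates) > 1L) {
    q <- next_question(candidates, asked)
    a <- as.integer(responder(q))
    if (!a %in% c(0L, 1L)) stop_input("responder must answer 0 or 1")
    asked <- c(asked, q)
    answers <- c(answers, a)
    keep <- vapply(candidates, function(s) (q %in% s) == (a == 1L), logical(1))
    candidates <- candidates[keep]
    if (!length(candidates)) { consistent <- FALSE; break }
  }
  if (consistent && verify) {
    final_state <- candidates[[1L]]
    for (q in setdiff(items, asked)) {
      a <- as.integer(responder(q))
      asked <- c(asked, q)
      answers <- c(answers, a)
      if (a != as.integer(q %in% final_state)) consistent <- FALSE
    }
  }
  if (consistent) {
    final_state <- candidates[[1L]]
    inferred_items <- setdiff(items, asked)
    inferred <- data.frame(item = inferred_items,
                           answer = as.integer(inferred_items %in% final_state))
  } else {
    # exhaustive fallback: ask everything not yet asked
    for (q in setdiff(items, asked)) {
      a <- as.integer(responder(q))
      asked <- c(asked, q)
      answers <- c(answers, a)
    }
    final_state <- sort(asked[answers == 1L])
    inferred <- data.frame(item = integer(0), answer = integer(0))
  }
  structure(
    list(asked = data.frame(item = asked, answer = answers),
         inferred = inferred,
         final_state = sort(final_state),
         n_asked = length(asked),
         consistent = consistent),
    class = "session_transcript"
  )
}

#' @export
print.session_transcript <- function(x, ...) {
  cat("Adaptive session:", x$n_asked, "questions asked,",
      nrow(x$inferred), "answers inferred",
      if (!x$consistent) "(responder inconsistent with structure)", "\n")
  cat("  final state (", length(x$final_state), " items): ",
      paste(x$final_state, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a session transcript as JSON
#'
#' @param transcript a `session_transcript`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  jsonlite::write_json(
    list(asked = transcript$asked, inferred = transcript$inferred,
         final_state = transcript$final_state,
         n_asked = transcript$n_asked, consistent = transcript$consistent),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' Question-savings statistics for a structure
#'
#' Simulates an error-free adaptive session for every state of the
#' structure (or for a seeded sample of states when the family is large)
#' and summarizes how many questions were needed.
#'
#' @param structure a `clinical_structure`.
#' @param seed integer seed used only when sampling is needed.
#' @param max_exhaustive run all states when the family is no larger than
#'   this; otherwise sample `sample_size` states.
#' @param sample_size number of states sampled for large families.
#' @return List with `mean_asked`, `max_asked`, `n_items`, `n_states` and
#'   `exhaustive` (whether all states were simulated).
#' @export
savings_report <- function(structure, seed = 1L, max_exhaustive = 4096L,
                           sample_size = 200L) {
  states <- structure$states
  exhaustive <- length(states) <= max_exhaustive
  if (!exhaustive) {
    set.seed(seed)
    states <- states[sample.int(length(states), sample_size)]
  }
  asked <- vapply(states, function(s) run_session(structure, s)$n_asked,
                  integer(1))
  list(mean_asked = mean(asked), max_asked = max(asked),
       n_items = nrow(structure$context$incidence),
       n_states = structure$n_states, exhaustive = exhaustive)
}
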