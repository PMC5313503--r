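# ---------------------------------------------------------------------------
# Formal Concept Analysis / Knowledge Space Theory engine.
#
# Derivation operators on a Boolean context, formal concepts (NextClosure,
# lectic order on intents), the prerequisite (surmise) quasi-order, and the
# clinical structure delineated by the conjunctive attribution model:
#   K(S) = { q : intent(q) subset of S }.
# Item sets are handled as logical vectors over the context's row order.
# ---------------------------------------------------------------------------

.item_index <- function(ctx, item_set) {
  idx <- match(item_set, ctx$items$id)
  if (anyNA(idx)) {
    stop_input("unknown item id(s): ",
               paste(item_set[is.na(idx)], collapse = ", "))
  }
  idx
}

.attr_index <- function(ctx, attr_set) {
  idx <- match(attr_set, ctx$attributes$id)
  if (anyNA(idx)) {
    stop_input("unknown attribute id(s): ",
               paste(attr_set[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Galois derivation operators
#'
#' `derive_items(ctx, item_set)` returns the attributes common to all items
#' in the set; `derive_attrs(ctx, attr_set)` returns the items possessing
#' all attributes in the set.  By the usual convention the derivation of the
#' empty set is the full opposite set.
#'
#' @param ctx a `clinical_context`.
#' @param item_set vector of item ids (possibly empty).
#' @param attr_set vector of attribute ids (possibly empty).
#' @return A character vector of attribute ids, or a vector of item ids.
#' @export
derive_items <- function(ctx, item_set) {
  if (!length(item_set)) return(ctx$attributes$id)
  idx <- .item_index(ctx, item_set)
  common <- colSums(ctx$incidence[idx, , drop = FALSE] == 0L) == 0L
  ctx$attributes$id[common]
}

#' @rdname derive_items
#' @export
derive_attrs <- function(ctx, attr_set) {
  if (!length(attr_set)) return(ctx$items$id)
  idx <- .attr_index(ctx, attr_set)
  has_all <- rowSums(ctx$incidence[, idx, drop = FALSE] == 0L) == 0L
  ctx$items$id[has_all]
}

#' Enumerate all formal concepts of a context
#'
#' A formal concept is a pair (extent, intent) with extent =
#' `derive_attrs(intent)` and intent = `derive_items(extent)`.  Concepts are
#' enumerated with Ganter's NextClosure algorithm, so the sequence of
#' intents is in lectic order and the output is deterministic.
#'
#' @param ctx a `clinical_context`.
#' @return List of concepts; each is a list with components `extent` (item
#'   ids) and `intent` (attribute ids).
#' @export
formal_concepts <- function(ctx) {
  m <- ncol(ctx$incidence)
  inc <- ctx$incidence == 1L
  # closure of an attribute set (logical over columns): A -> A''
  clo <- function(a) {
    ext <- if (!any(a)) rep(TRUE, nrow(inc)) else
      rowSums(!inc[, a, drop = FALSE]) == 0L
    if (!any(ext)) rep(TRUE, m) else colSums(!inc[ext, , drop = FALSE]) == 0L
  }
  concepts <- list()
  a <- clo(logical(m))
  repeat {
    ext <- if (!any(a)) ctx$items$id else derive_attrs(ctx, ctx$attributes$id[a])
    concepts[[length(concepts) + 1L]] <-
      list(extent = ext, intent = ctx$attributes$id[a])
    if (all(a)) break
    nxt <- NULL
    for (i in rev(seq_len(m))) {
      if (a[i]) { a[i] <- FALSE; next }
      b <- a; b[i] <- TRUE
      b <- clo(b)
      # lectic successor test: no new attribute before position i
      if (!any(b[seq_len(i - 1L)] & !a[seq_len(i - 1L)])) { nxt <- b; break }
    }
    if (is.null(nxt)) break
    a <- nxt
  }
  concepts
}

#' The prerequisite (surmise) relation of a context
#'
#' Item i is a prerequisite of item j exactly when i's intent is contained
#' in j's: an affirmative answer to j then presupposes every criterion of i,
#' so i must be endorsable too.  The relation is a quasi-order (reflexive
#' and transitive) by construction.
#'
#' @param ctx a `clinical_context`.
#' @return An object of class `prerequisite_relation` with components
#'   `pairs` (two-column matrix of (prerequisite, dependent) item ids) and
#'   `items`.
#' @export
prerequisites <- function(ctx) {
  inc <- ctx$incidence == 1L
  n <- nrow(inc)
  # leq[i, j] == TRUE iff intent(i) subset of intent(j)
  leq <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    leq[i, ] <- colSums(inc[i, ] & !t(inc)) == 0L
  }
  idx <- which(leq, arr.ind = TRUE)
  pairs <- cbind(prerequisite = ctx$items$id[idx[, 1L]],
                 dependent = ctx$items$id[idx[, 2L]])
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  structure(list(pairs = pairs, items = ctx$items$id),
            class = "prerequisite_relation")
}

#' @export
print.prerequisite_relation <- function(x, ...) {
  cat("Prerequisite relation on", length(x$items), "items:",
      nrow(x$pairs), "ordered pairs (incl. reflexive)\n")
  invisible(x)
}

#' Test a pair in a prerequisite relation
#'
#' @param relation a `prerequisite_relation`.
#' @param i,j item ids; tests whether i is a prerequisite of j.
#' @return Logical.
#' @export
has_prerequisite <- function(relation, i, j) {
  any(relation$pairs[, 1L] == i & relation$pairs[, 2L] == j)
}

.state_key <- function(ids) paste(sort(as.integer(ids)), collapse = ",")

#' Delineate the clinical structure of a context
#'
#' Under the conjunctive attribution model, a respondent characterised by a
#' criterion set S endorses exactly the items whose intent is contained in
#' S: K(S) = \{q : intent(q) ⊆ S\}.  The clinical structure is the family of
#' all such item sets.  It always contains the empty set and the full
#' domain, is closed under intersection, and every member is a down-set of
#' the prerequisite relation.
#'
#' The family is computed by breadth-first union-closure over item intents
#' (every state equals K(U) for U a union of its members' intents), which
#' visits each state once instead of enumerating all 2^|attributes| subsets.
#'
#' @param ctx a `clinical_context`.
#' @param max_states safety cap on the family size; exceeding it raises an
#'   error suggesting delineation of a factor subcontext instead.
#' @return An object of class `clinical_structure` with components `states`
#'   (list of sorted item-id vectors, ordered by size then lexicographically),
#'   `n_states`, and `context` (the generating context).
#' @export
delineate <- function(ctx, max_states = 5e6) {
  inc <- ctx$incidence == 1L
  n <- nrow(inc)
  ids <- as.integer(ctx$items$id)
  # K for an attribute set given as logical over columns
  k_of <- function(u) {
    if (all(u)) rep(TRUE, n) else rowSums(inc[, !u, drop = FALSE]) == 0L
  }
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  empty_state <- k_of(logical(ncol(inc)))  # items with empty intent: none in valid contexts
  states <- list()
  push <- function(k, u) {
    key <- paste0("s", paste(which(k), collapse = ","))
    if (!is.null(seen[[key]])) return(FALSE)
    if (length(states) + 1L > max_states) {
      stop_compute("clinical structure exceeds max_states = ", max_states,
                   "; delineate a factor subcontext instead")
    }
    assign(key, TRUE, envir = seen)
    states[[length(states) + 1L]] <<- list(k = k, u = u)
    TRUE
  }
  push(empty_state, logical(ncol(inc)))
  head <- 1L
  while (head <= length(states)) {
    cur <- states[[head]]
    outside <- which(!cur$k)
    for (q in outside) {
      u2 <- cur$u | inc[q, ]
      push(k_of(u2), u2)
    }
    head <- head + 1L
  }
  fam <- lapply(states, function(s) ids[s$k])
  ord <- order(lengths(fam),
               vapply(fam, function(s) paste(sprintf("%06d", s), collapse = ""),
                      character(1)))
  fam <- fam[ord]
  structure(
    list(states = fam, n_states = length(fam), context = ctx,
         keys = vapply(fam, .state_key, character(1))),
    class = "clinical_structure"
  )
}

#' @export
print.clinical_structure <- function(x, ...) {
  cat("Clinical structure:", x$n_states, "states over",
      nrow(x$context$incidence), "items\n")
  invisible(x)
}

#' Membership test in a clinical structure
#'
#' @param structure a `clinical_structure`.
#' @param item_set vector of item ids (possibly empty).
#' @return TRUE iff `item_set` is one of the structure's states.
#' @export
is_state <- function(structure, item_set) {
  .state_key(item_set) %in% structure$keys
}

# --- export ----------------------------------------------------------------

#' Export a structure or relation
#'
#' `write_structure()` writes the state family as JSON (each state a sorted
#' item-id list); `write_relation()` writes the prerequisite relation as a
#' tab-separated edge list (`prerequisite<TAB>dependent`) for graph tooling.
#'
#' @param structure a `clinical_structure`.
#' @param relation a `prerequisite_relation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  jsonlite::write_json(
    list(n_items = nrow(structure$context$incidence),
         n_states = structure$n_states,
         states = structure$states),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_structure
#' @export
write_relation <- function(relation, path) {
  utils::write.table(relation$pairs, path, sep = "\t", row.names = FALSE,
                     col.names = c("prerequisite", "dependent"), quote = FALSE)
  invisible(path)
}
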