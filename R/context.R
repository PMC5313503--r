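# ---------------------------------------------------------------------------
# Clinical contexts: the items-by-criteria Boolean incidence structure at the
# heart of Formal Psychological Assessment.  Items are the questionnaire
# prompts (objects); attributes are the diagnostic criteria (A1..A23) an item
# investigates.  incidence[i, a] == 1 iff item i investigates criterion a.
# ---------------------------------------------------------------------------

.queds_attributes <- function() {
  data.frame(
    id = paste0("A", 1:23),
    label = c(
      "Depressed mood",
      "Diminished interest and pleasure",
      "Decreased interest in sex",
      "Increase or loss of weight",
      "Gain or loss of appetite",
      "Insomnia or hypersomnia",
      "Agitation",
      "Psychomotor retardation",
      "Fatigue or energy loss",
      "Feelings of worthlessness",
      "Feelings of guilt",
      "Diminished ability to think and concentrate",
      "Indecision",
      "Recurrent thoughts of death",
      "Suicidal ideation or attempted suicide",
      "Negative view of the world",
      "Negative expectation of the future",
      "Learned helplessness",
      "Irritability",
      "Apathy",
      "Health concern",
      "Somatic disorders",
      "More positive mood in the evening"
    ),
    source = c(rep("DSM5", 15), "Beck", "Beck", "Seligman", rep("literature", 5)),
    stringsAsFactors = FALSE
  )
}

.queds_items <- function() {
  txt <- c(
    "I feel that I don't have the same energy to have sex",
    "I often wake up in the middle of the night and I can't sleep again",
    "I feel like my thinking is slowing down",
    "I have sleeping problems",
    "I am stressed by feelings of guilt",
    "I think the world is cruel and unhappy",
    "I keep crying very easily",
    "I get irritated very easily",
    "I think my life is hell and I only deserve to feel bad",
    "I feel incapable to face life's events",
    "I suffer from somatic disorders (e.g. headache, stomach ache)",
    "I have lost interest in the future which doesn't save anything good for me",
    "I am less interested in sex",
    "I feel incapable and totally useless",
    "I see the same unhappiness I have now in the future",
    "My desire to eat is not the same",
    "I often feel like crying, but I cannot do it",
    "I cannot have any interest and pleasure in people and things that before I was interested in",
    "I thought to kill myself",
    "Sometimes I think it would be better if I were dead",
    "I am really worried about my health",
    "My weight has had significant changes",
    "I've visibly lost (or gained) weight",
    "I am afraid of everything that will happen to me because I am not able to do anything",
    "I feel like I don't have any more power over my empty and sad life",
    "My appetite has changed",
    "To make choices is hard for me",
    "I feel I'm slowing down in my daily routines",
    "I feel helpless and inhibited facing my incapacity to concentrate",
    "I feel too much on the other people that it would be better if I killed myself",
    "I have not much energy and I feel tired",
    "I am disappointed of myself and the choices I made",
    "I have problems in making decisions",
    "I feel sad",
    "My ability to think and memorize has been reduced",
    "I don't have any interest and desire in doing anything",
    "I am agitated by the idea that this sadness won't ever leave me",
    "I feel agitated",
    "I feel so tired and without any energy that I need help to wash myself and to get dressed",
    "I am better in the evening more than in the morning",
    "I often feel like a loser"
  )
  intents <- list(
    c(3, 9), c(6, 7), c(8, 12), 6, 11, 16, c(1, 7, 19), 19, c(1, 11, 16),
    18, 22, c(2, 17), c(3, 20), c(10, 18), c(1, 17), 5, c(1, 20), c(2, 20),
    c(14, 15), 14, 21, 4, 4, c(17, 18), c(1, 16, 18), 5, c(12, 13, 20),
    c(8, 9), c(12, 20), c(10, 11, 14), 9, c(10, 11), 13, 1, c(8, 9, 12),
    2, c(1, 7, 17), 7, c(8, 9, 18, 20), 23, 10
  )
  list(
    items = data.frame(id = 1:41, text = txt, stringsAsFactors = FALSE),
    intents = lapply(intents, function(a) paste0("A", a))
  )
}

#' Construct a clinical context
#'
#' A clinical context is the Boolean incidence structure of Formal
#' Psychological Assessment: questionnaire items in rows, diagnostic criteria
#' (attributes) in columns, with a 1 wherever an item investigates a
#' criterion.  The incidence row of each item is exactly the indicator of the
#' item's intent (its attribute set).
#'
#' @param items data frame with columns `id` (unique integers) and `text`.
#' @param attributes data frame with columns `id` (unique tokens), `label`
#'   and optionally `source`.
#' @param intents list, parallel to the rows of `items`, of character vectors
#'   of attribute ids.
#' @return An object of class `clinical_context` with components `items`,
#'   `attributes` and `incidence` (a 0/1 integer matrix, one row per item).
#' @seealso [queds_context()] for the built-in instrument,
#'   [validate_context()], [subcontext()].
#' @export
clinical_context <- function(items, attributes, intents) {
  if (anyDuplicated(items$id)) {
    stop_input("duplicate item id(s): ",
               paste(unique(items$id[duplicated(items$id)]), collapse = ", "))
  }
  if (anyDuplicated(attributes$id)) {
    stop_input("duplicate attribute id(s)")
  }
  if (length(intents) != nrow(items)) {
    stop_input("one intent per item required")
  }
  unknown <- setdiff(unique(unlist(intents)), attributes$id)
  if (length(unknown)) {
    stop_input("intent refers to unknown attribute(s): ",
               paste(unknown, collapse = ", "))
  }
  inc <- matrix(0L, nrow(items), nrow(attributes),
                dimnames = list(items$id, attributes$id))
  for (i in seq_along(intents)) inc[i, intents[[i]]] <- 1L
  structure(
    list(items = items, attributes = attributes, incidence = inc),
    class = "clinical_context"
  )
}

#' The built-in QuEDS instrument
#'
#' Returns the 41-item, 23-criterion QuEDS clinical context: each item's
#' intent is the published set of major-depressive-episode criteria it
#' investigates.  The instrument covers every criterion (no empty columns)
#' and every item investigates at least one criterion (no empty rows).
#'
#' @return A `clinical_context` with 41 items and 23 attributes.
#' @examples
#' ctx <- queds_context()
#' item_intent(ctx, 27)   # criteria investigated by item 27
#' @export
queds_context <- function() {
  it <- .queds_items()
  clinical_context(it$items, .queds_attributes(), it$intents)
}

#' The three QuEDS factor subscales
#'
#' The cognitive, somatic and affective factors partition the 41 items
#' (15, 14 and 12 items respectively).
#'
#' @return Named list of integer item-id vectors.
#' @export
queds_factors <- function() {
  list(
    cognitive = c(5L, 6L, 9L, 10L, 14L, 19L, 20L, 21L, 24L, 25L, 27L, 30L, 32L, 33L, 41L),
    somatic   = c(1L, 2L, 3L, 4L, 11L, 13L, 16L, 22L, 23L, 26L, 28L, 31L, 35L, 39L),
    affective = c(7L, 8L, 12L, 15L, 17L, 18L, 29L, 34L, 36L, 37L, 38L, 40L)
  )
}

#' @export
print.clinical_context <- function(x, ...) {
  cat("Clinical context:", nrow(x$incidence), "items x",
      ncol(x$incidence), "attributes\n")
  cat("Incidence density:",
      formatC(mean(x$incidence), digits = 3, format = "f"), "\n")
  invisible(x)
}

#' Intent of a single item
#'
#' @param ctx a `clinical_context`.
#' @param item_id one item id.
#' @return Character vector of attribute ids investigated by the item.
#' @export
item_intent <- function(ctx, item_id) {
  i <- match(item_id, ctx$items$id)
  if (is.na(i)) stop_input("unknown item id: ", item_id)
  colnames(ctx$incidence)[ctx$incidence[i, ] == 1L]
}

.intent_list <- function(ctx) {
  apply(ctx$incidence, 1L, function(r) colnames(ctx$incidence)[r == 1L],
        simplify = FALSE)
}

# --- serialization ---------------------------------------------------------

#' Read / write a clinical context
#'
#' The CSV dialect has header `item_id,text,A1,...` (the `text` column is
#' optional) and 0/1 cells; the JSON document stores items with their
#' attribute lists plus the attribute table.  A write followed by a read
#' reproduces the context exactly.
#'
#' @param path file path; format is inferred from the extension (`.json` vs
#'   anything else = CSV) unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return `read_context()` returns a `clinical_context`; `write_context()`
#'   returns `path` invisibly.
#' @export
read_context <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") .read_context_json(path) else .read_context_csv(path)
}

.read_context_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!("item_id" %in% names(df))) {
    stop_input("malformed context CSV: missing 'item_id' header in ", path)
  }
  attr_cols <- setdiff(names(df), c("item_id", "text"))
  if (!length(attr_cols)) stop_input("context CSV has no attribute columns")
  if (anyDuplicated(df$item_id)) {
    stop_input("duplicate item id(s) in ", path, ": ",
               paste(unique(df$item_id[duplicated(df$item_id)]), collapse = ", "))
  }
  for (a in attr_cols) {
    bad <- which(!(df[[a]] %in% c("0", "1")))
    if (length(bad)) {
      stop_input("malformed cell at row ", df$item_id[bad[1]], ", column ", a,
                 ": '", df[[a]][bad[1]], "' is not 0/1")
    }
  }
  items <- data.frame(
    id = as.integer(df$item_id),
    text = if ("text" %in% names(df)) df$text else rep("", nrow(df)),
    stringsAsFactors = FALSE
  )
  known <- .queds_attributes()
  attributes <- data.frame(
    id = attr_cols,
    label = ifelse(attr_cols %in% known$id,
                   known$label[match(attr_cols, known$id)], attr_cols),
    source = ifelse(attr_cols %in% known$id,
                    known$source[match(attr_cols, known$id)], "literature"),
    stringsAsFactors = FALSE
  )
  intents <- lapply(seq_len(nrow(df)), function(i) {
    attr_cols[vapply(attr_cols, function(a) df[[a]][i] == "1", logical(1))]
  })
  clinical_context(items, attributes, intents)
}

.read_context_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$items) || is.null(doc$attributes)) {
    stop_input("malformed context JSON: 'items' and 'attributes' required")
  }
  items <- data.frame(
    id = vapply(doc$items, function(x) as.integer(x$id), integer(1)),
    text = vapply(doc$items, function(x) as.character(x$text %||% ""), character(1)),
    stringsAsFactors = FALSE
  )
  attributes <- data.frame(
    id = vapply(doc$attributes, function(x) as.character(x$id), character(1)),
    label = vapply(doc$attributes, function(x) as.character(x$label %||% x$id), character(1)),
    source = vapply(doc$attributes, function(x) as.character(x$source %||% "literature"), character(1)),
    stringsAsFactors = FALSE
  )
  intents <- lapply(doc$items, function(x) as.character(unlist(x$attributes)))
  clinical_context(items, attributes, intents)
}

#' @rdname read_context
#' @param ctx a `clinical_context`.
#' @export
write_context <- function(ctx, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    doc <- list(
      items = lapply(seq_len(nrow(ctx$items)), function(i) {
        list(id = ctx$items$id[i], text = ctx$items$text[i],
             attributes = as.list(item_intent(ctx, ctx$items$id[i])))
      }),
      attributes = lapply(seq_len(nrow(ctx$attributes)), function(i) {
        list(id = ctx$attributes$id[i], label = ctx$attributes$label[i],
             source = ctx$attributes$source[i])
      })
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    df <- data.frame(item_id = ctx$items$id, text = ctx$items$text,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(ctx$incidence, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# --- validation ------------------------------------------------------------

#' Validate a clinical context
#'
#' Content-validity check on the incidence structure: an empty row would be
#' an item that investigates no criterion; an empty column, a criterion not
#' investigated by any item.  Items with identical intents are reported as
#' informational duplicates (they are legitimate, e.g. two weight-change
#' items both investigating the same criterion).
#'
#' @param ctx a `clinical_context`.
#' @return A list of class `context_validation` with components `empty_rows`
#'   (item ids), `empty_cols` (attribute ids), `duplicate_rows` (item ids
#'   sharing an intent with another item) and `ok` (TRUE iff no empty rows
#'   or columns).
#' @export
validate_context <- function(ctx) {
  inc <- ctx$incidence
  empty_rows <- ctx$items$id[rowSums(inc) == 0L]
  empty_cols <- ctx$attributes$id[colSums(inc) == 0L]
  key <- apply(inc, 1L, paste, collapse = "")
  duplicate_rows <- ctx$items$id[key %in% key[duplicated(key)]]
  structure(
    list(empty_rows = empty_rows, empty_cols = empty_cols,
         duplicate_rows = duplicate_rows,
         ok = length(empty_rows) == 0L && length(empty_cols) == 0L),
    class = "context_validation"
  )
}

#' @export
print.context_validation <- function(x, ...) {
  cat("Context validation:", if (x$ok) "OK" else "PROBLEMS FOUND", "\n")
  cat("  empty rows:     ",
      if (length(x$empty_rows)) paste(x$empty_rows, collapse = ", ") else "none", "\n")
  cat("  empty columns:  ",
      if (length(x$empty_cols)) paste(x$empty_cols, collapse = ", ") else "none", "\n")
  cat("  duplicate rows: ",
      if (length(x$duplicate_rows)) paste(x$duplicate_rows, collapse = ", ") else "none",
      "(informational)\n")
  invisible(x)
}

#' Restrict a context to a subset of items
#'
#' Rows are restricted to `item_ids`; columns are restricted to the
#' attributes still investigated by at least one retained item.  This is how
#' the per-factor clinical contexts are obtained from the full instrument.
#'
#' @param ctx a `clinical_context`.
#' @param item_ids non-empty subset of the context's item ids.
#' @return A `clinical_context`.
#' @export
subcontext <- function(ctx, item_ids) {
  if (!length(item_ids)) stop_input("item_ids must be non-empty")
  idx <- match(item_ids, ctx$items$id)
  if (anyNA(idx)) {
    stop_input("unknown item id(s): ", paste(item_ids[is.na(idx)], collapse = ", "))
  }
  inc <- ctx$incidence[idx, , drop = FALSE]
  keep <- colSums(inc) > 0L
  clinical_context(
    ctx$items[idx, , drop = FALSE],
    ctx$attributes[keep, , drop = FALSE],
    apply(inc[, keep, drop = FALSE], 1L,
          function(r) colnames(inc)[keep][r == 1L], simplify = FALSE)
  )
}

#' Which factors investigate each attribute
#'
#' For each attribute of the context, lists the factors whose subcontext
#' retains it, i.e. the subscales through which that diagnostic criterion is
#' observable.
#'
#' @param ctx a `clinical_context`.
#' @param factors named list of item-id vectors partitioning the context's
#'   items (default: the built-in QuEDS factors).
#' @return Named list mapping attribute id to a character vector of factor
#'   names.
#' @export
attribute_coverage <- function(ctx, factors = queds_factors()) {
  all_ids <- sort(unlist(factors))
  if (!identical(as.integer(all_ids), sort(as.integer(ctx$items$id)))) {
    stop_input("factors must partition the context's items")
  }
  covered <- lapply(factors, function(ids) subcontext(ctx, ids)$attributes$id)
  out <- lapply(ctx$attributes$id, function(a) {
    names(factors)[vapply(covered, function(s) a %in% s, logical(1))]
  })
  names(out) <- ctx$attributes$id
  out
}

# --- expert agreement ------------------------------------------------------

#' Cohen's kappa between two Boolean matrices
#'
#' Chance-corrected cell-wise agreement between two expert-filled incidence
#' matrices of identical dimensions: kappa = (p_o - p_e) / (1 - p_e), with
#' p_o the proportion of agreeing cells and p_e the agreement expected from
#' the two matrices' marginal 0/1 proportions.
#'
#' @param m1,m2 0/1 matrices of identical dimensions.
#' @return Kappa in \[-1, 1\]; `NaN` (with a warning) when chance agreement
#'   equals 1, in which case kappa is undefined.
#' @export
cohen_kappa <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!identical(dim(m1), dim(m2))) {
    stop_input("matrices must have identical dimensions")
  }
  if (!all(m1 %in% c(0, 1)) || !all(m2 %in% c(0, 1))) {
    stop_input("matrices must be 0/1")
  }
  po <- mean(m1 == m2)
  p1 <- mean(m1); p2 <- mean(m2)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  if (pe >= 1) {
    warning("chance agreement is 1; kappa undefined")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' @rdname cohen_kappa
#' @param tables list of two or more 0/1 matrices.
#' @return `mean_pairwise_kappa()` returns the mean of Cohen's kappa over all
#'   unordered pairs of matrices.
#' @export
mean_pairwise_kappa <- function(tables) {
  if (length(tables) < 2L) stop_input("need at least two tables")
  ks <- c()
  for (i in seq_along(tables)[-length(tables)]) {
    for (j in seq((i + 1L), length(tables))) {
      ks <- c(ks, cohen_kappa(tables[[i]], tables[[j]]))
    }
  }
  mean(ks)
}

# --- error helpers ---------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("queds_input_error", "error")))
}

stop_compute <- function(...) {
  stop(errorCondition(paste0(...), class = c("queds_compute_error", "error")))
}
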