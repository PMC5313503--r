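# Shared fixtures and independent brute-force oracles.

# Build a small clinical context from a list of attribute-id vectors.
mk_context <- function(intents, attrs = NULL) {
  if (is.null(attrs)) attrs <- sort(unique(unlist(intents)))
  clinical_context(
    data.frame(id = seq_along(intents), text = paste("item", seq_along(intents)),
               stringsAsFactors = FALSE),
    data.frame(id = attrs, label = attrs, source = "literature",
               stringsAsFactors = FALSE),
    intents
  )
}

# Random context: every item gets a non-empty random intent.
random_context <- function(n_items, n_attrs) {
  attrs <- paste0("a", seq_len(n_attrs))
  intents <- lapply(seq_len(n_items), function(i) {
    sample(attrs, sample.int(n_attrs, 1L))
  })
  mk_context(intents, attrs)
}

# Oracle: delineated family by exhaustive enumeration of all 2^|attrs|
# attribute subsets, K(S) = { q : intent(q) subset of S }.
brute_delineate <- function(intents, attrs = sort(unique(unlist(intents)))) {
  m <- length(attrs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (code in 0:(2^m - 1L)) {
    s <- attrs[bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L) == 1L]
    k <- which(vapply(intents, function(a) all(a %in% s), logical(1)))
    key <- paste0("s", paste(k, collapse = ","))
    if (is.null(seen[[key]])) {
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <- as.integer(k)
    }
  }
  out
}

# Oracle: formal concepts by closing every item subset.
brute_concepts <- function(intents, attrs = sort(unique(unlist(intents)))) {
  n <- length(intents)
  derive_up <- function(items) {  # attributes common to all items in the set
    if (!length(items)) return(attrs)
    Reduce(intersect, intents[items])
  }
  derive_down <- function(aset) { # items possessing all attributes in the set
    which(vapply(intents, function(a) all(aset %in% a), logical(1)))
  }
  seen <- character(0)
  out <- list()
  for (code in 0:(2^n - 1L)) {
    sub <- which(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L) == 1L)
    int <- derive_up(sub)
    ext <- derive_down(int)
    key <- paste(ext, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(extent = as.integer(ext),
                                      intent = sort(int))
    }
  }
  out
}

# Oracle: AUC by explicit counting over all positive x negative pairs,
# ties counted 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "clinical"]
  neg <- scores[labels != "clinical"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Canonical set-of-sets comparison (order-insensitive).
same_family <- function(f1, f2) {
  k <- function(f) sort(vapply(f, function(s)
    paste(sort(as.integer(s)), collapse = ","), character(1)))
  identical(k(f1), k(f2))
}

# The two published worked-example patients with equal totals.
sc_items <- function() c(1, 3, 5, 6, 10, 12, 13, 14, 15, 16, 17, 18, 20, 22, 23,
                         24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 39,
                         40, 41)
fg_items <- function() c(2, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 18,
                         19, 20, 21, 24, 25, 26, 27, 29, 32, 33, 34, 36, 37, 38,
                         40, 41)

# Responses CSV with the worked-example patterns, for I/O and CLI tests.
write_example_responses <- function(path, ctx = queds_context()) {
  pats <- list(
    response_pattern(sc_items(), "SC", "clinical"),
    response_pattern(fg_items(), "FG", "clinical"),
    response_pattern(c(1, 11, 13, 27, 31, 33), "MT", "nonclinical")
  )
  write_responses(pats, path, ctx = ctx)
  path
}
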