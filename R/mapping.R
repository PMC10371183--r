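#' Normalize free text for lexical matching
#'
#' Case-folds, strips punctuation, and collapses whitespace. Matching on the
#' normalized form makes "LANSOPRAZOLE." and "lansoprazole" equivalent.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Lookup table from normalized label/synonym to CURIE. A normalized string
# matching more than one distinct term is marked ambiguous (CURIE NA).
lexical_index <- function(ontology) {
  labels <- data.frame(text = normalize_text(ontology$nodes$name),
                       curie = ontology$nodes$id, stringsAsFactors = FALSE)
  has_syn <- nzchar(ontology$nodes$synonyms)
  syn <- NULL
  if (any(has_syn)) {
    syn_split <- strsplit(ontology$nodes$synonyms[has_syn], "|", fixed = TRUE)
    syn <- data.frame(
      text = normalize_text(unlist(syn_split)),
      curie = rep(ontology$nodes$id[has_syn], lengths(syn_split)),
      stringsAsFactors = FALSE
    )
  }
  idx <- unique(rbind(labels, syn))
  amb <- unique(idx$text[duplicated(idx$text)])
  idx$curie[idx$text %in% amb] <- NA_character_
  unique(idx)
}

#' Match free text against ontology labels and synonyms
#'
#' Deterministic exact matcher standing in for semi-automated named-entity
#' curation: the normalized text is compared against normalized term labels
#' and registered synonyms. Exactly one matching term yields its CURIE; zero
#' or several yield `NA` (the caller records the miss in the unmapped
#' report). Misses are reported, never raised.
#'
#' @param text Character scalar (or vector) of free-text responses.
#' @param ontology An [ontology()].
#' @return CURIE(s) or `NA` where unmatched/ambiguous.
#' @export
match_free_text <- function(text, ontology) {
  idx <- attr(ontology, ".lex_index")
  if (is.null(idx)) idx <- lexical_index(ontology)
  idx$curie[match(normalize_text(text), idx$text)]
}

#' Load and validate a translation key
#'
#' The key maps each survey question to a predicate and either a single CURIE
#' (binary / ordinal questions), a `value=CURIE;...` map (categorical), or
#' the directive `MATCH` (free text, delegated to the lexical matcher).
#'
#' @param path TSV with columns `question_id`, `response_type`, `predicate`,
#'   `curie_or_map`.
#' @param ontology An [ontology()] against which every CURIE must resolve.
#' @return A data.frame of class `translation_key`.
#' @export
load_translation_key <- function(path, ontology) {
  key <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("question_id", "response_type", "predicate", "curie_or_map")
  if (!all(required %in% names(key))) {
    stop("translation key must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(key) == 0) {
    warning("translation key is empty")
    return(structure(key, class = c("translation_key", "data.frame")))
  }
  validate_translation_key(key, ontology)
}

#' @rdname load_translation_key
#' @param key An in-memory key data.frame with the same columns.
#' @export
validate_translation_key <- function(key, ontology) {
  dup <- unique(key$question_id[duplicated(key$question_id)])
  if (length(dup) > 0) {
    stop("duplicate question_id in translation key: ", paste(dup, collapse = ", "))
  }
  referenced <- unlist(lapply(seq_len(nrow(key)), function(i) {
    if (key$response_type[i] == "free_text") return(character(0))
    if (key$response_type[i] == "categorical") {
      pairs <- strsplit(key$curie_or_map[i], ";", fixed = TRUE)[[1]]
      sub(".*=", "", pairs)
    } else {
      key$curie_or_map[i]
    }
  }))
  names(referenced) <- unlist(lapply(seq_len(nrow(key)), function(i) {
    if (key$response_type[i] == "free_text") return(character(0))
    n <- if (key$response_type[i] == "categorical") {
      length(strsplit(key$curie_or_map[i], ";", fixed = TRUE)[[1]])
    } else 1L
    rep(key$question_id[i], n)
  }))
  bad <- !ontology_contains(ontology, referenced)
  if (any(bad)) {
    stop("translation key cites CURIEs absent from the ontology: ",
         paste(sprintf("%s -> %s", names(referenced)[bad], referenced[bad]),
               collapse = ", "))
  }
  structure(key, class = c("translation_key", "data.frame"))
}

parse_categorical_map <- function(s) {
  pairs <- strsplit(s, ";", fixed = TRUE)[[1]]
  vals <- sub("=.*", "", pairs)
  stats::setNames(sub(".*=", "", pairs), vals)
}

affirmative <- function(v) {
  !is.na(v) & tolower(v) %in% c("yes", "y", "true", "1")
}

#' Map survey responses to ontology assertions
#'
#' Applies the per-question-type transform: affirmative binary answers yield
#' one assertion with the question's term; ordinal-frequency answers are
#' binarized at value > 0; categorical answers are looked up in the value
#' map; free-text answers go through [match_free_text()]. Negative or
#' missing responses never produce an assertion. Unmappable responses
#' (unknown categorical value, unmatched or ambiguous free text) are
#' collected in the unmapped report, not raised.
#'
#' @param responses Long data.frame `respondent_id, survey, question_id,
#'   value`.
#' @param key A `translation_key`.
#' @param ontology An [ontology()].
#' @return List with `assertions` (`respondent_id, predicate, object_curie,
#'   value`) and `unmapped` (`respondent_id, question_id, value, reason`).
#' @export
map_responses <- function(responses, key, ontology) {
  stopifnot(inherits(key, "translation_key"))
  attr(ontology, ".lex_index") <- lexical_index(ontology)
  ki <- match(responses$question_id, key$question_id)
  if (anyNA(ki)) {
    stop("responses reference question_ids absent from the key: ",
         paste(unique(responses$question_id[is.na(ki)]), collapse = ", "))
  }
  type <- key$response_type[ki]
  pred <- key$predicate[ki]
  curie <- rep(NA_character_, nrow(responses))
  reason <- rep(NA_character_, nrow(responses))
  v <- responses$value

  bin <- type == "binary"
  curie[bin & affirmative(v)] <- key$curie_or_map[ki][bin & affirmative(v)]

  ord <- type == "ordinal_frequency"
  ord_pos <- ord & !is.na(v) & suppressWarnings(as.numeric(v)) > 0
  curie[ord_pos] <- key$curie_or_map[ki][ord_pos]

  cat_i <- which(type == "categorical" & !is.na(v))
  for (i in cat_i) {
    m <- parse_categorical_map(key$curie_or_map[ki[i]])
    if (v[i] %in% names(m)) {
      curie[i] <- m[[v[i]]]
    } else {
      reason[i] <- "categorical value not in map"
    }
  }

  ft <- which(type == "free_text" & !is.na(v) & nzchar(v) &
                normalize_text(v) != "none")
  if (length(ft) > 0) {
    hit <- match_free_text(v[ft], ontology)
    curie[ft] <- hit
    reason[ft][is.na(hit)] <- "no unique lexical match"
  }

  ok <- !is.na(curie)
  assertions <- data.frame(
    respondent_id = responses$respondent_id[ok],
    predicate = pred[ok],
    object_curie = curie[ok],
    value = v[ok],
    stringsAsFactors = FALSE
  )
  bad <- !is.na(reason)
  unmapped <- data.frame(
    respondent_id = responses$respondent_id[bad],
    question_id = responses$question_id[bad],
    value = v[bad],
    reason = reason[bad],
    stringsAsFactors = FALSE
  )
  rownames(assertions) <- rownames(unmapped) <- NULL
  list(assertions = assertions, unmapped = unmapped)
}

#' Map a single response record
#'
#' @param record One-row data.frame (or list) with `respondent_id`,
#'   `question_id`, `value`.
#' @inheritParams map_responses
#' @return A one-row assertion data.frame, or `NULL` when the response maps
#'   to nothing.
#' @export
map_response <- function(record, key, ontology) {
  df <- data.frame(respondent_id = record$respondent_id,
                   survey = NA_character_,
                   question_id = record$question_id,
                   value = as.character(record$value),
                   stringsAsFactors = FALSE)
  out <- map_responses(df, key, ontology)
  if (nrow(out$assertions) == 0) NULL else out$assertions
}
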