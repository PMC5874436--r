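# Text preprocessing: dosage-mention standardization, lowercasing,
# punctuation removal, stopword and drug-name removal, stemming, n-grams.

.upper_accents <- "ÀÂÄÉÈÊËÎÏÔÖÙÛÜÇŒ"
.lower_accents <- "àâäéèêëîïôöùûüçœ"

# Locale-independent lower-casing covering the French accented range.
.to_lower <- function(x) chartr(.upper_accents, .lower_accents, tolower(x))

#' Default dosage units
#'
#' Unit spellings recognized by [standardize_dosage()]. Longest spellings are
#' listed first so that regex alternation matches maximally.
#'
#' @return character vector of unit strings.
#' @export
default_dosage_units <- function() {
  c("milligrammes", "milligramme", "milligrams", "milligram",
    "grammes", "gramme", "mcg", "µg", "mg", "ml", "g")
}

#' Replace dosage mentions by a neutral token
#'
#' Every maximal occurrence of a number (integer or decimal, with `.` or `,`
#' as the decimal mark) followed by an optional space and a dosage unit is
#' replaced by the literal string `"dosemilligrams"`. All other characters are
#' left unchanged. Applied before tokenization so that the number and the unit
#' are still contiguous.
#'
#' @param text character vector of raw message text.
#' @param units character vector of unit spellings (default
#'   [default_dosage_units()]); matching is case-insensitive.
#' @return character vector with dosage mentions standardized.
#' @examples
#' standardize_dosage("je prends 2,5mg le soir")
#' @export
standardize_dosage <- function(text, units = default_dosage_units()) {
  units <- units[order(-nchar(units))]
  alt <- paste(vapply(units, function(u) gsub("([.\\\\])", "\\\\\\1", u),
                      character(1)),
               collapse = "|")
  pat <- paste0("(?<![\\p{L}\\d])\\d+(?:[.,]\\d+)?\\s*(?:", alt,
                ")(?![\\p{L}\\d])")
  gsub(pat, "dosemilligrams", text, perl = TRUE, ignore.case = TRUE)
}

#' Lowercase and tokenize text
#'
#' Lowercases the text, replaces every Unicode punctuation or symbol character
#' (including apostrophes, so French elisions such as "l'arrêt" split) by a
#' space, and splits on whitespace.
#'
#' @param text a single character string.
#' @return character vector of tokens; `character(0)` for empty or
#'   all-punctuation input.
#' @examples
#' tokenize_text("Bonjour, ça VA!")
#' @export
tokenize_text <- function(text) {
  stopifnot(length(text) == 1L)
  x <- .to_lower(text)
  # punctuation, symbols and every separator (incl. non-breaking spaces)
  x <- gsub("[\\p{P}\\p{S}\\p{Z}\\s]+", " ", x, perl = TRUE)
  toks <- strsplit(x, " ", fixed = TRUE)[[1L]]
  toks[nzchar(toks)]
}

#' Remove stopwords from a token sequence
#'
#' Order-preserving exact-membership filter.
#'
#' @param tokens character vector of lowercased tokens.
#' @param stopwords character vector of stopwords.
#' @return filtered token vector.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!tokens %in% stopwords]
}

#' Remove drug-name tokens
#'
#' Removes tokens exactly matching one of the configured drug names (the
#' drug used to build a corpus appears in every message, carries no topical
#' information, and is therefore dropped). Matching is exact; misspellings
#' are retained.
#'
#' @param tokens character vector of lowercased tokens.
#' @param drug_names character vector of lowercased drug names (brand names
#'   and active-ingredient names).
#' @return filtered token vector.
#' @export
remove_drug_mentions <- function(tokens, drug_names) {
  tokens[!tokens %in% .to_lower(drug_names)]
}

#' Stem a token sequence
#'
#' Applies the French Snowball stemmer to each token. The neutral dosage token
#' `"dosemilligrams"` is protected and never stemmed; further protected tokens
#' can be supplied.
#'
#' @param tokens character vector of lowercased, punctuation-free tokens.
#' @param protect character vector of tokens exempt from stemming.
#' @return character vector of stems, same length and order.
#' @export
stem_tokens <- function(tokens, protect = "dosemilligrams") {
  if (length(tokens) == 0L) return(character(0))
  out <- tokens
  idx <- !(tokens %in% protect)
  out[idx] <- stem_french(tokens[idx])
  out
}

#' Build unigrams and adjacent bigrams
#'
#' Returns all unigrams in order followed by all adjacent-pair bigrams joined
#' with an underscore. Adjacency is measured in the input sequence, i.e. after
#' stopword/drug removal and stemming, so frequent collocations such as
#' "effet_secondair" survive filtering.
#'
#' @param tokens character vector (post-stemming sequence).
#' @param orders integer vector, subset of `c(1, 2)`.
#' @return character vector of n-gram tokens.
#' @examples
#' build_ngrams(c("a", "b", "c"))
#' @export
build_ngrams <- function(tokens, orders = c(1L, 2L)) {
  stopifnot(all(orders %in% c(1L, 2L)))
  out <- character(0)
  if (1L %in% orders) out <- c(out, tokens)
  if (2L %in% orders && length(tokens) >= 2L) {
    n <- length(tokens)
    out <- c(out, paste(tokens[-n], tokens[-1L], sep = "_"))
  }
  out
}

#' Preprocess one message into tokens
#'
#' Applies the full cleaning pipeline in order: dosage standardization,
#' lowercasing + punctuation removal + tokenization, stopword removal,
#' drug-name removal, French stemming, and n-gram construction.
#'
#' @param msg a single-row message data frame (columns `id`, `text`) or a
#'   character string; in the latter case `id` must be given.
#' @param config a [run_config()] list (fields `drug_names`, `stopwords`,
#'   `dosage_units`, `ngram_orders` are used).
#' @param id message identifier when `msg` is a bare string.
#' @return a list with elements `message_id` and `tokens`.
#' @export
preprocess_message <- function(msg, config = run_config(), id = NULL) {
  if (is.data.frame(msg)) {
    stopifnot(nrow(msg) == 1L)
    id <- msg$id[[1L]]
    text <- msg$text[[1L]]
  } else {
    stopifnot(is.character(msg), length(msg) == 1L)
    if (is.null(id)) stop("`id` is required when `msg` is a character string")
    text <- msg
  }
  toks <- tokenize_text(standardize_dosage(text, config$dosage_units))
  toks <- remove_stopwords(toks, config$stopwords)
  toks <- remove_drug_mentions(toks, config$drug_names)
  toks <- stem_tokens(toks)
  toks <- build_ngrams(toks, config$ngram_orders)
  list(message_id = id, tokens = toks)
}

#' Preprocess a whole corpus
#'
#' Vectorized version of [preprocess_message()] over a corpus data frame.
#' Stemming is memoized over the corpus vocabulary, so large corpora are
#' processed quickly.
#'
#' @param corpus data frame with columns `id` and `text` (as returned by
#'   [read_corpus()] or [generate_corpus()]).
#' @param config a [run_config()] list.
#' @return a list of tokenized documents, each a list with `message_id` and
#'   `tokens`, in corpus order.
#' @export
preprocess_corpus <- function(corpus, config = run_config()) {
  stopifnot(is.data.frame(corpus), all(c("id", "text") %in% names(corpus)))
  std <- standardize_dosage(corpus$text, config$dosage_units)
  std <- .to_lower(std)
  std <- gsub("[\\p{P}\\p{S}\\p{Z}\\s]+", " ", std, perl = TRUE)
  tok_lists <- strsplit(std, " ", fixed = TRUE)
  drop <- c(config$stopwords, .to_lower(config$drug_names))
  all_tokens <- unlist(tok_lists, use.names = FALSE)
  all_tokens <- all_tokens[nzchar(all_tokens)]
  uq <- setdiff(unique(all_tokens), drop)
  stem_map <- stem_tokens(uq)
  names(stem_map) <- uq
  out <- vector("list", nrow(corpus))
  for (i in seq_along(tok_lists)) {
    toks <- tok_lists[[i]]
    toks <- toks[nzchar(toks) & !toks %in% drop]
    toks <- unname(stem_map[toks])
    out[[i]] <- list(message_id = corpus$id[[i]],
                     tokens = build_ngrams(toks, config$ngram_orders))
  }
  out
}
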