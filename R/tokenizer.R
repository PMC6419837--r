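# SMILES tokenization: purely lexical. Multi-letter atoms ("Cl", "Br"),
# bracket expressions ("[N+]") and "%nn" ring-closure digits are single
# tokens; everything else is one character per token. "^" and "$" mark
# sequence begin/end.

TOKEN_BEGIN <- "^"
TOKEN_END <- "$"

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the token sequence a sequence model consumes.
#' Concatenating the tokens reproduces the input exactly. Chemical validity
#' is not required (the tokenizer is lexical), but an unmatched `[` is an
#' error.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens (without begin/end markers).
#' @examples
#' tokenize_smiles("CN1CCCC1c1cccnc1")  # nicotine: 16 tokens
#' tokenize_smiles("ClCCl")             # 3 tokens
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unmatched '[' in SMILES: ", smiles)
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" && i + 2L <= n &&
               grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L]))) {
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if ((ch == "C" && i < n && chars[i + 1L] == "l") ||
               (ch == "B" && i < n && chars[i + 1L] == "r")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Build a token vocabulary from a corpus
#'
#' The vocabulary is the set of all tokens appearing in the corpus plus the
#' begin (`^`) and end (`$`) markers. Ordering is deterministic: the two
#' specials first, then the remaining tokens sorted, so that two shuffles of
#' the same corpus yield identical vocabularies (and hence identical model
#' checkpoints).
#'
#' @param corpus character vector of SMILES strings.
#' @return object of class `smiles_vocabulary`: list with `tokens` (ordered)
#'   and `index` (named integer map, 1-based).
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus))
  if (length(corpus) == 0) stop("empty corpus")
  toks <- unique(unlist(lapply(corpus, tokenize_smiles)))
  toks <- setdiff(toks, c(TOKEN_BEGIN, TOKEN_END))
  tokens <- c(TOKEN_BEGIN, TOKEN_END, sort(toks, method = "radix"))
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "smiles_vocabulary")
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat(sprintf("SMILES vocabulary: %d tokens\n  %s\n", length(x$tokens),
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' @export
length.smiles_vocabulary <- function(x) length(x$tokens)

#' Encode a SMILES string as token ids
#'
#' Wraps the token sequence in begin/end markers and maps it to 1-based
#' integer ids under the vocabulary. `decode_ids()` inverts the mapping,
#' dropping the markers, so `decode_ids(encode_smiles(s, v)$ids, v)`
#' reproduces `s` exactly.
#'
#' @param smiles a single SMILES string ("" encodes to just the markers).
#' @param vocab a [build_vocabulary()] result.
#' @return list with `tokens` (including `^`/`$`) and `ids`.
#' @export
encode_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  tokens <- c(TOKEN_BEGIN, tokenize_smiles(smiles), TOKEN_END)
  ids <- vocab$index[tokens]
  if (anyNA(ids)) {
    missing <- unique(tokens[is.na(ids)])
    stop("token(s) not in vocabulary: ", paste(missing, collapse = " "))
  }
  list(tokens = tokens, ids = unname(ids))
}

#' @param ids integer vector of token ids.
#' @rdname encode_smiles
#' @export
decode_ids <- function(ids, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  if (any(ids < 1 | ids > length(vocab$tokens)))
    stop("token id out of range")
  toks <- vocab$tokens[ids]
  paste(toks[!(toks %in% c(TOKEN_BEGIN, TOKEN_END))], collapse = "")
}

#' Vocabulary serialization
#'
#' The vocabulary is stored as a JSON ordered token list, referenced by
#' path from model checkpoints.
#' @param vocab a `smiles_vocabulary`.
#' @param path JSON file path.
#' @rdname vocabulary_io
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname vocabulary_io
#' @export
read_vocabulary <- function(path) {
  tokens <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(tokens[1] == TOKEN_BEGIN, tokens[2] == TOKEN_END)
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "smiles_vocabulary")
}
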