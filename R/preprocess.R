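# Text normalization, sentence segmentation and tokenization.
#
# The pipeline defines an explicit tokenization contract rather than
# delegating to an external engine, so results do not depend on a tokenizer
# version: lowercase, ASCII-mapped dashes/quotes, whitespace collapsed;
# sentence boundaries at terminal punctuation with abbreviation guards;
# tokens split on whitespace/punctuation, keeping intra-word hyphens and
# numerals. All character offsets are 0-based, half-open.

# tokens: runs of alphanumerics, optionally joined by internal hyphens
TOKEN_REGEX <- "[[:alnum:]]+(?:-[[:alnum:]]+)*"

# abbreviations whose trailing period is not a sentence boundary
ABBREVIATIONS <- c("e.g", "i.e", "etc", "no", "dr", "mr", "mrs", "approx",
                   "fig", "vs", "ref")

#' Normalize raw report text
#'
#' Lowercases, maps unicode dashes and quotes to ASCII, strips control
#' characters and collapses whitespace runs to single spaces. Deterministic
#' and idempotent; empty input yields empty output.
#'
#' @param raw Character vector of raw report text.
#' @return Character vector of normalized text.
#' @examples
#' normalize_text("Tooth  #38 is  MESIOANGULAR.")
#' @export
normalize_text <- function(raw) {
  x <- as.character(raw)
  x <- gsub("[\u2010\u2011\u2012\u2013\u2014\u2015\u2212]", "-", x, perl = TRUE)
  x <- gsub("[\u2018\u2019\u201a\u201b]", "'", x, perl = TRUE)
  x <- gsub("[\u201c\u201d\u201e\u201f]", "\"", x, perl = TRUE)
  x <- gsub("[[:cntrl:]]", " ", x)
  x <- tolower(x)
  x <- gsub("[ \t\u00a0]+", " ", x, perl = TRUE)
  trimws(x)
}

# tokenize one normalized string; returns tokens plus 0-based start offsets
tokenize <- function(text) {
  m <- gregexpr(TOKEN_REGEX, text)[[1L]]
  if (m[[1L]] == -1L) {
    return(list(tokens = character(0), starts = integer(0)))
  }
  list(
    tokens = regmatches(text, list(m))[[1L]],
    starts = as.integer(m) - 1L
  )
}

# is the period ending at position `pos` (1-based index of ".") a guarded
# abbreviation or an intra-number decimal point rather than a boundary?
.guarded_period <- function(text, pos) {
  before <- substr(text, 1L, pos - 1L)
  after_chr <- substr(text, pos + 1L, pos + 1L)
  prev_chr <- substr(text, pos - 1L, pos - 1L)
  if (grepl("[0-9]", prev_chr) && grepl("[0-9]", after_chr)) return(TRUE)
  last_tok <- regmatches(before, regexpr("[a-z0-9]+(?:\\.[a-z0-9]+)*$", before))
  if (length(last_tok) == 0L) return(FALSE)
  if (last_tok %in% ABBREVIATIONS) return(TRUE)
  # single-letter tokens ("e.", initials) never end a sentence
  nchar(last_tok) == 1L && grepl("^[a-z]$", last_tok)
}

#' Segment a report into sentences and tokens
#'
#' Normalizes the input (idempotently) and splits it into sentences at
#' terminal punctuation (`.` and `;`), honoring abbreviation guards such as
#' "e.g." and "no." and decimal points. Each sentence is tokenized on
#' whitespace and punctuation; tokens retain intra-word hyphens and numerals.
#'
#' @param text Raw or normalized report text (single string).
#' @param report_id Identifier stored on the document.
#' @return A `cbct_document`: list with `report_id`, `raw_text`,
#'   `normalized_text` and `sentences`, a tibble with columns `index`
#'   (0-based), `text`, `start`, `end` (0-based half-open offsets into the
#'   normalized text) and list-columns `tokens` and `token_starts` (0-based
#'   offsets within the sentence).
#' @examples
#' doc <- segment_report("Two roots present. Contact with canal.")
#' doc$sentences$text
#' @export
segment_report <- function(text, report_id = "doc") {
  stopifnot(length(text) == 1L)
  raw <- as.character(text)
  norm <- normalize_text(raw)
  n <- nchar(norm)
  bounds <- integer(0)
  if (n > 0L) {
    for (pos in seq_len(n)) {
      ch <- substr(norm, pos, pos)
      if (ch == ";") {
        bounds <- c(bounds, pos)
      } else if (ch == "." && !.guarded_period(norm, pos)) {
        bounds <- c(bounds, pos)
      }
    }
  }
  pieces <- list()
  cur <- 1L
  for (b in c(bounds, n)) {
    if (b < cur) next
    seg <- substr(norm, cur, b)
    # trim but keep track of offsets
    lead <- nchar(seg) - nchar(sub("^ +", "", seg))
    seg_trim <- trimws(seg)
    if (nzchar(seg_trim)) {
      start0 <- cur - 1L + lead
      pieces[[length(pieces) + 1L]] <- list(
        text = seg_trim, start = start0, end = start0 + nchar(seg_trim)
      )
    }
    cur <- b + 1L
  }
  if (length(pieces) == 0L) {
    sentences <- tibble::tibble(
      index = integer(0), text = character(0),
      start = integer(0), end = integer(0),
      tokens = list(), token_starts = list()
    )
  } else {
    toks <- lapply(pieces, function(p) tokenize(p$text))
    sentences <- tibble::tibble(
      index = seq_along(pieces) - 1L,
      text = vapply(pieces, `[[`, character(1), "text"),
      start = vapply(pieces, `[[`, numeric(1), "start"),
      end = vapply(pieces, `[[`, numeric(1), "end"),
      tokens = lapply(toks, `[[`, "tokens"),
      token_starts = lapply(toks, `[[`, "starts")
    )
    sentences$start <- as.integer(sentences$start)
    sentences$end <- as.integer(sentences$end)
  }
  structure(
    list(
      report_id = report_id,
      raw_text = raw,
      normalized_text = norm,
      sentences = sentences
    ),
    class = "cbct_document"
  )
}

#' @export
print.cbct_document <- function(x, ...) {
  cat("<cbct_document>", x$report_id, "-", nrow(x$sentences), "sentence(s)\n")
  invisible(x)
}
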