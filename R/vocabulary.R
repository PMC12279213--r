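#' Build a symbol vocabulary from a training corpus
#'
#' The vocabulary maps every symbol occurring in the corpus, plus the
#' special tokens `[PAD]`, `[START]`, `[STOP]`, to contiguous integer
#' indices. Corpus symbols are ordered lexicographically so the mapping is
#' reproducible regardless of input order. Molecules that do not fit in
#' `max_length` symbols are excluded (their count is reported in the
#' `n_rejected` field and a warning).
#'
#' @param molecules Character vector of molecular strings.
#' @param max_length Number of token positions per molecule (default 32).
#' @return A `selfies_vocabulary`: list with `tokens`, `max_length`,
#'   `pad_id`, `start_id`, `stop_id`, `n_rejected`, `kept` (logical over
#'   the input).
#' @export
#' @examples
#' v <- build_vocabulary(c("[C][C][O]", "[C][=O]"), max_length = 8)
#' v$tokens
build_vocabulary <- function(molecules, max_length = 32L) {
  stopifnot(is.numeric(max_length), max_length >= 1)
  if (length(molecules) == 0) stop("empty molecule list")
  max_length <- as.integer(max_length)
  sym_list <- lapply(molecules, split_symbols)
  lens <- lengths(sym_list)
  kept <- lens <= max_length
  if (!any(kept)) stop("no molecule fits within max_length = ", max_length)
  n_rejected <- sum(!kept)
  if (n_rejected > 0)
    warning(n_rejected, " molecule(s) exceed max_length = ", max_length,
            " and were excluded")
  corpus_syms <- sort(unique(unlist(sym_list[kept])))
  tokens <- c("[PAD]", "[START]", "[STOP]", corpus_syms)
  structure(
    list(
      tokens = tokens, max_length = max_length,
      pad_id = 1L, start_id = 2L, stop_id = 3L,
      n_rejected = n_rejected, kept = kept
    ),
    class = "selfies_vocabulary"
  )
}

#' @export
print.selfies_vocabulary <- function(x, ...) {
  cat("<selfies_vocabulary> ", length(x$tokens), " tokens, max_length ",
      x$max_length, "\n", sep = "")
  invisible(x)
}

#' Tokenize a molecular string to a fixed-length integer sequence
#'
#' @param selfies Molecular string whose symbols are all in `vocab`.
#' @param vocab A [build_vocabulary()] result.
#' @return Integer vector of length `vocab$max_length`, right-padded with
#'   the `[PAD]` index.
#' @export
tokenize <- function(selfies, vocab) {
  stopifnot(inherits(vocab, "selfies_vocabulary"))
  syms <- split_symbols(selfies)
  if (length(syms) > vocab$max_length)
    stop("molecule has ", length(syms), " symbols, exceeding max_length = ",
         vocab$max_length)
  ids <- match(syms, vocab$tokens)
  if (anyNA(ids)) {
    unknown <- unique(syms[is.na(ids)])
    stop("symbol(s) not in vocabulary: ", paste(unknown, collapse = ", "))
  }
  c(ids, rep(vocab$pad_id, vocab$max_length - length(ids)))
}

#' Recover the molecular string from a token sequence
#'
#' Reads symbols until the first `[PAD]` or `[STOP]` token; `[START]`
#' tokens are dropped. Inverse of [tokenize()] on its image.
#'
#' @param ids Integer token sequence.
#' @param vocab A [build_vocabulary()] result.
#' @return Molecular string (possibly empty).
#' @export
detokenize <- function(ids, vocab) {
  stopifnot(inherits(vocab, "selfies_vocabulary"))
  stopifnot(all(ids >= 1 & ids <= length(vocab$tokens)))
  end <- which(ids == vocab$pad_id | ids == vocab$stop_id)
  if (length(end) > 0) ids <- ids[seq_len(min(end) - 1L)]
  ids <- ids[ids != vocab$start_id]
  paste(vocab$tokens[ids], collapse = "")
}
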