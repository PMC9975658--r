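#' Tokenize text for scoring and language-model use
#'
#' Lowercases, strips punctuation, and splits on whitespace. No stemming —
#' the goal is a reproducible, deterministic token stream.
#'
#' @param text Character vector of sentences.
#' @return A list of character vectors, one per input sentence.
#' @export
#' @examples
#' tokenize("The cat, the CAT!")
tokenize <- function(text) {
  cleaned <- tolower(gsub("[^[:alnum:][:space:]']", " ", text))
  lapply(strsplit(trimws(cleaned), "\\s+"),
         function(x) x[nzchar(x)])
}

#' Per-word probabilities of a sentence
#'
#' A `sentence_probabilities` object pairs each token of a sentence with
#' its conditional probability under some language model; it is the
#' interchange format between any word-probability provider (an n-gram
#' model here, a neural language model elsewhere) and the perplexity and
#' covariate computations.
#'
#' @param tokens Character vector of tokens.
#' @param probabilities Numeric vector in `(0, 1]`, one per token.
#' @param provider_id Optional label of the generating model.
#' @param sentence_id Optional sentence identifier.
#' @return A `sentence_probabilities` object.
#' @export
sentence_probabilities <- function(tokens, probabilities,
                                   provider_id = NULL, sentence_id = NULL) {
  if (length(tokens) != length(probabilities)) {
    stop_invalid_input("One probability per token is required.")
  }
  if (length(tokens) < 1L) {
    stop_invalid_input("A sentence needs at least one token.")
  }
  bad <- which(!is.finite(probabilities) | probabilities <= 0 |
                 probabilities > 1)
  if (length(bad) > 0) {
    stop_invalid_input(sprintf(
      "Probability out of (0, 1] at token index %d ('%s').",
      bad[1], tokens[bad[1]]))
  }
  structure(
    list(tokens = as.character(tokens),
         probabilities = as.numeric(probabilities),
         provider_id = provider_id, sentence_id = sentence_id),
    class = "sentence_probabilities"
  )
}

#' @export
print.sentence_probabilities <- function(x, ...) {
  cat(sprintf("<sentence_probabilities: %d tokens (%s)>\n",
              length(x$tokens), x$provider_id %||% "unknown provider"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sentence_probabilities <- function(x, ...) {
  tibble::tibble(index = seq_along(x$tokens), token = x$tokens,
                 probability = x$probabilities)
}

#' Sentence perplexity
#'
#' Perplexity summarizes how predictable a sentence is under a language
#' model: the inverse geometric mean of its word probabilities,
#' \deqn{\mathrm{PPL} = \left(\prod_{i=1}^{N} p_i\right)^{-1/N}
#'   = \exp\left(-\frac{1}{N}\sum_i \ln p_i\right) \ge 1,}
#' computed in log space so very long, very improbable sentences do not
#' underflow. Lower perplexity means higher predictability. The
#' length-normalized arithmetic-mean reading, \eqn{1 / \bar{p}}, is
#' available via `formula = "arithmetic"`.
#'
#' @param sp A [sentence_probabilities()] object (or a bare numeric vector
#'   of probabilities).
#' @param formula `"geometric"` (standard; default) or `"arithmetic"`.
#' @return A one-row tibble: `sentence_id`, `n_tokens`, `log_prob_sum`,
#'   `perplexity`.
#' @export
#' @examples
#' perplexity(c(0.5, 0.125))$perplexity # 4
perplexity <- function(sp, formula = c("geometric", "arithmetic")) {
  formula <- match.arg(formula)
  if (is.numeric(sp)) {
    sp <- sentence_probabilities(rep("?", length(sp)), sp)
  }
  if (!inherits(sp, "sentence_probabilities")) {
    stop_invalid_input("`sp` must be a sentence_probabilities object.")
  }
  lp <- log(sp$probabilities)
  n <- length(lp)
  ppl <- switch(formula,
    geometric = exp(-mean(lp)),
    arithmetic = 1 / mean(sp$probabilities)
  )
  tibble::tibble(
    sentence_id = sp$sentence_id %||% NA,
    n_tokens = n,
    log_prob_sum = sum(lp),
    perplexity = ppl
  )
}

#' Conditional probability of a target word
#'
#' Looks up the conditional probability of one token of a sentence — the
#' nuisance covariate used when specific target words of an item enter the
#' trial-level model.
#'
#' @param sp A [sentence_probabilities()] object.
#' @param target_index Token position (1-based).
#' @return A single probability.
#' @export
target_word_probability <- function(sp, target_index) {
  if (!inherits(sp, "sentence_probabilities")) {
    stop_invalid_input("`sp` must be a sentence_probabilities object.")
  }
  check_count(target_index, "target_index", lower = 1L)
  if (target_index > length(sp$tokens)) {
    stop_invalid_input(sprintf(
      "Target index %d exceeds sentence length %d.",
      target_index, length(sp$tokens)))
  }
  sp$probabilities[target_index]
}

#' Add-k smoothed n-gram word-probability provider
#'
#' Builds a unigram or bigram language model over a training corpus with
#' add-k smoothing and a closed vocabulary plus an out-of-vocabulary (OOV)
#' symbol, and returns a provider function mapping any sentence to a
#' [sentence_probabilities()] object. It is a small, fully deterministic
#' stand-in for heavier language models: conditional probabilities per
#' context sum to one by construction.
#'
#' For bigrams, the first word of a sentence is conditioned on a
#' start-of-sentence context; no end-of-sentence token is scored.
#'
#' @param corpus Character vector of training sentences (or a list of token
#'   vectors).
#' @param order 1 (unigram) or 2 (bigram).
#' @param k Add-k smoothing constant (`> 0`, default 1).
#' @return A function `f(sentence, sentence_id = NULL)` returning a
#'   [sentence_probabilities()]. The vocabulary (including `"<oov>"`) is
#'   attached as attribute `"vocabulary"`.
#' @export
#' @examples
#' p <- ngram_provider(c("a b a b"), order = 2, k = 0.001)
#' tidy(p("a b"))
ngram_provider <- function(corpus, order = 1, k = 1) {
  if (length(corpus) == 0) stop_invalid_input("Corpus must be nonempty.")
  check_number(k, "k", lower = 1e-12)
  if (!order %in% c(1, 2)) stop_invalid("`order` must be 1 or 2.")
  toks <- if (is.list(corpus)) corpus else tokenize(corpus)
  toks <- toks[lengths(toks) > 0]
  if (length(toks) == 0) stop_invalid_input("Corpus must be nonempty.")
  oov <- "<oov>"
  bos <- "<s>"
  vocab <- sort(unique(unlist(toks)))
  v_all <- c(vocab, oov)
  v_size <- length(v_all)
  uni <- table(factor(unlist(toks), levels = v_all))
  n_tokens <- sum(uni)
  map_vocab <- function(w) ifelse(w %in% vocab | w == bos, w, oov)
  if (order == 2) {
    ctx <- unlist(lapply(toks, function(s) c(bos, head(s, -1))))
    nxt <- unlist(toks)
    big <- table(paste(map_vocab(ctx), map_vocab(nxt)))
    ctx_tot <- table(factor(map_vocab(ctx), levels = c(v_all, bos)))
  }
  provider <- function(sentence, sentence_id = NULL) {
    s <- if (is.character(sentence) && length(sentence) == 1) {
      tokenize(sentence)[[1]]
    } else {
      as.character(sentence)
    }
    if (length(s) == 0) stop_invalid_input("Sentence has no tokens.")
    sm <- map_vocab(s)
    probs <- if (order == 1) {
      (as.numeric(uni[sm]) + k) / (n_tokens + k * v_size)
    } else {
      ctxs <- c(bos, head(sm, -1))
      key <- paste(ctxs, sm)
      cnt <- as.numeric(big[key])
      cnt[is.na(cnt)] <- 0
      (cnt + k) / (as.numeric(ctx_tot[ctxs]) + k * v_size)
    }
    sentence_probabilities(s, probs,
                           provider_id = sprintf("%s-gram add-%g",
                                                 order, k),
                           sentence_id = sentence_id)
  }
  attr(provider, "vocabulary") <- v_all
  provider
}

#' Score sentences with a word-probability provider
#'
#' Convenience wrapper: runs a provider over a vector of sentences and
#' returns one row per sentence with its perplexity and, optionally, the
#' probabilities of two target-word positions.
#'
#' @param sentences Character vector.
#' @param provider A provider function, e.g. from [ngram_provider()].
#' @param targets Optional two-column matrix/data frame of target token
#'   indices (target 1, target 2), one row per sentence.
#' @param formula Passed to [perplexity()].
#' @return A tibble: `sentence_id`, `n_tokens`, `perplexity` (and
#'   `target1_prob`, `target2_prob` when `targets` is given).
#' @export
score_predictability <- function(sentences, provider, targets = NULL,
                                 formula = "geometric") {
  out <- purrr::imap(sentences, function(s, i) {
    sp <- provider(s, sentence_id = i)
    row <- perplexity(sp, formula = formula)
    if (!is.null(targets)) {
      row$target1_prob <- target_word_probability(sp, targets[i, 1][[1]])
      row$target2_prob <- target_word_probability(sp, targets[i, 2][[1]])
    }
    row
  })
  dplyr::bind_rows(out)
}
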