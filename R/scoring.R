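#' Score an intelligibility (word identification) response
#'
#' Percentage of reference words correctly repeated in the response, using
#' case-insensitive, punctuation-free multiset matching: each reference
#' token type is matched `min(count in reference, count in response)`
#' times, so repeating a word more often than it occurs earns no extra
#' credit and word order is ignored.
#'
#' @param reference Reference sentence (string or token vector). Must be
#'   nonempty.
#' @param response Response sentence (string or token vector); may be
#'   empty.
#' @return Percent correct in `[0, 100]`.
#' @export
#' @examples
#' score_intelligibility("the cat sat", "the sat") # 66.67
score_intelligibility <- function(reference, response) {
  ref <- as_tokens(reference)
  resp <- as_tokens(response)
  if (length(ref) == 0) {
    stop_invalid_input("Reference sentence must contain at least one word.")
  }
  if (length(resp) == 0) return(0)
  ref_counts <- table(ref)
  resp_counts <- table(resp)
  common <- intersect(names(ref_counts), names(resp_counts))
  matched <- sum(pmin(ref_counts[common], resp_counts[common]))
  100 * matched / length(ref)
}

as_tokens <- function(x) {
  if (length(x) == 1L && is.character(x)) tokenize(x)[[1]] else
    as.character(x)
}

#' Score a word-order judgement trial
#'
#' A trial presents two target words from the sentence; the response is
#' correct iff the word chosen as "heard first" is the one that truly
#' occurred first.
#'
#' @param target1,target2 The two target words shown.
#' @param true_first The word that actually occurred first (must be one of
#'   the targets).
#' @param chosen_first The word the participant chose (must be one of the
#'   targets).
#' @return `1L` (correct) or `0L`.
#' @export
score_word_order <- function(target1, target2, true_first, chosen_first) {
  pair <- c(target1, target2)
  if (!true_first %in% pair) {
    stop_invalid_input("`true_first` is not one of the two targets.")
  }
  if (!chosen_first %in% pair) {
    stop_invalid_input("`chosen_first` is not one of the two targets.")
  }
  as.integer(chosen_first == true_first)
}

#' Word-order index per item
#'
#' From control-experiment responses — guesses of which of two words would
#' come first in a hypothetical sentence, without hearing it — computes per
#' item the percentage of control participants who guessed the true order.
#' This "word order index" enters the main trial-level model as a nuisance
#' covariate: items whose order is guessable from the words alone are
#' flagged by a high index.
#'
#' @param control_trials A tibble with columns `item` and `correct`
#'   (binary/logical), one row per control response.
#' @param items Optional vector of all item ids; items with no responses
#'   are returned with `NA` index and flagged.
#' @return A tibble: `item`, `n_responses`, `word_order_index` (percent in
#'   `[0, 100]`), `missing`.
#' @export
#' @examples
#' word_order_index(tibble::tibble(item = c(1, 1, 1, 1),
#'                                 correct = c(1, 1, 1, 0)))
word_order_index <- function(control_trials, items = NULL) {
  if (!all(c("item", "correct") %in% names(control_trials))) {
    stop_invalid_input("`control_trials` needs columns `item`, `correct`.")
  }
  if (any(!control_trials$correct %in% c(0, 1))) {
    stop_invalid_input("`correct` must be binary.")
  }
  idx <- control_trials |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(n_responses = dplyr::n(),
                     word_order_index = 100 * mean(.data$correct),
                     .groups = "drop")
  if (!is.null(items)) {
    idx <- tibble::tibble(item = items) |>
      dplyr::left_join(idx, by = "item") |>
      dplyr::mutate(n_responses = dplyr::coalesce(.data$n_responses, 0L))
  }
  dplyr::mutate(idx, missing = .data$n_responses == 0L)
}
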