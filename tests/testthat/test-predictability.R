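test_that("perplexity follows the closed forms", {
  expect_equal(perplexity(c(1, 1, 1))$perplexity, 1)
  expect_equal(perplexity(rep(1 / 50, 7))$perplexity, 50, tolerance = 1e-9)
  expect_equal(perplexity(c(0.5, 0.125))$perplexity, 4, tolerance = 1e-12)
  # arithmetic-mean variant
  expect_equal(perplexity(c(0.5, 0.25), formula = "arithmetic")$perplexity,
               1 / 0.375, tolerance = 1e-12)
  expect_error(
    sentence_probabilities(c("a", "b"), c(0.5, 0)),
    class = "speechsync_invalid_input")
})

test_that("perplexity is computed in log space without underflow", {
  ppl <- perplexity(rep(1e-6, 1000))$perplexity
  expect_true(is.finite(ppl))
  expect_equal(ppl, 1e6, tolerance = 1e-6)
})

test_that("appending certain tokens pulls perplexity toward one", {
  base <- c(0.2, 0.1, 0.05)
  ppls <- vapply(0:6, function(k) {
    perplexity(c(base, rep(1, k)))$perplexity
  }, numeric(1))
  expect_true(all(diff(ppls) < 0))
  expect_gt(min(ppls), 1)
})

test_that("unigram perplexity ignores token order", {
  prov <- ngram_provider(c("the cat sat on the mat", "a cat ran"),
                         order = 1, k = 0.5)
  p1 <- perplexity(prov("the cat sat"))$perplexity
  p2 <- perplexity(prov("sat the cat"))$perplexity
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("add-k probabilities match hand-computed values", {
  # corpus of a single token type, count 4; vocab with OOV has size 2
  prov <- ngram_provider("x x x x", order = 1, k = 1)
  expect_equal(prov("x")$probabilities, 5 / 6, tolerance = 1e-12)
  expect_equal(prov("zzz")$probabilities, 1 / 6, tolerance = 1e-12) # OOV

  # bigram with vanishing smoothing: p(b|a) -> 1 in "a b a b"
  prov2 <- ngram_provider("a b a b", order = 2, k = 1e-9)
  sp <- prov2("a b")
  expect_equal(sp$probabilities[2], 1, tolerance = 1e-6)

  # per-context probabilities sum to one (bigram, add-1)
  prov3 <- ngram_provider(c("a b", "b a", "a a"), order = 2, k = 1)
  vocab <- attr(prov3, "vocabulary")
  total <- sum(vapply(vocab, function(w) {
    prov3(c("a", w))$probabilities[2]
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-9)

  expect_error(ngram_provider(character(0)),
               class = "speechsync_invalid_input")
})

test_that("target-word probabilities are plain lookups", {
  prov <- ngram_provider(c("the cat sat"), order = 1, k = 1)
  sp <- prov("the cat sat")
  expect_equal(target_word_probability(sp, 1), sp$probabilities[1])
  expect_equal(target_word_probability(sp, 3), sp$probabilities[3])
  expect_error(target_word_probability(sp, 4),
               class = "speechsync_invalid_input")
})

test_that("score_predictability returns one row per sentence", {
  prov <- ngram_provider(c("the cat sat on the mat"), order = 1, k = 1)
  out <- score_predictability(c("the cat", "the mat sat"), prov,
                              targets = rbind(c(1, 2), c(1, 3)))
  expect_equal(nrow(out), 2)
  expect_equal(out$n_tokens, c(2, 3))
  expect_true(all(out$perplexity >= 1))
  expect_true(all(out$target1_prob > 0 & out$target1_prob <= 1))
})
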