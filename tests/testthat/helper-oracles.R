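# Independent oracles, written against the constraint definitions directly
# (loops and explicit checks, no reuse of package internals).

# Brute-force language checker: re-derives every profile constraint from
# scratch on the raw word strings.
oracle_language_ok <- function(words, profile_name) {
  if (length(words) != 4) return(FALSE)
  if (any(nchar(words) != 6)) return(FALSE)
  pools <- list(
    exp1 = list(v = c("a", "u", "i", "o"), c = c("p", "t", "k", "b", "d", "g", "n")),
    exp2 = list(
      v = c("a", "e", "i", "o", "u"),
      c = c("b", "d", "g", "p", "t", "k", "f", "v", "s", "m", "n", "l", "r")
    )
  )[[profile_name]]
  syls <- lapply(words, function(w) {
    sapply(c(1, 3, 5), function(i) substr(w, i, i + 1))
  })
  for (s in unlist(syls)) {
    if (!substr(s, 1, 1) %in% pools$c) return(FALSE)
    if (!substr(s, 2, 2) %in% pools$v) return(FALSE)
  }
  for (ws in syls) {
    if (length(unique(ws)) != 3) return(FALSE)
  }
  if (length(unique(words)) != 4) return(FALSE)
  if (profile_name == "exp2") {
    for (ws in syls) {
      vw <- substr(ws, 2, 2)
      if (length(unique(vw)) != 3) return(FALSE)
    }
    cons <- substr(unlist(syls), 1, 1)
    if (any(duplicated(cons))) return(FALSE)
    vcounts <- sort(as.integer(table(substr(unlist(syls), 2, 2))), decreasing = TRUE)
    if (!identical(vcounts, c(3L, 3L, 2L, 2L, 2L))) return(FALSE)
  }
  TRUE
}

# Exhaustive enumeration of all word orders of length n_words * n_repeats
# satisfying: exact occurrence counts, no immediate repeats, ordered-pair
# counts differing by at most 1. Only feasible for tiny cases.
oracle_enumerate_orders <- function(n_words, n_repeats) {
  total <- n_words * n_repeats
  results <- list()
  recurse <- function(seq_so_far, remaining) {
    if (length(seq_so_far) == total) {
      trans <- paste(seq_so_far[-total], seq_so_far[-1])
      lv <- as.vector(outer(1:n_words, 1:n_words, paste))
      lv <- lv[rep(diag(n_words) == 0, length.out = length(lv))]
      counts <- table(factor(trans, levels = lv))
      if (max(counts) - min(counts) <= 1) {
        results[[length(results) + 1]] <<- seq_so_far
      }
      return(invisible())
    }
    for (w in seq_len(n_words)) {
      if (remaining[w] == 0) next
      if (length(seq_so_far) > 0 && w == seq_so_far[length(seq_so_far)]) next
      remaining[w] <- remaining[w] - 1
      recurse(c(seq_so_far, w), remaining)
      remaining[w] <- remaining[w] + 1
    }
  }
  recurse(integer(0), rep(n_repeats, n_words))
  results
}

# Corrupt a valid language in a random constraint-violating way; returns the
# word strings.
corrupt_language <- function(words, profile_name) {
  mode <- sample(3, 1)
  w <- words
  if (mode == 1) {
    # repeat a syllable within a word
    syl <- substr(w[1], 1, 2)
    w[1] <- paste0(syl, syl, substr(w[1], 5, 6))
  } else if (mode == 2) {
    # duplicate a whole word
    w[2] <- w[1]
  } else {
    # out-of-pool consonant
    substr(w[3], 1, 1) <- "z"
  }
  w
}
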