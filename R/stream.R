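#' Generate a pseudo-random word order with balanced transitions
#'
#' Produces an ordering of `n_words` word indices, each occurring exactly
#' `n_repeats` times, such that (i) no word occurs twice in a row and (ii)
#' every ordered pair of distinct words is used as a transition "equally
#' often" — implemented as maximal balance: with `T = n_words * n_repeats - 1`
#' transitions over `n_words * (n_words - 1)` ordered pairs, every pair count
#' is `floor(T/P)` or `ceil(T/P)`, so the counts differ by at most 1. (Exact
#' equality is impossible when `P` does not divide `T`, e.g. 39 or 95
#' transitions over 12 pairs.)
#'
#' Internally the generator first fixes a balanced transition-count matrix
#' consistent with the word occurrence counts, then walks it with a
#' randomized Hierholzer Eulerian-path traversal, which is linear in the
#' stream length and cannot dead-end.
#'
#' @param n_words Number of distinct words (4 in the published designs).
#' @param n_repeats Occurrences of each word (10 for the 40-word streams,
#'   24 for the 96-word streams).
#' @param seed Integer seed for reproducibility.
#' @return An integer vector of word indices (1-based) of length
#'   `n_words * n_repeats`, of class `seg_word_order`.
#' @examples
#' length(generate_word_order(n_repeats = 10, seed = 1))
#' @export
generate_word_order <- function(n_words = 4L, n_repeats, seed = NULL) {
  n_words <- as.integer(n_words)
  n_repeats <- as.integer(n_repeats)
  stopifnot(n_repeats >= 1L)
  if (n_words < 2L && n_repeats > 1L) {
    stop("no-repeat constraint unsatisfiable with fewer than 2 words", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  total <- n_words * n_repeats
  if (total == 1L) {
    return(structure(1L, class = "seg_word_order"))
  }

  for (attempt in 1:100) {
    mat <- balanced_pair_matrix(n_words, n_repeats)
    if (is.null(mat)) next
    seq_out <- eulerian_path(mat$counts, mat$first)
    if (!is.null(seq_out) && length(seq_out) == total) {
      return(structure(seq_out, class = "seg_word_order"))
    }
  }
  stop("could not construct a balanced word order", call. = FALSE)
}

## Balanced ordered-pair count matrix for a no-repeat sequence in which every
## word occurs n_repeats times. Row sums must equal out-degrees
## (n_repeats, minus 1 for the last word) and column sums the in-degrees
## (n_repeats, minus 1 for the first word); all entries floor or ceil of T/P.
balanced_pair_matrix <- function(n_words, n_repeats) {
  total_trans <- n_words * n_repeats - 1L
  n_pairs <- n_words * (n_words - 1L)
  q <- total_trans %/% n_pairs
  r <- total_trans %% n_pairs

  ends <- sample(n_words, 2L, replace = FALSE)
  first <- ends[1L]
  last <- ends[2L]

  out_deg <- rep(n_repeats, n_words)
  out_deg[last] <- out_deg[last] - 1L
  in_deg <- rep(n_repeats, n_words)
  in_deg[first] <- in_deg[first] - 1L

  # extras: how many cells in each row/column get q+1 instead of q
  e <- out_deg - (n_words - 1L) * q
  f <- in_deg - (n_words - 1L) * q
  if (any(e < 0L) || any(e > n_words - 1L) ||
    any(f < 0L) || any(f > n_words - 1L) || sum(e) != r) {
    return(NULL)
  }

  x <- find_extra_cells(e, f, n_words)
  if (is.null(x)) {
    return(NULL)
  }

  counts <- matrix(q, n_words, n_words) + x
  diag(counts) <- 0L
  list(counts = counts, first = first)
}

## 0/1 off-diagonal matrix with row sums e and column sums f. Randomized
## greedy over rows, filling the columns with most remaining demand first;
## the instance is tiny (at most n*(n-1) cells) so retries are cheap.
find_extra_cells <- function(e, f, n_words) {
  x_zero <- matrix(0L, n_words, n_words)
  if (sum(e) == 0L) {
    return(x_zero)
  }
  for (try in 1:200) {
    fx <- f
    x <- x_zero
    ok <- TRUE
    for (i in sample(seq_len(n_words))) {
      if (e[i] == 0L) next
      avail <- setdiff(which(fx > 0L), i)
      if (length(avail) < e[i]) {
        ok <- FALSE
        break
      }
      pick <- avail[order(-fx[avail], runif(length(avail)))][seq_len(e[i])]
      fx[pick] <- fx[pick] - 1L
      x[i, pick] <- 1L
    }
    if (ok && all(fx == 0L)) {
      return(x)
    }
  }
  NULL
}

## Randomized Hierholzer traversal of the transition multigraph; returns the
## node sequence (length = edges + 1) or NULL if the edge set is disconnected.
eulerian_path <- function(counts, first) {
  n <- nrow(counts)
  remaining <- counts
  path <- integer(sum(counts) + 1L)
  stack <- integer(sum(counts) + 1L)
  stack[1L] <- first
  top <- 1L
  out <- integer(0)
  while (top > 0L) {
    v <- stack[top]
    nxt <- which(remaining[v, ] > 0L)
    if (length(nxt) == 0L) {
      out <- c(out, v)
      top <- top - 1L
    } else {
      w <- if (length(nxt) == 1L) nxt else sample(nxt, 1L)
      remaining[v, w] <- remaining[v, w] - 1L
      top <- top + 1L
      stack[top] <- w
    }
  }
  if (any(remaining > 0L)) {
    return(NULL)
  }
  rev(out)
}

#' Expand a word order into a syllable token stream
#'
#' @param language A `seg_language`.
#' @param order A word order from [generate_word_order()] (integer indices
#'   into the language's four words).
#' @return A tibble with one row per syllable token: `stream_index`,
#'   `word_index`, `word`, `position` (`"initial"/"medial"/"final"`),
#'   `syllable`.
#' @examples
#' lang <- builtin_languages()$L0
#' build_stream(lang, generate_word_order(n_repeats = 10, seed = 1))
#' @export
build_stream <- function(language, order) {
  stopifnot(inherits(language, "seg_language"))
  order <- as.integer(order)
  stopifnot(all(order >= 1L), all(order <= length(language$words)))
  positions <- c("initial", "medial", "final")
  tibble::tibble(
    stream_index = seq_len(3L * length(order)),
    word_index = rep(order, each = 3L),
    word = rep(language$words[order], each = 3L),
    position = rep(positions, times = length(order)),
    syllable = as.vector(t(language$syllables[order, , drop = FALSE]))
  )
}

#' Syllable-to-syllable transitional probabilities of a stream
#'
#' Computes bigram counts and forward transitional probabilities
#' `TP(a -> b) = count(a, b) / count(a as antecedent)` over consecutive
#' syllable tokens. The stream-final syllable contributes no outgoing
#' transition. Each bigram is classified as `"within"` (word-internal:
#' initial->medial or medial->final) or `"between"` (word-final ->
#' word-initial across a boundary).
#'
#' @param tokens A token tibble from [build_stream()] (needs `syllable` and
#'   `position` columns).
#' @return A tibble with columns `from`, `to`, `type`, `n`, `tp`.
#' @examples
#' lang <- builtin_languages()$L0
#' st <- build_stream(lang, generate_word_order(n_repeats = 10, seed = 1))
#' transition_stats(st)
#' @export
transition_stats <- function(tokens) {
  if (nrow(tokens) < 2L) {
    stop("need at least two syllable tokens to compute transitions", call. = FALSE)
  }
  n <- nrow(tokens)
  bigrams <- tibble::tibble(
    from = tokens$syllable[-n],
    to = tokens$syllable[-1L],
    type = ifelse(tokens$position[-n] == "final", "between", "within")
  )
  bigrams |>
    dplyr::count(.data$from, .data$to, .data$type, name = "n") |>
    dplyr::group_by(.data$from) |>
    dplyr::mutate(tp = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
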