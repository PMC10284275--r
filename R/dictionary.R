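#' Re-code a mean Likert rating into a dictionary score
#'
#' Raw lexicon terms are rated on 7-point Likert scales (mean of the
#' touched-feeling and elevation dimensions, averaged over raters). Ratings
#' are re-coded to the integer dictionary score: 0 for ratings below 2.5,
#' 1 for ratings in the closed band [2.5, 5.5], 2 for ratings above 5.5.
#'
#' @param mean_rating Numeric vector of mean ratings, each in [1, 7].
#' @return Integer vector of scores in {0, 1, 2}.
#' @examples
#' recode_rating(c(2, 4, 6))
#' @export
recode_rating <- function(mean_rating) {
  if (!is.numeric(mean_rating) || any(!is.finite(mean_rating)))
    stop("mean_rating must be finite numeric")
  if (any(mean_rating < 1 | mean_rating > 7))
    stop("mean_rating must lie in [1, 7]")
  score <- integer(length(mean_rating))
  score[mean_rating >= 2.5 & mean_rating <= 5.5] <- 1L
  score[mean_rating > 5.5] <- 2L
  score
}

#' Default degree-word multipliers
#'
#' The four degree levels and their weights: "a little" 0.75, "more" 1.25,
#' "very" 1.5, "most" 2. Fully user-configurable; these defaults name the
#' English glosses of the levels.
#'
#' @return Named numeric vector of multipliers.
#' @export
default_degree_words <- function() {
  c("a little" = 0.75, "more" = 1.25, "very" = 1.5, "most" = 2)
}

#' Build an emotion dictionary
#'
#' Assembles the scoring lexicon from rated terms plus the modifier
#' lexicons (negators, which flip the weight to -1, and degree words,
#' which multiply it). The three term sets must be pairwise disjoint.
#'
#' @param rated_terms Data frame with columns `term` (character) and
#'   `mean_rating` (numeric in [1, 7]), or a named numeric vector of
#'   already re-coded scores in {0, 1, 2}.
#' @param negators Character vector of negator terms (default `"not"`).
#' @param degree_words Named numeric vector mapping degree terms to strictly
#'   positive multipliers (default [default_degree_words()]).
#' @return An object of class `emotion_dictionary`: a list with elements
#'   `entries` (named integer vector of scores), `negators` (character) and
#'   `degree_words` (named numeric).
#' @examples
#' d <- build_dictionary(data.frame(term = c("kind", "moving", "meh"),
#'                                  mean_rating = c(6.1, 4.0, 1.5)))
#' d$entries
#' @export
build_dictionary <- function(rated_terms,
                             negators = "not",
                             degree_words = default_degree_words()) {
  if (is.data.frame(rated_terms)) {
    if (!all(c("term", "mean_rating") %in% names(rated_terms)))
      stop("rated_terms needs columns 'term' and 'mean_rating'")
    terms <- as.character(rated_terms$term)
    scores <- recode_rating(rated_terms$mean_rating)
  } else {
    terms <- names(rated_terms)
    scores <- as.integer(rated_terms)
    if (length(terms) != length(scores) ||
        (length(scores) && !all(scores %in% 0:2)))
      stop("pre-scored entries must be a named vector with scores in {0,1,2}")
  }
  names(scores) <- terms
  negators <- as.character(negators)
  if (length(degree_words) && (is.null(names(degree_words)) ||
      any(!nzchar(names(degree_words)))))
    stop("degree_words must be a named numeric vector")
  degree_words <- vapply(degree_words, as.numeric, numeric(1))
  new_emotion_dictionary(scores, negators, degree_words)
}

new_emotion_dictionary <- function(entries, negators, degree_words) {
  d <- structure(list(entries = entries, negators = negators,
                      degree_words = degree_words),
                 class = "emotion_dictionary")
  validate_dictionary(d)
  d
}

validate_dictionary <- function(d) {
  stopifnot(inherits(d, "emotion_dictionary"))
  if (length(d$entries) && !all(d$entries %in% 0:2))
    stop("entry scores must all be 0, 1 or 2")
  if (anyDuplicated(names(d$entries)))
    stop("duplicate entry terms: ",
         paste(unique(names(d$entries)[duplicated(names(d$entries))]),
               collapse = ", "))
  if (length(d$degree_words) && any(d$degree_words <= 0))
    stop("degree multipliers must be strictly positive")
  sets <- list(entry = names(d$entries), negator = d$negators,
               degree = names(d$degree_words))
  all_terms <- unlist(sets, use.names = FALSE)
  dup <- unique(all_terms[duplicated(all_terms)])
  if (length(dup))
    stop("terms present in more than one lexicon: ",
         paste(dup, collapse = ", "))
  invisible(d)
}

#' @export
print.emotion_dictionary <- function(x, ...) {
  cat("<emotion_dictionary>\n")
  tab <- table(factor(x$entries, levels = 0:2))
  cat(sprintf("  %d entries (score 0: %d, 1: %d, 2: %d)\n",
              length(x$entries), tab[["0"]], tab[["1"]], tab[["2"]]))
  cat(sprintf("  %d negators, %d degree words\n",
              length(x$negators), length(x$degree_words)))
  invisible(x)
}

#' Write / read a dictionary as TSV
#'
#' UTF-8, tab-separated, header `term  role  value`; `role` is one of
#' `entry`, `negator`, `degree`; `value` is the 0/1/2 score for entries,
#' empty for negators, and a positive decimal multiplier for degree words.
#' `read_dictionary(write_dictionary(d, path))` restores `d` exactly.
#'
#' @param dict An `emotion_dictionary`.
#' @param path File path.
#' @return `read_dictionary` returns an `emotion_dictionary`;
#'   `write_dictionary` returns `path` invisibly.
#' @export
write_dictionary <- function(dict, path) {
  validate_dictionary(dict)
  df <- rbind(
    data.frame(term = names(dict$entries),
               role = rep("entry", length(dict$entries)),
               value = as.character(dict$entries)),
    data.frame(term = dict$negators,
               role = rep("negator", length(dict$negators)),
               value = rep("", length(dict$negators))),
    data.frame(term = names(dict$degree_words),
               role = rep("degree", length(dict$degree_words)),
               value = format(dict$degree_words, digits = 17,
                              scientific = FALSE, trim = TRUE))
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   colClasses = "character", encoding = "UTF-8")
  if (!identical(names(df), c("term", "role", "value")))
    stop("dictionary file must have header: term, role, value")
  bad_role <- which(!df$role %in% c("entry", "negator", "degree"))
  if (length(bad_role))
    stop("unknown role '", df$role[bad_role[1]], "' at line ",
         bad_role[1] + 1L)
  ent <- df[df$role == "entry", ]
  scores <- suppressWarnings(as.integer(ent$value))
  bad <- which(is.na(scores) | !scores %in% 0:2 | scores != as.numeric(ent$value))
  if (length(bad))
    stop("invalid entry score '", ent$value[bad[1]], "' at line ",
         match(rownames(ent)[bad[1]], rownames(df)) + 1L)
  names(scores) <- ent$term
  deg <- df[df$role == "degree", ]
  mult <- suppressWarnings(as.numeric(deg$value))
  badd <- which(!is.finite(mult) | mult <= 0)
  if (length(badd))
    stop("invalid degree multiplier '", deg$value[badd[1]], "' at line ",
         match(rownames(deg)[badd[1]], rownames(df)) + 1L)
  names(mult) <- deg$term
  new_emotion_dictionary(scores, df$term[df$role == "negator"], mult)
}
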