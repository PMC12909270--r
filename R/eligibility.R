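#' Eligibility for Yes/No classification
#'
#' A participant-dimension is eligible only if both classes have at least
#' `min_per_class` trials; with fewer, the classifier cannot be trained
#' reliably for both classes and the participant is excluded from that
#' dimension's analysis. Trials without a response are ignored.
#'
#' @param responses character vector of `"yes"` / `"no"` / `"none"`.
#' @param min_per_class minimum trials per class (boundary inclusive).
#' @return logical flag.
#' @export
eligibility_classification <- function(responses, min_per_class = 20) {
  n_yes <- sum(responses == "yes")
  n_no <- sum(responses == "no")
  n_yes >= min_per_class && n_no >= min_per_class
}

#' Eligibility for rating regression
#'
#' Ratings must be sufficiently variable to fit a regression model:
#' standard deviation at least `min_sd` rating units and at least
#' `min_unique` distinct values.
#'
#' @param ratings numeric vector of 0-100 ratings (NAs dropped).
#' @param min_unique minimum count of distinct rating values.
#' @param min_sd minimum standard deviation, rating units.
#' @return logical flag.
#' @export
eligibility_regression <- function(ratings, min_unique = 5, min_sd = 1) {
  ratings <- ratings[!is.na(ratings)]
  if (length(ratings) < 2) return(FALSE)
  stats::sd(ratings) >= min_sd && length(unique(ratings)) >= min_unique
}

#' Balance two classes by majority subsampling
#'
#' Randomly subsamples the majority class down to the minority count so
#' that 50% is the true chance level of the classifier. Deterministic
#' given the seed; balanced input is returned unchanged (all indices).
#'
#' @param labels vector with exactly two distinct values present.
#' @param seed integer seed.
#' @return sorted integer vector of retained trial indices.
#' @export
balance_classes <- function(labels, seed) {
  tab <- table(labels)
  if (length(tab) != 2)
    stop_invalid("need exactly two classes present, got %d", length(tab))
  n_min <- min(tab)
  set.seed(seed)
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  sort(keep)
}
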