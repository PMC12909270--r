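#' Behavioral summary table
#'
#' Per participant and question dimension: Yes and No trial counts, the
#' count of missing responses, the mean 0-100 rating, and the
#' vaping-status group.
#'
#' @param responses long data.frame with columns `participant`, `group`,
#'   `dimension`, `response`, `rating` (one row per trial).
#' @return data.frame of class `behavioral_table`.
#' @export
behavioral_table <- function(responses) {
  need <- c("participant", "group", "dimension", "response", "rating")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop_invalid("responses lacks columns: %s",
                                 paste(miss, collapse = ", "))
  key <- interaction(responses$participant, responses$dimension, drop = TRUE)
  agg <- function(f) as.numeric(tapply(seq_len(nrow(responses)), key, f))
  idx <- tapply(seq_len(nrow(responses)), key, function(i) i[1])
  out <- data.frame(
    participant = responses$participant[idx],
    group = responses$group[idx],
    dimension = responses$dimension[idx],
    yes_count = agg(function(i) sum(responses$response[i] == "yes")),
    no_count = agg(function(i) sum(responses$response[i] == "no")),
    missing_count = agg(function(i) sum(responses$response[i] == "none")),
    mean_rating = agg(function(i) mean(responses$rating[i], na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$dimension, out$participant), ]
  rownames(out) <- NULL
  class(out) <- c("behavioral_table", "data.frame")
  out
}

#' Group descriptives of choices and ratings
#'
#' Median / min / max of Yes and No counts and mean (SD) of ratings, per
#' vaping-status group and overall, for each question dimension --
#' mirroring the usual stratified descriptive table. Empty groups yield
#' missing values with a flag.
#'
#' @param table a [behavioral_table()].
#' @return data.frame: dimension, group (including `"all"`), n,
#'   yes_mdn/min/max, no_mdn/min/max, rating_mean, rating_sd, flagged.
#' @export
behavior_descriptives <- function(table) {
  stopifnot(nrow(table) > 0)
  groups <- c("all", unique(table$group))
  out <- list()
  for (dim in unique(table$dimension)) {
    td <- table[table$dimension == dim, ]
    for (g in groups) {
      tg <- if (g == "all") td else td[td$group == g, ]
      if (nrow(tg) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          dimension = dim, group = g, n = 0L, yes_mdn = NA_real_,
          yes_min = NA_real_, yes_max = NA_real_, no_mdn = NA_real_,
          no_min = NA_real_, no_max = NA_real_, rating_mean = NA_real_,
          rating_sd = NA_real_, flagged = TRUE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        dimension = dim, group = g, n = nrow(tg),
        yes_mdn = stats::median(tg$yes_count), yes_min = min(tg$yes_count),
        yes_max = max(tg$yes_count),
        no_mdn = stats::median(tg$no_count), no_min = min(tg$no_count),
        no_max = max(tg$no_count),
        rating_mean = mean(tg$mean_rating),
        rating_sd = stats::sd(tg$mean_rating), flagged = FALSE)
    }
  }
  do.call(rbind, out)
}

#' One-way ANOVA with Bonferroni post hoc tests
#'
#' Classical one-way ANOVA of a per-participant value over group labels,
#' followed by all pairwise equal-variance two-sample t tests with
#' Bonferroni-adjusted p values (`min(1, n_pairs * p)`). Groups with
#' fewer than 2 members are excluded with a warning.
#'
#' @param values numeric, one per participant.
#' @param groups group labels, same length.
#' @param alpha significance level applied to adjusted p values.
#' @return list: `F`, `p`, `df` (length 2), `posthoc` (data.frame:
#'   group1, group2, t, p_raw, p_adj, significant), `degenerate`.
#' @export
oneway_anova_bonferroni <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("excluding group(s) with < 2 members: %s",
                    paste(small, collapse = ", ")))
    keep <- !(as.character(g) %in% small)
    values <- values[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop_invalid("need at least 2 groups with >= 2 members")

  if (stats::var(values) < 1e-24) {
    pairs <- t(utils::combn(levels(g), 2))
    return(list(F = 0, p = 1, df = c(nlevels(g) - 1, length(values) - nlevels(g)),
                posthoc = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                                     t = 0, p_raw = 1, p_adj = 1,
                                     significant = FALSE),
                degenerate = TRUE))
  }

  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  pairs <- t(utils::combn(levels(g), 2))
  ph <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- values[g == pairs[i, 1]]; b <- values[g == pairs[i, 2]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(group1 = pairs[i, 1], group2 = pairs[i, 2],
               t = unname(tt$statistic), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, ph)
  ph$p_adj <- stats::p.adjust(ph$p_raw, method = "bonferroni")
  ph$significant <- ph$p_adj < alpha
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = s[["Df"]], posthoc = ph, degenerate = FALSE)
}

#' Image-level correlation of Yes counts with mean ratings
#'
#' Per image: the number of Yes responses across participants and the
#' mean post-experimental rating; Pearson correlation (two-sided p)
#' between the two across images, and the analogous correlation for No
#' counts. With no missing responses the No count is an affine transform
#' of the Yes count, so the two correlations are exact negatives.
#'
#' @param responses long trial data.frame (see [behavioral_table()]).
#' @param dimension question dimension to analyse.
#' @return list: `per_image` data.frame, `r_yes`, `p_yes`, `r_no`,
#'   `p_no`, `flagged` (TRUE when a correlation is undefined through zero
#'   variance).
#' @export
image_level_correlation <- function(responses, dimension) {
  df <- responses[responses$dimension == dimension, ]
  if (nrow(df) == 0) stop_invalid("no trials for dimension '%s'", dimension)
  imgs <- unique(df$image_id)
  if (length(imgs) < 3) stop_invalid("need at least 3 images")
  per <- do.call(rbind, lapply(imgs, function(im) {
    di <- df[df$image_id == im, ]
    data.frame(image_id = im,
               yes_count = sum(di$response == "yes"),
               no_count = sum(di$response == "no"),
               mean_rating = mean(di$rating, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  safe_cor <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
      return(list(estimate = NA_real_, p.value = NA_real_))
    ct <- stats::cor.test(x, y)
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  cy <- safe_cor(per$yes_count, per$mean_rating)
  cn <- safe_cor(per$no_count, per$mean_rating)
  list(per_image = per, r_yes = cy$estimate, p_yes = cy$p.value,
       r_no = cn$estimate, p_no = cn$p.value,
       flagged = is.na(cy$estimate) || is.na(cn$estimate))
}
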