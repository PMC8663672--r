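#' Score the System Usability Scale (SUS)
#'
#' Standard SUS scoring: ten items on a 1-5 Likert scale, odd items
#' positively worded, even items negatively worded. Each odd item
#' contributes `r - 1`, each even item `5 - r`, and the summed
#' contributions are multiplied by 2.5, yielding a score between 0 and
#' 100 (higher = better usability; about 70 is the conventional
#' acceptability threshold). No proration: all ten items must be present.
#'
#' @param responses Integer vector of exactly 10 responses in `[1, 5]`,
#'   in item order (item 1 first).
#' @return A single score in `[0, 100]`; the attainable image is the grid
#'   `{0, 2.5, 5, ..., 100}`.
#' @examples
#' sus_score(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1))  # 100
#' sus_score(rep(3, 10))                        # 50
#' @export
sus_score <- function(responses) {
  if (length(responses) != 10 || anyNA(responses)) {
    stop("SUS requires exactly 10 non-missing responses", call. = FALSE)
  }
  if (any(responses < 1 | responses > 5 | responses != round(responses))) {
    stop("SUS responses must be integers in [1, 5]", call. = FALSE)
  }
  odd <- responses[seq(1, 9, by = 2)]
  even <- responses[seq(2, 10, by = 2)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' Scale configuration for Likert-type instruments
#'
#' Describes how an instrument's items aggregate into subscale and total
#' scores: the response range, the item-to-subscale mapping, and the
#' reverse-keyed item set. Scores are item means on the native response
#' scale (not sums), so a 12-item instrument on a 1-5 scale scores
#' between 1 and 5. The item-to-subscale mappings shipped by
#' [default_scale_configs()] are editable placeholders: the instruments
#' are copyrighted and their item keys are not redistributed here, so any
#' real analysis must supply the licensed mapping.
#'
#' @param instrument Instrument name (e.g. `"AQ-SF"`).
#' @param items Character vector of all item ids.
#' @param range Numeric `c(min, max)` of the response scale.
#' @param subscales Named list mapping subscale name to a character vector
#'   of item ids; subscales must not share items.
#' @param reverse_keyed Character vector of reverse-keyed item ids
#'   (reflected as `r -> min + max - r` before aggregation).
#' @param min_answered_prop Minimum proportion of a (sub)scale's items
#'   that must be answered for a prorated score (default 0.8); below it
#'   the score is `NA`.
#' @return A `scale_config` object.
#' @export
scale_config <- function(instrument, items, range = c(1, 5),
                         subscales = list(), reverse_keyed = character(),
                         min_answered_prop = 0.8) {
  items <- as.character(items)
  stopifnot(length(range) == 2, range[1] < range[2],
            min_answered_prop > 0, min_answered_prop <= 1)
  sub_items <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(sub_items)) {
    stop("subscales must not share items", call. = FALSE)
  }
  if (!all(sub_items %in% items) || !all(reverse_keyed %in% items)) {
    stop("subscale and reverse-keyed item ids must be declared in items",
         call. = FALSE)
  }
  structure(list(instrument = instrument, items = items, range = range,
                 subscales = subscales,
                 reverse_keyed = as.character(reverse_keyed),
                 min_answered_prop = min_answered_prop),
            class = "scale_config")
}

#' Default configurations for the evaluation instruments
#'
#' Ships ready-made [scale_config()] objects for the aggression
#' questionnaire short form (AQ-SF: 12 items, 1-5 scale, subscales
#' physical aggression, verbal aggression, anger, hostility), the
#' state-trait anger inventory (STAXI-2 state and trait anger scales,
#' 1-4 scale) and an 18-item bodily-sensations-of-anger questionnaire
#' (ABSQ, 1-5 scale). Item-to-subscale assignments are uniform
#' placeholders (consecutive blocks) because the licensed item keys are
#' not redistributable; replace them for real data.
#'
#' @return Named list of `scale_config` objects
#'   (`AQ-SF`, `STAXI-2`, `ABSQ`).
#' @export
default_scale_configs <- function() {
  aq_items <- sprintf("aq%02d", 1:12)
  staxi_items <- c(sprintf("s%02d", 1:15), sprintf("t%02d", 1:10))
  absq_items <- sprintf("b%02d", 1:18)
  list(
    "AQ-SF" = scale_config(
      "AQ-SF", aq_items, range = c(1, 5),
      subscales = list(physical_aggression = aq_items[1:3],
                       verbal_aggression = aq_items[4:6],
                       anger = aq_items[7:9],
                       hostility = aq_items[10:12])),
    "STAXI-2" = scale_config(
      "STAXI-2", staxi_items, range = c(1, 4),
      subscales = list(state_anger = staxi_items[1:15],
                       trait_anger = staxi_items[16:25])),
    "ABSQ" = scale_config("ABSQ", absq_items, range = c(1, 5))
  )
}

#' Read a scale configuration from JSON or YAML
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file with fields
#'   `instrument`, `items`, `range`, `subscales`, `reverse_keyed`.
#' @return A `scale_config`.
#' @export
read_scale_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  scale_config(instrument = x$instrument,
               items = x$items,
               range = as.numeric(x$range),
               subscales = lapply(x$subscales, as.character),
               reverse_keyed = as.character(x$reverse_keyed %||% character()),
               min_answered_prop = x$min_answered_prop %||% 0.8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score an item-response table against a scale configuration
#'
#' Takes a long-format item-response table (columns `respondent_id`,
#' `timepoint`, `instrument`, `item_id`, `response`), keeps the rows for
#' the config's instrument, reflects reverse-keyed items
#' (`r -> min + max - r`), and returns total and subscale scores as item
#' means on the native response scale, per respondent and timepoint.
#' When some items are missing, the score is prorated (mean of answered
#' items) provided at least `min_answered_prop` of the (sub)scale's items
#' were answered; otherwise the score is `NA`.
#'
#' @param table Long-format data frame of item responses.
#' @param config A [scale_config()].
#' @return Tibble with columns `respondent_id`, `timepoint`, `scale`
#'   (`"total"` and one row per subscale) and `score`.
#' @export
scale_scores <- function(table, config) {
  stopifnot(inherits(config, "scale_config"),
            all(c("respondent_id", "timepoint", "item_id", "response") %in%
                  names(table)))
  if ("instrument" %in% names(table)) {
    table <- table[table$instrument == config$instrument, , drop = FALSE]
  }
  bad <- !is.na(table$response) &
    (table$response < config$range[1] | table$response > config$range[2])
  if (any(bad)) {
    stop("responses outside the configured range [", config$range[1], ", ",
         config$range[2], "] for ", config$instrument, call. = FALSE)
  }
  refl <- table$item_id %in% config$reverse_keyed
  table$response[refl] <- config$range[1] + config$range[2] -
    table$response[refl]

  score_items <- function(resp_by_item, item_set) {
    v <- resp_by_item[item_set]
    answered <- sum(!is.na(v))
    if (answered / length(item_set) >= config$min_answered_prop) {
      mean(v, na.rm = TRUE)
    } else {
      NA_real_
    }
  }

  groups <- split(table, interaction(table$respondent_id, table$timepoint,
                                     drop = TRUE))
  scales <- c("total", names(config$subscales))
  out <- lapply(groups, function(g) {
    resp <- stats::setNames(rep(NA_real_, length(config$items)),
                            config$items)
    keep <- g$item_id %in% config$items
    resp[g$item_id[keep]] <- g$response[keep]
    sc <- c(score_items(resp, config$items),
            vapply(config$subscales, function(it) score_items(resp, it),
                   numeric(1)))
    tibble::tibble(respondent_id = g$respondent_id[1],
                   timepoint = g$timepoint[1],
                   scale = scales, score = unname(sc))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$respondent_id, out$timepoint), , drop = FALSE]
}

#' Summary table of scale scores with pre/post statistics
#'
#' Produces the usual evaluation summary: per scale and timepoint the
#' mean and SD of the scores across respondents, and for every scale
#' present at both timepoints a Wilcoxon matched-pairs test on the
#' respondents with scores at both.
#'
#' @param scores Output of [scale_scores()] (possibly several instruments
#'   row-bound together).
#' @param t0,t1 Timepoint labels to compare (defaults `"T0"`, `"T1"`).
#' @return List with `summary` (tibble: `scale`, `timepoint`, `n`,
#'   `mean`, `sd`, `median`) and `tests` (tibble: `scale`, `n_pairs`,
#'   `W`, `Z`, `p`).
#' @export
scale_summary <- function(scores, t0 = "T0", t1 = "T1") {
  grp <- interaction(scores$scale, scores$timepoint, drop = TRUE)
  summ <- do.call(rbind, lapply(split(scores, grp), function(g) {
    v <- g$score[!is.na(g$score)]
    tibble::tibble(scale = g$scale[1], timepoint = g$timepoint[1],
                   n = length(v), mean = mean(v), sd = stats::sd(v),
                   median = stats::median(v))
  }))
  rownames(summ) <- NULL

  tests <- lapply(unique(scores$scale), function(sc) {
    a <- scores[scores$scale == sc & scores$timepoint == t0, ]
    b <- scores[scores$scale == sc & scores$timepoint == t1, ]
    ids <- intersect(a$respondent_id, b$respondent_id)
    pre <- a$score[match(ids, a$respondent_id)]
    post <- b$score[match(ids, b$respondent_id)]
    ok <- !is.na(pre) & !is.na(post)
    if (sum(ok) < 1) return(NULL)
    w <- wilcoxon_matched_pairs(pre[ok], post[ok])
    tibble::tibble(scale = sc, n_pairs = sum(ok), W = w$W, Z = w$Z,
                   p = w$p)
  })
  tests <- do.call(rbind, tests[!vapply(tests, is.null, TRUE)])
  list(summary = summ[order(summ$scale, summ$timepoint), ], tests = tests)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' The nonparametric equivalent of the paired t test. Differences
#' `post - pre` are ranked by absolute value with average ranks for ties;
#' `W` is the smaller of the positive- and negative-rank sums. The
#' two-sided p value is exact — computed from the full null distribution
#' of the positive-rank sum over all sign assignments — whenever the
#' number of nonzero differences is at most 15, and otherwise uses the
#' normal approximation with tie correction (via the exact rank-sum
#' variance) and a 0.5 continuity correction. `Z` carries the sign of
#' the positive-minus-negative rank-sum difference.
#'
#' Zero differences are dropped by default (the classic procedure and the
#' default of mainstream statistics packages); `zero_policy = "pratt"`
#' instead ranks zeros with the rest and then discards their ranks, which
#' retains their influence on the ranking of nonzero differences.
#'
#' @param pre,post Paired numeric vectors of equal length.
#' @param zero_policy `"drop"` (default) or `"pratt"`.
#' @return List with `W` (min rank sum), `W_plus`, `W_minus`, `Z`, `p`
#'   (two-sided), `n_effective` (nonzero differences used), `exact`
#'   (logical) and `degenerate` (`TRUE` when all differences are zero,
#'   in which case `p = 1`, `W = 0`, `n_effective = 0`).
#' @examples
#' wilcoxon_matched_pairs(c(2.35, 2.1, 2.6), c(1.9, 1.8, 2.0))
#' @export
wilcoxon_matched_pairs <- function(pre, post,
                                   zero_policy = c("drop", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(pre) == length(post), length(pre) >= 1,
            !anyNA(pre), !anyNA(post))
  d <- post - pre

  if (all(d == 0)) {
    return(list(W = 0, W_plus = 0, W_minus = 0, Z = 0, p = 1,
                n_effective = 0L, exact = TRUE, degenerate = TRUE))
  }

  if (zero_policy == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n_eff <- length(d)
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  total <- w_plus + w_minus

  # exact null distribution: signs independent, so Var(W+) = sum(r^2)/4
  mu <- total / 2
  sigma <- sqrt(sum(r^2) / 4)

  if (n_eff <= 15) {
    dist <- signed_rank_null_distribution(r)
    # distribution over 2*W+ (integer grid; average ranks give halves)
    w2 <- round(2 * w)
    hi2 <- round(2 * (total - w))
    p <- sum(dist$prob[dist$value <= w2]) +
      sum(dist$prob[dist$value >= hi2])
    p <- min(1, p)
    exact <- TRUE
    z_mag <- if (sigma > 0) max(0, (mu - w - 0.5) / sigma) else 0
  } else {
    z_mag <- max(0, (mu - w - 0.5) / sigma)
    p <- 2 * stats::pnorm(-z_mag)
    exact <- FALSE
  }
  z_sign <- sign(w_plus - w_minus)
  list(W = w, W_plus = w_plus, W_minus = w_minus,
       Z = if (z_sign == 0) 0 else z_sign * z_mag, p = p,
       n_effective = as.integer(n_eff), exact = exact, degenerate = FALSE)
}

# full null distribution of 2*W+ for signed ranks r (counts over all
# 2^n equiprobable sign vectors), by convolution
signed_rank_null_distribution <- function(r) {
  r2 <- round(2 * r)
  counts <- c(1, numeric(sum(r2)))
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  list(value = seq_along(counts) - 1L, prob = counts / 2^length(r2))
}

#' Pearson product-moment correlation with t-based p value
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @param method `"pearson"` (default) or `"spearman"` (rank
#'   correlation, for a robustness check).
#' @return List with `r`, `df` (`n - 2`) and two-sided `p` from the t
#'   transform `t = r * sqrt(df / (1 - r^2))`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)$r  # 1
#' @export
pearson_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3,
            !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- stats::cor(x, y)
  df <- length(x) - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(r = r, df = df, p = p)
}
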