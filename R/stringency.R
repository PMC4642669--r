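#' Mismatch-rate stringency settings
#'
#' A single mismatch *rate* applied uniformly across read lengths, rather
#' than a fixed mismatch count, keeps mappings comparable between lengths.
#' The strict default of 2% is the smallest rate that admits at least one
#' mismatch in a 50 bp read (1 in 50); the relaxed default of 14% is the
#' rate equivalent to the BWA default settings.
#'
#' @param label `"strict"`, `"relaxed"`, or `"custom"`.
#' @param rate mismatch fraction in `[0, 1)`; required for `"custom"`,
#'   otherwise derived from the label.
#' @return a `stringency_config` list with `rate` and `label`.
#' @export
stringency_config <- function(label = c("strict", "relaxed", "custom"),
                              rate = NULL) {
  label <- match.arg(label)
  if (is.null(rate))
    rate <- switch(label, strict = 0.02, relaxed = 0.14,
                   custom = abort("custom stringency needs an explicit rate"))
  stopifnot(rate >= 0, rate < 1)
  structure(list(rate = rate, label = label), class = "stringency_config")
}

#' Per-read mismatch budget
#'
#' The largest number of mismatches a read of length `L` may carry at
#' mismatch rate `r`: `floor(r * L)`. Non-decreasing in both arguments.
#'
#' @param L read length(s) in bp.
#' @param r mismatch rate(s) in `[0, 1)`.
#' @return integer vector of budgets.
#' @export
max_mismatches <- function(L, r) {
  stopifnot(all(L >= 1), all(r >= 0), all(r < 1))
  as.integer(floor(r * L + 1e-9))
}

#' Linear alignment scoring scheme
#'
#' @param match per-base match reward (non-negative).
#' @param mismatch_penalty per-base mismatch penalty magnitude
#'   (non-negative).
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch_penalty = 1) {
  stopifnot(match >= 0, mismatch_penalty >= 0)
  structure(list(match = match, mismatch_penalty = mismatch_penalty),
            class = "scoring_scheme")
}

#' Translate a mismatch rate into a minimum alignment score
#'
#' Under a linear scheme, an ungapped alignment with `d` mismatches scores
#' `(L - d) * match - d * penalty`, so requiring at most
#' `max_mismatches(L, r)` mismatches is the same as requiring a score of at
#' least `L * match - max_mismatches(L, r) * (match + penalty)`. Exposed as
#' a generic approximation of per-mapper threshold flags.
#'
#' @inheritParams max_mismatches
#' @param scheme a [scoring_scheme()].
#' @return numeric score threshold(s).
#' @export
min_score_threshold <- function(L, r, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  L * scheme$match -
    max_mismatches(L, r) * (scheme$match + scheme$mismatch_penalty)
}

#' Suggested external-mapper flags for a stringency setting
#'
#' Approximate flag strings for common mappers, derived from the linear
#' translation in [min_score_threshold()]. These are documented
#' approximations, not reproductions of each mapper's internal scoring.
#'
#' @param L read length in bp.
#' @param stringency a [stringency_config()].
#' @return tibble with `mapper` and `flags`.
#' @export
suggest_mapper_flags <- function(L, stringency = stringency_config("strict")) {
  m <- max_mismatches(L, stringency$rate)
  tibble(
    mapper = c("bowtie2", "bwa-sw"),
    flags = c(
      sprintf("--end-to-end --mp 6,6 --score-min L,%d,0", -6L * m),
      sprintf("-a 1 -b 3 -T %d", as.integer(L - 4L * m))
    )
  )
}

#' Mismatch-budget curves across read lengths
#'
#' Tabulates [max_mismatches()] for every combination of the supplied read
#' lengths and rates; the strict (2%) and relaxed (14%) curves diverge
#' linearly in read length.
#'
#' @param lengths read lengths in bp.
#' @param rates mismatch rates.
#' @return tibble with `length`, `rate`, `budget`.
#' @export
mismatch_budget_curve <- function(lengths = c(50, 100, 150, 300, 500, 1000),
                                  rates = c(0.02, 0.14)) {
  tidyr::expand_grid(length = lengths, rate = rates) %>%
    mutate(budget = max_mismatches(.data$length, .data$rate))
}
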