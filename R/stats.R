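#' log10(N + 1) transform for false-positive counts
#'
#' The variance-stabilising transform applied to FP SNP counts before the
#' factorial ANOVA; zero counts map to zero.
#'
#' @param n non-negative counts.
#' @return `log10(n + 1)`.
#' @export
log_fp_transform <- function(n) {
  if (any(n < 0, na.rm = TRUE)) abort("counts must be non-negative")
  log10(n + 1)
}

#' The published 576-combination factor grid
#'
#' The fully crossed design of the reference experiment: read length (6
#' levels), assembly (3), mapper (2), stringency (2), MAPQ (2), variant
#' caller (2), depth filter (2) — 576 combinations, observed in duplicate.
#'
#' @param replicates number of replicates to cross in, or `NULL` for the
#'   bare combination grid.
#' @return tibble with one row per combination (times replicate).
#' @export
reference_design <- function(replicates = NULL) {
  g <- tidyr::expand_grid(
    length = c(50L, 100L, 150L, 300L, 500L, 1000L),
    assembly = c("Allpaths", "Control", "Velvet"),
    mapper = c("Bowtie2", "BWA"),
    stringency = c("relaxed", "strict"),
    mapq = c(0L, 20L),
    caller = c("FreeBayes", "GATK"),
    depth_filter = c("no", "yes"))
  if (!is.null(replicates))
    g <- tidyr::expand_grid(g, replicate = seq_len(replicates))
  g
}

# ---- balanced-ANOVA engine ----------------------------------------------

# Grouping index and group size for a subset of factor columns.
subset_index <- function(data, cols) {
  if (length(cols) == 1) {
    f <- factor(data[[cols]])
  } else {
    f <- interaction(lapply(cols, function(cc) data[[cc]]), drop = FALSE)
  }
  as.integer(f)
}

#' Balanced full-factorial ANOVA with a replicate stratum
#'
#' Decomposes the (transformed) response of a complete, balanced factorial
#' design into a replicate blocking stratum, every main effect and
#' interaction up to full order, and a residual (the replicate-by-treatment
#' stratum). Sums of squares are computed from marginal cell means with
#' Moebius (inclusion-exclusion) correction — for a balanced design this is
#' exactly the classical orthogonal decomposition, and it is fast enough to
#' recompute hundreds of times inside [permutation_test()]. Variance ratios
#' take the residual mean square as denominator; F probabilities are upper
#' tail.
#'
#' @param data one row per factor combination and replicate.
#' @param response name of the count (or already-transformed) column.
#' @param factors character vector of factor columns; defaults to every
#'   column except `response` and `replicate`.
#' @param replicate name of the replicate column.
#' @param transform applied to the response before analysis; the default is
#'   [log_fp_transform()], use `identity` for pre-transformed responses.
#' @param max_order include interactions up to this order (default: full).
#' @return an `fp_anova` object; see [tidy.fp_anova()].
#' @export
balanced_factorial_anova <- function(data, response = "n_fp",
                                     factors = NULL,
                                     replicate = "replicate",
                                     transform = log_fp_transform,
                                     max_order = Inf) {
  stopifnot(is.data.frame(data), response %in% names(data),
            replicate %in% names(data))
  if (is.null(factors))
    factors <- setdiff(names(data), c(response, replicate))
  stopifnot(length(factors) >= 1, all(factors %in% names(data)))

  nlev <- vapply(factors, function(f) length(unique(data[[f]])), 0L)
  n_comb <- prod(nlev)
  reps <- sort(unique(data[[replicate]]))
  n_rep <- length(reps)
  if (nrow(data) != n_comb * n_rep ||
      nrow(dplyr::distinct(data[, c(factors, replicate)])) != nrow(data)) {
    want <- do.call(tidyr::expand_grid, c(
      setNames(lapply(factors, function(f) unique(data[[f]])), factors),
      setNames(list(reps), replicate)))
    missing <- dplyr::anti_join(want, data, by = c(factors, replicate))
    abort(paste0("design is not balanced and complete; ",
                 nrow(missing), " missing cell(s), e.g. ",
                 paste(unlist(missing[1, ]), collapse = "/")))
  }

  y <- transform(data[[response]])
  N <- length(y)
  CF <- sum(y)^2 / N

  k <- length(factors)
  masks <- seq_len(2^k - 1L)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(k - 1))) > 0), 0L)
  keep <- sizes <= max_order
  masks <- masks[keep]
  sizes <- sizes[keep]
  ord <- order(sizes, masks)
  masks <- masks[ord]
  sizes <- sizes[ord]

  idx_list <- list()
  m_groups <- numeric(length(masks))
  df_term <- numeric(length(masks))
  labels <- character(length(masks))
  for (i in seq_along(masks)) {
    cols <- factors[bitwAnd(masks[i], 2^(0:(k - 1))) > 0]
    idx_list[[i]] <- subset_index(data, cols)
    m_groups[i] <- N / prod(nlev[cols])
    df_term[i] <- prod(nlev[cols] - 1L)
    labels[i] <- paste(cols, collapse = ":")
  }
  rep_idx <- as.integer(factor(data[[replicate]]))
  mask_pos <- setNames(seq_along(masks), masks)

  compute_ss <- function(yy) {
    cf <- sum(yy)^2 / N
    ss_u <- vapply(seq_along(masks), function(i) {
      sum(rowsum(yy, idx_list[[i]], reorder = FALSE)^2) / m_groups[i] - cf
    }, 0)
    ss <- numeric(length(masks))
    for (i in seq_along(masks)) {
      sub_terms <- 0
      mm <- masks[i]
      if (sizes[i] > 1) {
        subs <- masks[bitwAnd(masks, mm) == masks & masks != mm]
        sub_terms <- sum(ss[mask_pos[as.character(subs)]])
      }
      ss[i] <- ss_u[i] - sub_terms
    }
    ss_rep <- sum(rowsum(yy, rep_idx, reorder = FALSE)^2) / (N / n_rep) - cf
    ss_tot <- sum(yy^2) - cf
    list(ss = ss, ss_rep = ss_rep, ss_tot = ss_tot,
         ss_res = ss_tot - ss_rep - sum(ss))
  }

  got <- compute_ss(y)
  df_res <- N - 1 - (n_rep - 1) - sum(df_term)
  ms_res <- got$ss_res / df_res
  terms <- tibble(
    term = labels, df = df_term, ss = pmax(got$ss, 0),
    ms = pmax(got$ss, 0) / df_term,
    vr = (pmax(got$ss, 0) / df_term) / ms_res,
    f_prob = pf((pmax(got$ss, 0) / df_term) / ms_res, df_term, df_res,
                lower.tail = FALSE),
    perm_prob = NA_real_)

  out <- structure(list(
    terms = terms,
    stratum = tibble(term = "replicate", df = n_rep - 1, ss = got$ss_rep,
                     ms = got$ss_rep / (n_rep - 1),
                     vr = (got$ss_rep / (n_rep - 1)) / ms_res),
    residual = tibble(term = "residual", df = df_res, ss = got$ss_res,
                      ms = ms_res),
    total_ss = got$ss_tot,
    n_obs = N,
    factors = factors, replicate = replicate, n_rep = n_rep,
    transform_label = deparse(substitute(transform)),
    .cache = list(y = y, compute_ss = compute_ss, rep_idx = rep_idx,
                  df_term = df_term, df_res = df_res)),
    class = "fp_anova")
  out$terms$pct_ss <- if (got$ss_tot > 0)
    100 * pmax(got$ss, 0) / got$ss_tot else NA_real_
  out
}

#' @export
print.fp_anova <- function(x, ...) {
  cat("Balanced factorial ANOVA (", x$n_obs, " observations, ",
      length(x$factors), " factors)\n", sep = "")
  main <- x$terms %>% filter(!grepl(":", .data$term))
  cat("Replicate stratum: df ", x$stratum$df, ", s.s. ",
      signif(x$stratum$ss, 6), ", v.r. ", round(x$stratum$vr, 2), "\n",
      sep = "")
  print(as.data.frame(main), digits = 5)
  cat("Residual: df ", x$residual$df, ", m.s. ",
      signif(x$residual$ms, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy an fp_anova into one row per source of variation
#'
#' Rows cover the replicate stratum, every treatment term, and the
#' residual, mirroring the conventional published layout (df, s.s., m.s.,
#' v.r., F prob., permutation prob., percentage SS).
#'
#' @param x an `fp_anova`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fp_anova <- function(x, ...) {
  pct <- percent_ss(x)
  bind_rows(
    tibble(term = "Replicate stratum", df = x$stratum$df, ss = x$stratum$ss,
           ms = x$stratum$ms, vr = x$stratum$vr, f_prob = NA_real_,
           perm_prob = NA_real_),
    x$terms %>% select("term", "df", "ss", "ms", "vr", "f_prob",
                       "perm_prob"),
    tibble(term = "Residual", df = x$residual$df, ss = x$residual$ss,
           ms = x$residual$ms, vr = NA_real_, f_prob = NA_real_,
           perm_prob = NA_real_)) %>%
    left_join(pct, by = "term")
}

#' @export
glance.fp_anova <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_terms = nrow(x$terms),
         total_ss = x$total_ss, residual_ss = x$residual$ss,
         residual_df = x$residual$df, residual_ms = x$residual$ms,
         replicate_ss = x$stratum$ss)
}

#' Percentage of total sum of squares per source
#'
#' @param x an `fp_anova`.
#' @param include_stratum include the replicate stratum (and thus use the
#'   full total SS as denominator); with `FALSE` the denominator is the
#'   treatment-plus-residual SS.
#' @return tibble with `term` and `pct_ss`, including `Replicate stratum`
#'   and `Residual` rows; percentages sum to 100.
#' @export
percent_ss <- function(x, include_stratum = TRUE) {
  stopifnot(inherits(x, "fp_anova"))
  denom <- if (include_stratum) x$total_ss else x$total_ss - x$stratum$ss
  if (denom <= 0) abort("zero total sum of squares")
  rows <- tibble(
    term = c("Replicate stratum", x$terms$term, "Residual"),
    pct_ss = 100 * c(x$stratum$ss, x$terms$ss, x$residual$ss) / denom)
  if (!include_stratum) rows <- rows %>% filter(.data$term != "Replicate stratum")
  rows
}

#' Permutation test for every ANOVA term
#'
#' Permutes the response and recomputes each term's variance ratio;
#' `p = (1 + #{F* >= F}) / (n_perm + 1)`, so the smallest attainable value
#' is `1 / (n_perm + 1)` (0.001 at 999 permutations). The default scheme
#' permutes within replicate strata, respecting the blocking; whole-table
#' permutation is available as an alternative.
#'
#' @param x an `fp_anova`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param scheme `"within_replicate"` or `"whole_table"`.
#' @return `x` with `perm_prob` filled in on its `terms`.
#' @export
permutation_test <- function(x, n_perm = 999, seed = 1L,
                             scheme = c("within_replicate", "whole_table")) {
  stopifnot(inherits(x, "fp_anova"), n_perm >= 1)
  scheme <- match.arg(scheme)
  cache <- x$.cache
  y <- cache$y
  rep_groups <- split(seq_along(y), cache$rep_idx)
  f_obs <- x$terms$vr
  exceed <- numeric(length(f_obs))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    yy <- y
    if (scheme == "within_replicate") {
      for (g in rep_groups) yy[g] <- y[sample(g)]
    } else {
      yy <- y[sample.int(length(y))]
    }
    got <- cache$compute_ss(yy)
    ms_res <- got$ss_res / cache$df_res
    f_perm <- (got$ss / cache$df_term) / ms_res
    exceed <- exceed + (f_perm >= f_obs)
  }
  x$terms$perm_prob <- (1 + exceed) / (n_perm + 1)
  x
}

#' Cell means with the standard error of a difference
#'
#' Means of the transformed response over the cells of a chosen factor
#' cross, with `m` (observations averaged per cell) and
#' `sed = sqrt(2 * MS_residual / m)` from the full ANOVA, carried at full
#' precision.
#'
#' @param data the factor table (as for [balanced_factorial_anova()]).
#' @param factors_sel factors defining the cells.
#' @param response,replicate,transform as in [balanced_factorial_anova()].
#' @param anova an existing `fp_anova` for the full design; computed when
#'   `NULL`.
#' @return an `fp_cell_means` object: list with `means` (tibble), `m`,
#'   `sed`, `ms_residual`.
#' @export
cell_means_sed <- function(data, factors_sel, response = "n_fp",
                           replicate = "replicate",
                           transform = log_fp_transform, anova = NULL) {
  stopifnot(all(factors_sel %in% names(data)))
  if (is.null(anova))
    anova <- balanced_factorial_anova(data, response = response,
                                      replicate = replicate,
                                      transform = transform)
  y <- transform(data[[response]])
  cells <- data %>%
    mutate(.y = y) %>%
    group_by(dplyr::across(dplyr::all_of(factors_sel))) %>%
    summarise(mean = mean(.data$.y), m = n(), .groups = "drop")
  m <- unique(cells$m)
  if (length(m) != 1)
    abort("selected factors do not define equally sized cells")
  if (m < 2)
    abort("one observation per cell: sed is undefined (select fewer factors)")
  structure(list(means = cells %>% select(-"m"), m = m,
                 sed = sed_from_residual(anova$residual$ss,
                                         anova$residual$df, m),
                 ms_residual = anova$residual$ms,
                 factors = factors_sel),
            class = "fp_cell_means")
}

#' @export
print.fp_cell_means <- function(x, ...) {
  cat("Cell means over ", paste(x$factors, collapse = " x "),
      " (m = ", x$m, " per cell)\n", sep = "")
  print(as.data.frame(x$means), digits = 4)
  cat("Sed = ", format(round(x$sed, 5), nsmall = 5), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fp_cell_means <- function(x, ...) {
  x$means %>% mutate(m = x$m, sed = x$sed)
}

#' Standard error of a difference from a residual row
#'
#' `sed = sqrt(2 * (ss / df) / m)` — the standard error of the difference
#' between two cell means each averaging `m` observations, given the
#' residual sum of squares and degrees of freedom of a balanced ANOVA.
#'
#' @param ss residual sum of squares.
#' @param df residual degrees of freedom.
#' @param m observations averaged per cell.
#' @return the sed.
#' @export
sed_from_residual <- function(ss, df, m) {
  stopifnot(ss >= 0, df > 0, m > 0)
  sqrt(2 * (ss / df) / m)
}

#' Zero-FP factor combinations
#'
#' A combination counts as zero-FP when its response is zero in every
#' replicate. Reports the overall count and a per-level breakdown for a
#' chosen factor (e.g. the assembly/control split).
#'
#' @param data the factor table.
#' @param response count column name.
#' @param replicate replicate column name.
#' @param by optional factor for the breakdown.
#' @return list with `n_combinations`, `n_zero_fp`, and `by_level`
#'   (tibble, `NULL` when `by` is not given).
#' @export
zero_fp_summary <- function(data, response = "n_fp", replicate = "replicate",
                            by = NULL) {
  factors <- setdiff(names(data), c(response, replicate))
  comb <- data %>%
    group_by(dplyr::across(dplyr::all_of(factors))) %>%
    summarise(all_zero = all(.data[[response]] == 0), .groups = "drop")
  by_level <- NULL
  if (!is.null(by)) {
    by_level <- comb %>%
      group_by(dplyr::across(dplyr::all_of(by))) %>%
      summarise(n_combinations = n(), n_zero_fp = sum(.data$all_zero),
                .groups = "drop")
  }
  list(n_combinations = nrow(comb), n_zero_fp = sum(comb$all_zero),
       by_level = by_level)
}

#' Read a factor-level FP-count table
#'
#' Long-format TSV with one row per factor combination and replicate:
#' factor columns, a replicate column and a count column. This is the entry
#' point for analysing externally produced count tables with
#' [balanced_factorial_anova()], [cell_means_sed()] and
#' [zero_fp_summary()].
#'
#' @param path TSV file.
#' @param response,replicate expected column names.
#' @return tibble.
#' @export
read_fp_count_table <- function(path, response = "n_fp",
                                replicate = "replicate") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  out <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
  if (!all(c(response, replicate) %in% names(out)))
    abort(paste0("table must have '", response, "' and '", replicate,
                 "' columns"))
  out
}

#' Write a factor-level FP-count table
#'
#' @param data the factor table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fp_count_table <- function(data, path) {
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
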