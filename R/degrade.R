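#' Configuration for reference degradation
#'
#' Emulates the three pathologies of draft assemblies that drive read
#' mismapping: fragmentation (contig breaks), non-assembly (dropped
#' sequence), and misassembly through repeat collapse (all copies of a
#' family merged into one representative).
#'
#' @param fragmentation_breaks_per_mb expected contig breaks per Mb.
#' @param deletion_fraction fraction of the genome dropped, in `[0, 1)`.
#' @param collapse_repeat_families character vector of family names whose
#'   copies are merged to a single representative.
#' @param min_contig_length contigs shorter than this are discarded.
#' @param mean_deletion_length mean length of an individual dropped block.
#' @param seed integer seed.
#' @return a `degrade_config` list.
#' @export
degrade_config <- function(fragmentation_breaks_per_mb = 0,
                           deletion_fraction = 0,
                           collapse_repeat_families = character(0),
                           min_contig_length = 1L,
                           mean_deletion_length = 1500,
                           seed = 1L) {
  stopifnot(deletion_fraction >= 0, deletion_fraction < 1,
            min_contig_length >= 1, fragmentation_breaks_per_mb >= 0)
  structure(list(fragmentation_breaks_per_mb = fragmentation_breaks_per_mb,
                 deletion_fraction = deletion_fraction,
                 collapse_repeat_families = collapse_repeat_families,
                 min_contig_length = as.integer(min_contig_length),
                 mean_deletion_length = mean_deletion_length,
                 seed = as.integer(seed)),
            class = "degrade_config")
}

#' Bundled degradation presets
#'
#' `"control"` leaves the genome intact; `"moderate"` collapses the low-copy
#' `teC` family with light fragmentation; `"severe"` collapses the high-copy
#' `teA`, its sister `teB`, and `teC`, with heavier fragmentation and more
#' dropped sequence. The two degraded presets stand in for the two draft
#' assemblies of a factorial experiment, the intact genome for its control.
#'
#' @param preset one of `"control"`, `"moderate"`, `"severe"`.
#' @param seed integer seed.
#' @return a `degrade_config`.
#' @export
degrade_preset <- function(preset = c("control", "moderate", "severe"),
                           seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    control = degrade_config(seed = seed),
    moderate = degrade_config(fragmentation_breaks_per_mb = 10,
                              deletion_fraction = 0.02,
                              collapse_repeat_families = "teC",
                              min_contig_length = 500L, seed = seed),
    severe = degrade_config(fragmentation_breaks_per_mb = 25,
                            deletion_fraction = 0.05,
                            collapse_repeat_families = c("teA", "teB", "teC"),
                            min_contig_length = 500L, seed = seed))
}

#' Degrade a toy genome into a draft-like reference
#'
#' Applies repeat collapse, random sequence loss and fragmentation, and
#' records full provenance: every contig base traces to a source interval on
#' the toy genome, and collapsed representatives record all merged source
#' copies. Deletion junctions concatenate their flanks (a misjoin), which is
#' what removes the true mapping target of reads from the dropped sequence.
#'
#' @param genome a [simulate_genome()] result.
#' @param cfg a [degrade_config()].
#' @return a `degraded_reference`: list with `contigs` (named character
#'   vector), `provenance` (tibble mapping contig intervals to source
#'   intervals, 0-based half-open), `events` (tibble log of applied
#'   degradation events), `collapsed` (merged source copies per
#'   representative) and `config`.
#' @export
degrade_reference <- function(genome, cfg = degrade_config()) {
  stopifnot(inherits(genome, "toy_genome"), inherits(cfg, "degrade_config"))
  set.seed(cfg$seed)
  chroms <- genome$chromosomes
  G <- sum(nchar(chroms))

  del <- tibble(chrom = character(), start = integer(), end = integer())
  events <- list()
  collapsed <- tibble(family = character(), rep_chrom = character(),
                      rep_start = integer(), rep_end = integer(),
                      src_chrom = character(), src_start = integer(),
                      src_end = integer())

  # repeat collapse: keep the first copy (lowest chrom, coordinate), delete
  # the rest, remember the merged sources on the representative
  for (fam in cfg$collapse_repeat_families) {
    copies <- genome$features %>%
      filter(.data$label == "TE", .data$family == fam) %>%
      arrange(.data$chrom, .data$start)
    if (nrow(copies) == 0)
      abort(paste0("no TE copies found for family '", fam, "'"))
    rep_copy <- copies[1, ]
    gone <- copies[-1, , drop = FALSE]
    if (nrow(gone) > 0) {
      del <- bind_rows(del, gone %>% select("chrom", "start", "end"))
      collapsed <- bind_rows(collapsed, tibble(
        family = fam, rep_chrom = rep_copy$chrom,
        rep_start = rep_copy$start, rep_end = rep_copy$end,
        src_chrom = gone$chrom, src_start = gone$start, src_end = gone$end))
    }
    events[[length(events) + 1L]] <- tibble(
      event = "collapse", family = fam, chrom = rep_copy$chrom,
      start = rep_copy$start, end = rep_copy$end,
      detail = paste0(nrow(copies), " copies -> 1 representative"))
  }

  # random sequence loss, until the union of dropped intervals reaches target
  target <- cfg$deletion_fraction * G
  if (target > 0) {
    dropped <- union_width(del)
    guard <- 0L
    while (dropped < target && guard < 10000L) {
      guard <- guard + 1L
      chrom <- sample(names(chroms), 1, prob = nchar(chroms))
      L <- nchar(chroms[[chrom]])
      w <- min(max(100L, round(rexp(1, 1 / cfg$mean_deletion_length))), L - 1L)
      s <- sample.int(L - w, 1) - 1L
      cand <- tibble(chrom = chrom, start = s, end = s + w)
      new_del <- bind_rows(del, cand)
      gain <- union_width(new_del) - union_width(del)
      if (gain > 0) {
        del <- new_del
        dropped <- dropped + gain
        events[[length(events) + 1L]] <- tibble(
          event = "deletion", family = NA_character_, chrom = chrom,
          start = s, end = s + w, detail = paste0(w, " bp dropped"))
      }
    }
  }

  # build per-chromosome scaffolds of kept segments (flanks joined at
  # deletion junctions), then fragment into contigs
  contigs <- character(0)
  prov <- list()
  for (chrom in names(chroms)) {
    L <- nchar(chroms[[chrom]])
    d <- del %>% filter(.data$chrom == !!chrom)
    kept <- interval_complement(d, L)
    if (nrow(kept) == 0) next
    segs <- kept %>% mutate(src_chrom = chrom) %>%
      rename(src_start = "start", src_end = "end")

    n_breaks <- stats::rpois(1, cfg$fragmentation_breaks_per_mb *
                                  sum(segs$src_end - segs$src_start) / 1e6)
    scaffold_len <- sum(segs$src_end - segs$src_start)
    breaks <- sort(unique(sample.int(max(scaffold_len - 1L, 1L),
                                     min(n_breaks, scaffold_len - 1L))))
    if (length(breaks) > 0)
      events[[length(events) + 1L]] <- tibble(
        event = "fragmentation", family = NA_character_, chrom = chrom,
        start = NA_integer_, end = NA_integer_,
        detail = paste0(length(breaks), " breaks"))

    pieces <- split_segments(segs, breaks)
    whole <- length(pieces) == 1 && nrow(pieces[[1]]) == 1 &&
      pieces[[1]]$src_start[1] == 0 && pieces[[1]]$src_end[1] == L
    for (ci in seq_along(pieces)) {
      p <- pieces[[ci]]
      seq <- paste(vapply(seq_len(nrow(p)), function(i)
        substr(chroms[[chrom]], p$src_start[i] + 1L, p$src_end[i]),
        character(1)), collapse = "")
      if (nchar(seq) < cfg$min_contig_length) {
        events[[length(events) + 1L]] <- tibble(
          event = "drop_short", family = NA_character_, chrom = chrom,
          start = p$src_start[1], end = p$src_end[nrow(p)],
          detail = paste0(nchar(seq), " bp contig discarded"))
        next
      }
      nm <- if (whole) chrom else
        sprintf("%s_c%02d", chrom, ci)
      contigs[[nm]] <- seq
      off <- cumsum(c(0L, p$src_end - p$src_start))
      prov[[length(prov) + 1L]] <- tibble(
        contig = nm, c_start = off[-length(off)], c_end = off[-1L],
        src_chrom = chrom, src_start = p$src_start, src_end = p$src_end)
    }
  }
  if (length(contigs) == 0)
    abort("degradation removed the whole genome; no contigs remain")

  structure(list(
    contigs = contigs,
    provenance = if (length(prov)) bind_rows(prov) else tibble(),
    events = if (length(events)) bind_rows(events) else
      tibble(event = character(), family = character(), chrom = character(),
             start = integer(), end = integer(), detail = character()),
    collapsed = collapsed,
    config = cfg), class = "degraded_reference")
}

#' @export
print.degraded_reference <- function(x, ...) {
  cat("<degraded_reference> ", length(x$contigs), " contigs, ",
      sum(nchar(x$contigs)), " bp (", nrow(x$events), " events)\n", sep = "")
  invisible(x)
}

# total width of the union of 0-based half-open intervals
union_width <- function(iv) {
  if (nrow(iv) == 0) return(0)
  red <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  sum(IRanges::width(red))
}

# complement of intervals within [0, L)
interval_complement <- function(iv, L) {
  if (nrow(iv) == 0) return(tibble(start = 0L, end = as.integer(L)))
  red <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  s <- IRanges::start(red) - 1L
  e <- IRanges::end(red)
  starts <- c(0L, e)
  ends <- c(s, as.integer(L))
  keep <- ends > starts
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

# split an ordered run of source segments at scaffold-coordinate break points
split_segments <- function(segs, breaks) {
  widths <- segs$src_end - segs$src_start
  ends <- cumsum(widths)
  starts <- ends - widths
  cuts <- c(0L, breaks, ends[length(ends)])
  out <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    if (b <= a) next
    rows <- which(ends > a & starts < b)
    piece <- segs[rows, , drop = FALSE]
    piece$src_start <- pmax(piece$src_start, piece$src_start + (a - starts[rows]))
    piece$src_end <- pmin(piece$src_end, piece$src_end - (ends[rows] - b))
    out[[length(out) + 1L]] <- piece
  }
  out
}

#' Trace contig coordinates back to the source genome
#'
#' For a degraded reference, maps positions on contigs to the toy-genome
#' coordinates they derive from via the provenance table; for an intact
#' reference this is the identity.
#'
#' @param reference a `degraded_reference`, `toy_genome` or named character
#'   vector.
#' @param chrom,pos vectors of contig name and 0-based position.
#' @return tibble with `src_chrom` and `src_pos` (NA when a position has no
#'   provenance, which cannot happen for contigs built by
#'   [degrade_reference()]).
#' @export
map_to_source <- function(reference, chrom, pos) {
  q <- tibble(chrom = as.character(chrom), pos = as.integer(pos),
              .row = seq_along(chrom))
  if (!inherits(reference, "degraded_reference")) {
    return(tibble(src_chrom = q$chrom, src_pos = q$pos))
  }
  hit <- q %>%
    left_join(reference$provenance, by = c(chrom = "contig"),
              relationship = "many-to-many") %>%
    filter(is.na(.data$c_start) |
             (.data$pos >= .data$c_start & .data$pos < .data$c_end)) %>%
    distinct(.data$.row, .keep_all = TRUE)
  out <- q %>% left_join(hit %>% select(".row", "src_chrom", "src_start",
                                        "c_start"), by = ".row")
  tibble(src_chrom = out$src_chrom,
         src_pos = as.integer(out$src_start + (out$pos - out$c_start)))
}
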