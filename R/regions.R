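#' Genome descriptor
#'
#' A genome is the set of chromosome lengths against which region coordinates
#' are validated and on which random-region nulls and coverage fractions are
#' defined. Coordinates everywhere in docseq are 0-based, half-open
#' (BED convention).
#'
#' @param chrom_sizes a named numeric vector (name = chromosome, value =
#'   length in bp), or a two-column data frame (chrom, length).
#' @return A tibble of class `docseq_genome` with columns `chrom` and
#'   `length`, carrying the total (effective) size as an attribute.
#' @examples
#' genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(ncol(chrom_sizes) >= 2)
    g <- tibble(chrom = as.character(chrom_sizes[[1]]),
                length = as.numeric(chrom_sizes[[2]]))
  } else {
    if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
      abort("chrom_sizes must be named by chromosome")
    }
    g <- tibble(chrom = names(chrom_sizes), length = as.numeric(chrom_sizes))
  }
  if (any(duplicated(g$chrom))) abort("duplicated chromosome names")
  if (any(!is.finite(g$length)) || any(g$length <= 0)) {
    abort("all chromosome lengths must be positive")
  }
  attr(g, "effective_size") <- sum(g$length)
  class(g) <- c("docseq_genome", class(g))
  g
}

#' Total genome size in bp
#' @param genome a [genome()] object.
#' @return Numeric scalar, the sum of chromosome lengths.
#' @export
effective_size <- function(genome) {
  stopifnot(inherits(genome, "docseq_genome"))
  attr(genome, "effective_size")
}

#' Read a chrom.sizes file (two-column TSV: chromosome, length)
#' @param path file path.
#' @return A [genome()] object.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", comment = "#", progress = FALSE)
  genome(x)
}

# ---- region tibbles ---------------------------------------------------------

#' Construct a region set
#'
#' Region sets are plain tibbles with at least `chrom`, `start`, `end`
#' (0-based half-open) and optionally `name`, `score`, `strand`. All docseq
#' interval functions take and return tibbles of this shape so they compose
#' with dplyr verbs.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-valued vectors; `0 <= start < end`.
#' @param name,score,strand optional per-interval columns. `strand` must be
#'   one of "+", "-", ".".
#' @param genome optional [genome()]; when given, intervals are checked
#'   against chromosome bounds.
#' @return A tibble with one row per interval.
#' @examples
#' region_set("chr1", 0, 100)
#' @export
region_set <- function(chrom, start, end, name = NULL, score = NULL,
                       strand = NULL, genome = NULL) {
  rs <- tibble(chrom = as.character(chrom),
               start = as.numeric(start),
               end = as.numeric(end))
  if (!is.null(name)) rs$name <- as.character(name)
  if (!is.null(score)) rs$score <- as.numeric(score)
  if (!is.null(strand)) rs$strand <- as.character(strand)
  validate_regions(rs, genome)
}

validate_regions <- function(rs, genome = NULL, what = "region set") {
  if (!all(c("chrom", "start", "end") %in% names(rs))) {
    abort(paste0(what, " must have columns chrom, start, end"))
  }
  bad <- which(!(rs$start >= 0 & rs$start < rs$end))
  if (length(bad)) {
    abort(sprintf("%s: invalid interval (need 0 <= start < end) at row %d",
                  what, bad[1]))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(rs$chrom), genome$chrom)
    if (length(unknown)) {
      abort(sprintf("%s: chromosome(s) not in genome: %s", what,
                    paste(unknown, collapse = ", ")))
    }
    len <- setNames(genome$length, genome$chrom)
    over <- which(rs$end > len[rs$chrom])
    if (length(over)) {
      abort(sprintf("%s: interval beyond chromosome end at row %d", what,
                    over[1]))
    }
  }
  if ("strand" %in% names(rs) &&
      !all(rs$strand %in% c("+", "-", "."))) {
    abort(paste0(what, ": strand must be one of '+', '-', '.'"))
  }
  as_tibble(rs)
}

#' Read BED3+ intervals
#'
#' Tab-separated, 0-based half-open; `track`, `browser` and `#` lines are
#' skipped. Columns beyond the sixth are ignored.
#'
#' @param path file path.
#' @param genome optional [genome()] for bounds validation.
#' @return A region tibble with chrom/start/end and, when present in the
#'   file, name/score/strand.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(region_set(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 fields",
                  lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: non-integer coordinates",
                  lineno[bad[1]]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: start >= end", lineno[bad[1]]))
  }
  rs <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) rs$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) {
    rs$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  }
  if (all(nf >= 6)) rs$strand <- vapply(fields, `[[`, "", 6)
  validate_regions(rs, genome, what = basename(path))
}

#' Write a region tibble as BED
#'
#' Emits BED3/BED4/BED6 depending on which optional columns are present
#' (score defaults to 0 and strand to "." when only some are available).
#'
#' @param rs region tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  validate_regions(rs)
  cols <- list(rs$chrom, format_coord(rs$start), format_coord(rs$end))
  if ("name" %in% names(rs) || "score" %in% names(rs) ||
      "strand" %in% names(rs)) {
    cols <- c(cols, list(col_or(rs, "name") %||% rep(".", nrow(rs))))
  }
  if ("score" %in% names(rs) || "strand" %in% names(rs)) {
    cols <- c(cols, list(col_or(rs, "score") %||% rep(0, nrow(rs))))
  }
  if ("strand" %in% names(rs)) cols <- c(cols, list(rs$strand))
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Merge overlapping and touching intervals
#'
#' @param rs region tibble (any extra columns are dropped).
#' @return A sorted tibble of disjoint intervals covering exactly the same
#'   bases; touching intervals (end == next start) are merged.
#' @export
merge_regions <- function(rs) {
  validate_regions(rs)
  if (!nrow(rs)) return(tibble(chrom = character(), start = numeric(),
                               end = numeric()))
  rs <- arrange(rs[c("chrom", "start", "end")], .data$chrom, .data$start,
                .data$end)
  rs |>
    group_by(.data$chrom) |>
    mutate(cummax_end = cummax(.data$end),
           new_block = .data$start > dplyr::lag(.data$cummax_end,
                                                default = -Inf),
           block = cumsum(.data$new_block)) |>
    group_by(.data$chrom, .data$block) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    select("chrom", "start", "end")
}

#' Number of query intervals overlapping an annotation
#'
#' The annotation is merged internally; a query interval counts once if it
#' shares at least one bp with the merged annotation (half-open overlap).
#'
#' @param query,annotation region tibbles.
#' @return Integer count, at most `nrow(query)`.
#' @export
count_overlaps <- function(query, annotation) {
  sum(overlaps_any(query, annotation))
}

#' Logical per-query overlap indicator
#'
#' @inheritParams count_overlaps
#' @return Logical vector along rows of `query`.
#' @export
overlaps_any <- function(query, annotation) {
  validate_regions(query, what = "query")
  ann <- merge_regions(annotation)
  if (!nrow(query)) return(logical(0))
  out <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    a <- ann[ann$chrom == ch, ]
    if (!nrow(a)) next
    s <- query$start[qi]
    e <- query$end[qi]
    # last annotation block starting at or before the query end - 1
    idx <- findInterval(e - 1, a$start)
    hit <- idx >= 1 & a$end[pmax(idx, 1)] > s
    out[qi] <- hit
  }
  out
}

#' Fraction of the genome covered by a region set
#'
#' @param rs region tibble (merged internally so double-covered bases count
#'   once).
#' @param genome a [genome()] object.
#' @return Numeric in \[0, 1\]: merged bp / effective genome size.
#' @export
coverage_fraction <- function(rs, genome) {
  stopifnot(inherits(genome, "docseq_genome"))
  m <- merge_regions(validate_regions(rs, genome))
  if (!nrow(m)) return(0)
  sum(m$end - m$start) / effective_size(genome)
}

#' Total (merged) bp covered by a region set
#' @param rs region tibble.
#' @return Numeric scalar.
#' @export
total_bp <- function(rs) {
  m <- merge_regions(rs)
  if (!nrow(m)) 0 else sum(m$end - m$start)
}

#' Report chromosome-name mismatches between two inputs
#'
#' Naming conventions ("chr1" vs "1") are never reconciled silently; this
#' helper makes the mismatch visible so the caller can fix the input.
#'
#' @param a,b region tibbles or genomes.
#' @return A list with chroms only in `a`, only in `b`, and shared.
#' @export
check_chrom_names <- function(a, b) {
  ca <- unique(a$chrom)
  cb <- unique(b$chrom)
  out <- list(only_a = setdiff(ca, cb), only_b = setdiff(cb, ca),
              shared = intersect(ca, cb))
  if (length(out$only_a) || length(out$only_b)) {
    warn(sprintf("chromosome naming mismatch: %d only in first, %d only in second",
                 length(out$only_a), length(out$only_b)))
  }
  out
}

# column if present, else NULL (avoids tibble's unknown-column warning)
col_or <- function(df, nm) if (nm %in% names(df)) df[[nm]] else NULL
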