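# Readers for genomic inputs, promoter-window construction and per-gene
# extraction of the three binding-peak characteristics (height, distance to
# TSS, width). Coordinates are 0-based, half-open throughout, matching the
# native bedGraph/BED convention.

# Internal: read a whitespace-delimited text file, skipping track/browser/
# comment lines, and return a list of token vectors plus original line numbers.
read_genomic_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file does not exist: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  tokens <- strsplit(trimws(lines[keep]), "\\s+")
  list(tokens = tokens, line_numbers = idx)
}

parse_numeric_column <- function(values, line_numbers, path, what) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out) & !is.na(values))
  if (length(bad) > 0) {
    abort(paste0(
      "non-numeric ", what, " in ", path, " at line(s) ",
      paste(utils::head(line_numbers[bad], 5), collapse = ", ")
    ))
  }
  out
}

#' Read a bedGraph signal track
#'
#' Parses a 4-column bedGraph file (`chrom start end value`). `track`,
#' `browser`, comment and blank lines are tolerated and skipped. Intervals are
#' returned in file order.
#'
#' @param path Path to a bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`
#'   (0-based, half-open coordinates).
#' @export
#' @examples
#' f <- tempfile(fileext = ".bedGraph")
#' writeLines(c("track type=bedGraph", "chr1 100 200 5.0"), f)
#' read_bedgraph(f)
read_bedgraph <- function(path) {
  parsed <- read_genomic_lines(path)
  if (length(parsed$tokens) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(), value = double()
    ))
  }
  nf <- lengths(parsed$tokens)
  if (any(nf < 4)) {
    abort(paste0(
      "malformed bedGraph record (need 4 columns) in ", path, " at line(s) ",
      paste(utils::head(parsed$line_numbers[nf < 4], 5), collapse = ", ")
    ))
  }
  col <- function(i) vapply(parsed$tokens, `[[`, character(1), i)
  out <- tibble(
    chrom = col(1),
    start = as.integer(parse_numeric_column(col(2), parsed$line_numbers, path, "start")),
    end = as.integer(parse_numeric_column(col(3), parsed$line_numbers, path, "end")),
    value = parse_numeric_column(col(4), parsed$line_numbers, path, "value")
  )
  if (any(out$end <= out$start)) {
    abort(paste0("bedGraph interval with end <= start in ", path))
  }
  out
}

#' Read called peaks in narrowPeak format
#'
#' Parses a 10-column ENCODE narrowPeak file. Column 7 (`signalValue`) is
#' taken as the peak height; column 10 (summit offset from `start`, or -1 if
#' absent) gives the summit position.
#'
#' @param path Path to a narrowPeak file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `height`,
#'   `summit` (`NA` when the file carries no summit).
#' @export
read_narrowpeak <- function(path) {
  parsed <- read_genomic_lines(path)
  if (length(parsed$tokens) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), height = double(), summit = integer()
    ))
  }
  nf <- lengths(parsed$tokens)
  if (any(nf < 10)) {
    abort(paste0(
      "malformed narrowPeak record (need 10 columns) in ", path, " at line(s) ",
      paste(utils::head(parsed$line_numbers[nf < 10], 5), collapse = ", ")
    ))
  }
  col <- function(i) vapply(parsed$tokens, `[[`, character(1), i)
  start <- as.integer(parse_numeric_column(col(2), parsed$line_numbers, path, "start"))
  offset <- as.integer(parse_numeric_column(col(10), parsed$line_numbers, path, "summit"))
  out <- tibble(
    chrom = col(1),
    start = start,
    end = as.integer(parse_numeric_column(col(3), parsed$line_numbers, path, "end")),
    name = col(4),
    height = parse_numeric_column(col(7), parsed$line_numbers, path, "signalValue"),
    summit = ifelse(offset >= 0, start + offset, NA_integer_)
  )
  if (any(out$height < 0)) abort(paste0("negative signalValue in ", path))
  out
}

#' Read gene annotations with TSS and strand
#'
#' For BED6 input (`chrom start end name score strand`) the TSS is the
#' interval start on the `+` strand and `end - 1` on the `-` strand (0-based).
#' For GTF input, rows with feature type `gene` are used and the gene id is
#' taken from the `gene_id` attribute.
#'
#' @param path Path to the annotation file.
#' @param format Either `"bed6"` or `"gtf"`.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_gene_annotation <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  parsed <- read_genomic_lines(path)
  empty <- tibble(
    gene_id = character(), chrom = character(), tss = integer(), strand = character()
  )
  if (length(parsed$tokens) == 0) return(empty)
  if (format == "bed6") {
    nf <- lengths(parsed$tokens)
    if (any(nf < 6)) {
      abort(paste0(
        "malformed BED6 record (need 6 columns) in ", path, " at line(s) ",
        paste(utils::head(parsed$line_numbers[nf < 6], 5), collapse = ", ")
      ))
    }
    col <- function(i) vapply(parsed$tokens, `[[`, character(1), i)
    chrom <- col(1)
    start <- as.integer(parse_numeric_column(col(2), parsed$line_numbers, path, "start"))
    end <- as.integer(parse_numeric_column(col(3), parsed$line_numbers, path, "end"))
    gene_id <- col(4)
    strand <- col(6)
  } else {
    nf <- lengths(parsed$tokens)
    if (any(nf < 9)) {
      abort(paste0("malformed GTF record (need 9 fields) in ", path))
    }
    # GTF is tab-delimited with a free-text attribute field; re-split raw lines.
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*($|#|track\\b|browser\\b)", lines)]
    fields <- strsplit(lines, "\t")
    feature <- vapply(fields, `[[`, character(1), 3)
    fields <- fields[feature == "gene"]
    if (length(fields) == 0) return(empty)
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- as.integer(vapply(fields, `[[`, character(1), 4)) - 1L # GTF is 1-based
    end <- as.integer(vapply(fields, `[[`, character(1), 5))
    strand <- vapply(fields, `[[`, character(1), 7)
    attrs <- vapply(fields, `[[`, character(1), 9)
    m <- regmatches(attrs, regexpr('gene_id "[^"]+"', attrs))
    if (length(m) != length(attrs)) abort(paste0("GTF gene rows without gene_id in ", path))
    gene_id <- sub('gene_id "([^"]+)"', "\\1", m)
    parsed$line_numbers <- seq_along(fields)
  }
  if (!all(strand %in% c("+", "-"))) {
    abort(paste0(
      "unknown strand symbol in ", path, " (expected '+' or '-'): ",
      paste(unique(setdiff(strand, c("+", "-"))), collapse = ", ")
    ))
  }
  if (anyDuplicated(gene_id)) {
    abort(paste0(
      "duplicate gene_id in ", path, ": ",
      paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")
    ))
  }
  tibble(
    gene_id = gene_id,
    chrom = chrom,
    tss = as.integer(ifelse(strand == "+", start, end - 1L)),
    strand = strand
  )
}

#' Read a per-gene, per-timepoint expression table
#'
#' Expects a TSV with header columns `gene_id`, `day`, `expression`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `day`, `expression`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("gene_id", "day", "expression"), names(out))
  if (length(missing) > 0) {
    abort(paste0("expression table missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::mutate(
    out,
    gene_id = as.character(.data$gene_id),
    day = as.integer(.data$day),
    expression = as.numeric(.data$expression)
  )
  out[c("gene_id", "day", "expression")]
}

#' Strand-aware promoter windows around each TSS
#'
#' The promoter is defined as the window from `upstream` bp upstream to
#' `downstream` bp downstream of the TSS (defaults 1500 and 500, i.e. -1.5 kb
#' to +0.5 kb). Upstream means lower coordinates on the `+` strand and higher
#' coordinates on the `-` strand. Windows running past the chromosome origin
#' are clipped at 0 with a warning and flagged.
#'
#' @param genes Annotation tibble as returned by [read_gene_annotation()].
#' @param upstream,downstream Non-negative window extents in bp.
#' @return A tibble with columns `chrom`, `start`, `end`, `gene_id`, `clipped`
#'   (0-based, half-open).
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 10000L, strand = "+")
#' promoter_windows(genes)
promoter_windows <- function(genes, upstream = 1500, downstream = 500) {
  if (upstream < 0 || downstream < 0) abort("upstream and downstream must be >= 0")
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  start <- ifelse(genes$strand == "+", genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(genes$strand == "+", genes$tss + downstream, genes$tss + upstream)
  clipped <- start < 0
  if (any(clipped)) {
    warn(paste0(
      "promoter window(s) clipped at chromosome origin for gene(s): ",
      paste(genes$gene_id[clipped], collapse = ", ")
    ))
    start <- pmax(start, 0)
  }
  tibble(
    chrom = genes$chrom,
    start = as.integer(start),
    end = as.integer(end),
    gene_id = genes$gene_id,
    clipped = clipped
  )
}

#' Derive peaks from a signal track within a promoter window
#'
#' Maximal runs of contiguous intervals with `value >= min_height` are
#' intersected with the window and returned as peaks. A peak's height is the
#' maximum value over the run and its summit is the midpoint of the first
#' interval attaining that maximum.
#'
#' @param track Signal tibble from [read_bedgraph()].
#' @param window A one-row promoter-window tibble (or any list with `chrom`,
#'   `start`, `end`).
#' @param min_height Signal threshold (> 0) for a position to belong to a peak.
#' @return A tibble of peaks with columns `chrom`, `start`, `end`, `height`,
#'   `summit`; zero rows when nothing qualifies.
#' @export
peaks_from_signal <- function(track, window, min_height = 1) {
  if (min_height <= 0) abort("min_height must be > 0")
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    height = double(), summit = integer()
  )
  sel <- track$chrom == window$chrom[[1]] &
    track$end > window$start[[1]] & track$start < window$end[[1]] &
    track$value >= min_height
  hits <- track[sel, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$start <- pmax(hits$start, as.integer(window$start[[1]]))
  hits$end <- pmin(hits$end, as.integer(window$end[[1]]))
  # Runs of contiguous intervals: a gap (or overlap irregularity) starts a new run.
  new_run <- c(TRUE, hits$start[-1] != hits$end[-nrow(hits)])
  run_id <- cumsum(new_run)
  purrr::map_dfr(split(seq_len(nrow(hits)), run_id), function(i) {
    run <- hits[i, , drop = FALSE]
    top <- run[which.max(run$value), , drop = FALSE]
    tibble(
      chrom = run$chrom[[1]],
      start = min(run$start),
      end = max(run$end),
      height = max(run$value),
      summit = as.integer(floor((top$start + top$end) / 2))
    )
  })
}

#' Peak characteristics relative to a TSS
#'
#' For each peak: height `H` is the peak's maximum signal; width `W` is
#' `end - start`; distance `D` is the absolute bp separation between the
#' geometric midpoint of the peak interval, `floor((start + end) / 2)`, and
#' the TSS. `D` is unsigned.
#'
#' @param peaks A tibble of peaks (columns `start`, `end`, `height`).
#' @param tss Integer TSS position (0-based).
#' @return The input with columns `height`, `distance`, `width` (input
#'   `height` preserved).
#' @export
extract_peak_features <- function(peaks, tss) {
  midpoint <- floor((peaks$start + peaks$end) / 2)
  dplyr::mutate(
    peaks,
    distance = abs(midpoint - as.integer(tss)),
    width = .data$end - .data$start
  )
}

#' Select the strongest peak in a promoter
#'
#' Returns the peak of maximal height; ties are broken by smallest distance to
#' the TSS, then by leftmost start, so the result is invariant to input order.
#'
#' @param peaks A tibble of peaks with `height` (zero or more rows).
#' @param tss Integer TSS position used for the distance tie-break.
#' @return A one-row tibble, or a zero-row tibble when `peaks` is empty.
#' @export
select_strongest <- function(peaks, tss) {
  if (nrow(peaks) == 0) return(peaks)
  feat <- extract_peak_features(peaks, tss)
  ord <- order(-feat$height, feat$distance, feat$start)
  feat[ord[1], , drop = FALSE]
}

#' Extract per-gene peak features for one timepoint
#'
#' Runs the promoter pipeline for every gene: build the promoter window,
#' derive peaks from the signal track (or filter called peaks), keep the
#' strongest peak, and report its height, distance to TSS and width. Genes
#' with no qualifying peak are dropped with a warning.
#'
#' @param track Signal tibble from [read_bedgraph()], or called peaks from
#'   [read_narrowpeak()] when `peaks_given = TRUE`.
#' @param genes Annotation tibble from [read_gene_annotation()].
#' @param day Integer day label attached to the output.
#' @param upstream,downstream Promoter extents in bp.
#' @param min_height Peak threshold for signal-derived peaks.
#' @param peaks_given If `TRUE`, `track` already contains called peaks and
#'   only window intersection and strongest-peak selection are applied.
#' @return A tibble with columns `gene_id`, `day`, `height`, `distance`,
#'   `width`, one row per gene that has a peak.
#' @export
extract_features <- function(track, genes, day,
                             upstream = 1500, downstream = 500,
                             min_height = 1, peaks_given = FALSE) {
  windows <- promoter_windows(genes, upstream, downstream)
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    win <- windows[i, , drop = FALSE]
    if (peaks_given) {
      sel <- track$chrom == win$chrom & track$end > win$start & track$start < win$end
      peaks <- track[sel, , drop = FALSE]
    } else {
      peaks <- peaks_from_signal(track, win, min_height)
    }
    if (nrow(peaks) == 0) return(NULL)
    best <- select_strongest(peaks, genes$tss[i])
    tibble(
      gene_id = genes$gene_id[i],
      day = as.integer(day),
      height = best$height,
      distance = as.numeric(best$distance),
      width = as.numeric(best$width)
    )
  })
  dropped <- genes$gene_id[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0) {
    warn(paste0(
      "no peak in promoter at day ", day, " for gene(s): ",
      paste(dropped, collapse = ", "), " (dropped)"
    ))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      gene_id = character(), day = integer(),
      height = double(), distance = double(), width = double()
    )
  }
  out
}

#' Join peak features with expression values
#'
#' Inner join on `(gene_id, day)`. Keys present on only one side are logged
#' and dropped; duplicate keys on either side are fatal. The output is sorted
#' by `(gene_id, day)`.
#'
#' @param features Feature tibble from [extract_features()].
#' @param expression Expression tibble from [read_expression()].
#' @return A records tibble with columns `gene_id`, `day`, `height`,
#'   `distance`, `width`, `expression`.
#' @export
join_expression <- function(features, expression) {
  key <- function(d) paste(d$gene_id, d$day, sep = "\r")
  if (anyDuplicated(key(features))) abort("duplicate (gene_id, day) keys in features")
  if (anyDuplicated(key(expression))) abort("duplicate (gene_id, day) keys in expression")
  only_f <- setdiff(key(features), key(expression))
  only_e <- setdiff(key(expression), key(features))
  if (length(only_f) > 0) {
    warn(paste0(length(only_f), " feature record(s) without expression dropped"))
  }
  if (length(only_e) > 0) {
    warn(paste0(length(only_e), " expression record(s) without features dropped"))
  }
  out <- dplyr::inner_join(features, expression, by = c("gene_id", "day"))
  dplyr::arrange(out, .data$gene_id, .data$day)
}
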