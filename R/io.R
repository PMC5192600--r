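.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", x)
}

.strip_quotes <- function(x) gsub('^"|"$', "", x)

#' Read a DREAM-layout expression matrix
#'
#' Tab-separated text with a header row of gene names (optionally quoted)
#' followed by one numeric row per experimental condition. An optional
#' leading row-label column is auto-detected (a first field that does not
#' parse as a number, or one extra field per data row) and dropped, so both
#' common DREAM dialects load without flags. Malformed cells, duplicate
#' gene names and missing values are rejected with coordinates.
#'
#' @param path Path to the file.
#' @param verbose Print the parsed dimensions.
#' @return Numeric matrix, conditions x genes, gene names as column names.
#' @export
read_expression <- function(path, verbose = FALSE) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file needs a header and data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- .strip_quotes(fields[[1]])
  rows <- fields[-1]
  nh <- length(header)
  widths <- lengths(rows)
  has_rowlab <- FALSE
  if (all(widths == nh + 1L)) {
    has_rowlab <- TRUE
  } else if (all(widths == nh)) {
    first <- vapply(rows, `[[`, character(1), 1L)
    if (all(is.na(suppressWarnings(as.numeric(first))))) {
      # every first field is non-numeric: row labels with a padded header
      has_rowlab <- TRUE
      header <- header[-1L]
      nh <- nh - 1L
    }
  } else {
    bad <- which(widths != nh & widths != nh + 1L)[1]
    stop("row ", bad + 1L, " has ", widths[bad], " fields, expected ", nh)
  }
  if (has_rowlab) rows <- lapply(rows, `[`, -1L)
  if (any(lengths(rows) != nh)) {
    bad <- which(lengths(rows) != nh)[1]
    stop("row ", bad + 1L, " has ", lengths(rows)[bad],
         " fields, expected ", nh)
  }
  if (anyDuplicated(header)) {
    stop("duplicate gene name in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(nh)))
  vals <- matrix(vals, nrow = nh) # columns = conditions at this point
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing value at row ", idx[2] + 1L,
         ", column ", idx[1], " (gene ", header[idx[1]], ")")
  }
  out <- t(vals)
  colnames(out) <- header
  out <- .validate_expression(out)
  if (verbose) {
    message("read ", nrow(out), " conditions x ", ncol(out), " genes")
  }
  out
}

#' Write an expression matrix in DREAM layout
#'
#' Tab-separated, header row of gene names, one row per condition. Values
#' are printed with 17 significant digits so a read/write round trip is
#' exact.
#'
#' @param x Expression matrix (conditions x genes, named columns).
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  x <- .validate_expression(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a regulator (transcription factor) list
#'
#' One gene id per line; duplicates are dropped preserving first
#' occurrence.
#'
#' @param path Path to the file.
#' @return Character vector of regulator gene ids.
#' @export
read_regulators <- function(path) {
  x <- trimws(.read_lines(path))
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("regulator file is empty: ", path)
  unique(x)
}

#' Read a gold-standard edge list
#'
#' Three tab-separated columns: regulator, target, label (1 = known edge,
#' 0 = known absent edge). Label-1 lines become positives; when label-0
#' lines are present they define, together with the positives, the
#' explicit universe of eligible pairs; otherwise the universe defaults to
#' all non-self regulator x gene pairs at evaluation time.
#'
#' @param path Path to the file.
#' @return A `"gold_standard"` object.
#' @export
read_gold <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("gold-standard file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("malformed gold-standard line ", bad[1], ": expected 3 fields, got ",
         lengths(fields)[bad[1]])
  }
  reg <- vapply(fields, `[[`, character(1), 1L)
  tgt <- vapply(fields, `[[`, character(1), 2L)
  lab <- vapply(fields, `[[`, character(1), 3L)
  labn <- suppressWarnings(as.integer(lab))
  if (anyNA(labn) || !all(labn %in% c(0L, 1L))) {
    stop("malformed gold-standard line ",
         which(is.na(labn) | !labn %in% c(0L, 1L))[1], ": label must be 0 or 1")
  }
  positives <- data.frame(regulator = reg[labn == 1L],
                          target = tgt[labn == 1L], stringsAsFactors = FALSE)
  universe <- if (any(labn == 0L)) {
    data.frame(regulator = reg, target = tgt, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  gold_standard(positives, universe = universe)
}

#' Write a gold-standard edge list
#'
#' @param gold A `"gold_standard"` object.
#' @param path Output path.
#' @export
write_gold <- function(gold, path) {
  stopifnot(inherits(gold, "gold_standard"))
  pos <- gold$positives
  pkey <- .pair_key(pos$regulator, pos$target)
  lines <- paste(pos$regulator, pos$target, "1", sep = "\t")
  if (!is.null(gold$universe)) {
    u <- gold$universe
    neg <- u[!.pair_key(u$regulator, u$target) %in% pkey, , drop = FALSE]
    lines <- c(lines, paste(neg$regulator, neg$target, "0", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write ranked edge predictions in the DREAM submission format
#'
#' One `regulator<TAB>target<TAB>score` line per edge, sorted by descending
#' score; scores are printed with 6 significant digits.
#'
#' @param edges Ranked edge `data.frame` (see [rank_edges()]) or a
#'   `"plsnet"` fit.
#' @param path Output path.
#' @param top_n Optional truncation.
#' @export
write_predictions <- function(edges, path, top_n = NULL) {
  if (inherits(edges, "plsnet")) edges <- rank_edges(edges, top_n = top_n)
  else if (!is.null(top_n)) edges <- utils::head(edges, top_n)
  if (any(edges$regulator == edges$target)) stop("self-edge in predictions")
  if (is.unsorted(rev(edges$score))) stop("scores must be non-increasing")
  writeLines(paste(edges$regulator, edges$target,
                   sprintf("%.6g", edges$score), sep = "\t"), path)
  invisible(path)
}

#' Read ranked edge predictions
#'
#' @param path Path to a 3-column tab-separated prediction file.
#' @return Ranked edge `data.frame` (`regulator`, `target`, `score`).
#' @export
read_predictions <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("malformed prediction line ", bad[1], ": expected 3 fields, got ",
         lengths(fields)[bad[1]])
  }
  reg <- vapply(fields, `[[`, character(1), 1L)
  tgt <- vapply(fields, `[[`, character(1), 2L)
  sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(sc)) {
    stop("malformed prediction line ", which(is.na(sc))[1],
         ": score is not numeric")
  }
  if (any(reg == tgt)) {
    stop("self-edge at prediction line ", which(reg == tgt)[1])
  }
  if (anyDuplicated(.pair_key(reg, tgt))) {
    stop("duplicate edge at prediction line ",
         which(duplicated(.pair_key(reg, tgt)))[1])
  }
  if (is.unsorted(rev(sc))) {
    stop("prediction scores are not non-increasing")
  }
  data.frame(regulator = reg, target = tgt, score = sc,
             stringsAsFactors = FALSE)
}
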