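#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses the common MGF dialect: `BEGIN IONS` / `END IONS` blocks containing
#' `KEY=value` header lines (`TITLE`, `PEPMASS`, `CHARGE`) followed by one
#' `m/z intensity` pair per line. `PEPMASS` may carry a second (precursor
#' intensity) token, which is ignored. Blocks without a `PEPMASS` line are
#' rejected, because every downstream step needs a precursor m/z. `CHARGE`
#' strings such as `2+` or `3-` become signed integers; a missing charge is
#' stored as `NA`, never guessed.
#'
#' Fragment lists are sorted ascending and duplicate m/z values merged by
#' summing intensities (see [ms_spectrum()]).
#'
#' @param path path to an MGF file.
#' @param role `"query"` or `"reference"`, recorded on the returned set.
#' @return A [spectrum_set()], one spectrum per block, in file order. An empty
#'   file yields an empty set with a warning.
#' @export
read_mgf <- function(path, role = c("query", "reference")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  begins <- which(trimmed == "BEGIN IONS")
  ends <- which(trimmed == "END IONS")
  if (!length(begins)) {
    warning("no spectra found in ", path)
    return(spectrum_set(list(), source = path, role = role))
  }
  spectra <- vector("list", length(begins))
  seen_ids <- character(0)
  for (k in seq_along(begins)) {
    b <- begins[k]
    e <- ends[ends > b]
    nb <- begins[begins > b]
    if (!length(e) || (length(nb) && e[1] > nb[1]))
      stop(sprintf("MGF parse error: block %d (starting line %d) has no END IONS",
                   k, b), call. = FALSE)
    e <- e[1]
    body <- trimmed[seq(b + 1L, e - 1L)]
    body_lines <- seq(b + 1L, e - 1L)
    keep <- nzchar(body) & !startsWith(body, "#")
    body <- body[keep]; body_lines <- body_lines[keep]

    is_header <- grepl("=", body, fixed = TRUE)
    hdr <- body[is_header]
    keys <- toupper(sub("=.*", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)

    if (!"PEPMASS" %in% keys)
      stop(sprintf("MGF parse error: block %d (starting line %d) has no PEPMASS",
                   k, b), call. = FALSE)
    pep <- strsplit(trimws(vals[match("PEPMASS", keys)]), "[ \t]+")[[1]][1]
    precursor <- suppressWarnings(as.numeric(pep))
    if (is.na(precursor))
      stop(sprintf("MGF parse error: block %d has non-numeric PEPMASS '%s'",
                   k, pep), call. = FALSE)
    charge <- NA_integer_
    if ("CHARGE" %in% keys) {
      cv <- trimws(vals[match("CHARGE", keys)])
      m <- regmatches(cv, regexec("^([0-9]+)([+-]?)$", cv))[[1]]
      if (length(m) == 3L)
        charge <- as.integer(m[2]) * (if (m[3] == "-") -1L else 1L)
    }
    id <- if ("TITLE" %in% keys) trimws(vals[match("TITLE", keys)])
          else sprintf("spectrum_%d", k)
    if (id %in% seen_ids) {
      warning(sprintf("duplicate spectrum id '%s'; suffixing block ordinal %d",
                      id, k))
      id <- sprintf("%s_%d", id, k)
    }
    seen_ids <- c(seen_ids, id)

    peaks <- body[!is_header]
    peak_lines <- body_lines[!is_header]
    mz <- numeric(0); inten <- numeric(0)
    if (length(peaks)) {
      tok <- strsplit(peaks, "[ \t]+")
      mz <- suppressWarnings(as.numeric(vapply(tok, `[`, character(1), 1L)))
      inten <- suppressWarnings(as.numeric(vapply(tok, `[`, character(1), 2L)))
      bad <- which(is.na(mz) | is.na(inten))
      if (length(bad))
        stop(sprintf("MGF parse error: non-numeric peak line %d ('%s')",
                     peak_lines[bad[1]], peaks[bad[1]]), call. = FALSE)
    }
    spectra[[k]] <- ms_spectrum(mz, inten, precursor_mz = precursor,
                                id = id, charge = charge)
  }
  spectrum_set(spectra, source = path, role = role)
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: ids go to `TITLE`, precursor m/z to `PEPMASS`,
#' and a known charge to `CHARGE`. m/z is written with enough digits for a
#' lossless round trip at sub-0.01 mDa level.
#'
#' @param set a [spectrum_set()].
#' @param path output file path.
#' @return Invisibly, the number of spectra written.
#' @export
write_mgf <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in set$spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.9f", s$precursor_mz), con)
    if (!is.na(s$charge))
      writeLines(sprintf("CHARGE=%d%s", abs(s$charge),
                         if (s$charge < 0) "-" else "+"), con)
    if (length(s$mz))
      writeLines(sprintf("%.9f %.12g", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(length(set$spectra))
}

#' Write a filtered hit list from a score result
#'
#' The natural product of a thresholded search is a sparse hit list, so
#' results are written as delimited text with columns `query_id`, `ref_id`,
#' `score`, `matches`: exactly the pairs with `score >= min_score` and
#' `matches >= min_matches`, sorted by descending score with ties broken by
#' (`query_id`, `ref_id`) lexicographically.
#'
#' @param result a `score_result` from [score_all()] or [blink_score()].
#' @param path output path for the tab-delimited hit list.
#' @param min_score minimum cosine score to report (>= 0).
#' @param min_matches minimum matching-ion count to report (>= 0).
#' @return The number of data rows written.
#' @export
write_scores <- function(result, path, min_score = 0, min_matches = 0) {
  stopifnot(inherits(result, "score_result"))
  if (min_score < 0 || min_matches < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  hits <- score_hits(result, min_score, min_matches)
  ok <- tryCatch({
    write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write hit list to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  nrow(hits)
}

#' Extract a thresholded, sorted hit table from a score result
#'
#' @inheritParams write_scores
#' @return A data.frame with columns `query_id`, `ref_id`, `score`, `matches`,
#'   sorted by descending score, ties by (`query_id`, `ref_id`).
#' @export
score_hits <- function(result, min_score = 0, min_matches = 0) {
  stopifnot(inherits(result, "score_result"))
  keep <- which(result$scores >= min_score & result$matches >= min_matches,
                arr.ind = TRUE)
  hits <- data.frame(
    query_id = result$query_ids[keep[, 1]],
    ref_id = result$ref_ids[keep[, 2]],
    score = result$scores[keep],
    matches = as.integer(result$matches[keep]),
    stringsAsFactors = FALSE
  )
  hits[order(-hits$score, hits$query_id, hits$ref_id), , drop = FALSE]
}

#' Write a full score matrix as coordinate-format sparse text
#'
#' Writes every non-zero score as `row col score matches` (1-based indices
#' into the query and reference sets), for workflows that want the whole
#' matrix rather than a thresholded hit list.
#'
#' @inheritParams write_scores
#' @return The number of coordinate rows written.
#' @export
write_score_matrix <- function(result, path) {
  stopifnot(inherits(result, "score_result"))
  keep <- which(result$scores != 0 | result$matches != 0, arr.ind = TRUE)
  df <- data.frame(row = keep[, 1], col = keep[, 2],
                   score = result$scores[keep],
                   matches = as.integer(result$matches[keep]))
  df <- df[order(df$row, df$col), , drop = FALSE]
  write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  nrow(df)
}
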