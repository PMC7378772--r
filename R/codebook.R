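#' Hazard category levels
#'
#' The seven hazard groups used by the coding scheme: machine-side causes
#' (escalator condition, maintenance state), environment, and four passenger
#' groups (task-driven behaviour, improper riding, bad health, and the last
#' passive action immediately preceding injury).
#'
#' @export
hazard_categories <- c(
  "escalator", "maintenance", "environment",
  "rider_task_driven", "rider_improper_riding",
  "rider_bad_health", "rider_last_passive"
)

#' Load a hazard codebook
#'
#' Reads a delimited text table mapping integer hazard codes to short
#' descriptions and (optionally) a category. Comma- and tab-delimited files
#' are both accepted; a header row is detected automatically.
#'
#' @param source path to a delimited text file, or a connection.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the first line.
#' @return a `hazard_codebook`: a data.frame with columns `code` (integer),
#'   `label` (character) and `category` (character, `NA` when absent).
#' @examples
#' cb <- beijing_codebook()
#' codebook_label(cb, 52)
#' @export
load_codebook <- function(source, sep = NULL) {
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("codebook source is empty", call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  first <- scan(text = lines[[1L]], what = character(), sep = sep,
                quiet = TRUE, quote = "\"")
  has_header <- is.na(suppressWarnings(as.integer(first[[1L]])))
  tab <- utils::read.table(text = lines, sep = sep, header = has_header,
                           quote = "\"", stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE,
                           encoding = "UTF-8")
  if (ncol(tab) < 2L) stop("codebook needs at least two columns (code, label)",
                           call. = FALSE)
  codes_raw <- trimws(tab[[1L]])
  codes <- suppressWarnings(as.integer(codes_raw))
  bad <- which(is.na(codes) | codes != suppressWarnings(as.numeric(codes_raw)))
  if (length(bad)) {
    stop(sprintf("non-integer hazard code '%s' at codebook line %d",
                 codes_raw[bad[[1L]]], bad[[1L]] + has_header), call. = FALSE)
  }
  if (any(codes <= 0L)) stop("hazard codes must be positive integers",
                             call. = FALSE)
  dup <- codes[duplicated(codes)]
  if (length(dup)) {
    stop(sprintf("duplicate hazard code(s) in codebook: %s",
                 paste(sort(unique(dup)), collapse = ", ")), call. = FALSE)
  }
  labels <- trimws(tab[[2L]])
  if (any(!nzchar(labels))) stop("empty hazard label in codebook", call. = FALSE)
  category <- if (ncol(tab) >= 3L) trimws(tab[[3L]]) else rep(NA_character_, length(codes))
  category[!nzchar(category) | is.na(category)] <- NA_character_
  known <- is.na(category) | category %in% hazard_categories
  if (!all(known)) {
    stop(sprintf("unknown hazard category: %s",
                 paste(unique(category[!known]), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(code = codes, label = labels, category = category,
                    stringsAsFactors = FALSE)
  out <- out[order(out$code), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hazard_codebook", "data.frame")
  out
}

#' @export
print.hazard_codebook <- function(x, ...) {
  cat(sprintf("<hazard_codebook> %d hazards in %d categories\n",
              nrow(x), length(unique(stats::na.omit(x$category)))))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Look up hazard labels by code
#'
#' @param codebook a `hazard_codebook`.
#' @param codes integer hazard codes.
#' @return character vector of labels (`NA` for codes not in the codebook).
#' @export
codebook_label <- function(codebook, codes) {
  codebook$label[match(codes, codebook$code)]
}

#' The Beijing escalator-accident hazard codebook
#'
#' The packaged 61-hazard coding scheme identified from the Beijing metro
#' escalator accident sample: hazards 1-7 concern the escalator itself,
#' 8-11 maintenance, 12-14 the environment, and 15-61 the riders (task-driven
#' behaviour, improper riding, bad health, last passive action).
#'
#' @return a `hazard_codebook` with 61 entries.
#' @export
beijing_codebook <- function() {
  load_codebook(system.file("extdata", "beijing_codebook.csv",
                            package = "cehn", mustWork = TRUE))
}
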