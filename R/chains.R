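#' Parse one accident hazard chain
#'
#' A chain is an ordered sequence of integer hazard codes joined by an arrow,
#' either the typographic "→" or the ASCII "->", with optional
#' whitespace. Revisited codes are preserved in order.
#'
#' @param text a single chain string, e.g. `"21→35→52"`.
#' @param case_id optional case identifier attached to the chain.
#' @return an `accident_chain`: integer vector of codes with a `case_id`
#'   attribute.
#' @examples
#' parse_chain("21→35→52")
#' parse_chain("21 -> 35")
#' @export
parse_chain <- function(text, case_id = NA_character_) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty hazard chain string", call. = FALSE)
  }
  norm <- gsub("->", "→", text, fixed = TRUE)
  tokens <- trimws(strsplit(norm, "→", fixed = TRUE)[[1L]])
  if (any(!nzchar(tokens))) {
    stop(sprintf("malformed hazard chain '%s': empty code token", text),
         call. = FALSE)
  }
  codes <- suppressWarnings(as.integer(tokens))
  if (anyNA(codes)) {
    stop(sprintf("non-numeric hazard code token '%s' in chain '%s'",
                 tokens[which(is.na(codes))[[1L]]], text), call. = FALSE)
  }
  accident_chain(codes, case_id)
}

#' Construct an accident chain from codes
#'
#' @param codes ordered integer hazard codes (length >= 1).
#' @param case_id case identifier.
#' @return an `accident_chain`.
#' @export
accident_chain <- function(codes, case_id = NA_character_) {
  codes <- as.integer(codes)
  if (length(codes) == 0L || anyNA(codes) || any(codes <= 0L)) {
    stop("an accident chain needs at least one positive hazard code",
         call. = FALSE)
  }
  structure(codes, case_id = as.character(case_id), class = "accident_chain")
}

#' Format an accident chain as an arrow-joined string
#'
#' Inverse of [parse_chain()]: `parse_chain(format_chain(x))` reproduces the
#' code sequence.
#'
#' @param chain an `accident_chain` or plain integer vector.
#' @return single string of codes joined by "→".
#' @export
format_chain <- function(chain) {
  paste(as.integer(chain), collapse = "→")
}

#' @export
print.accident_chain <- function(x, ...) {
  cat(sprintf("<accident_chain %s> %s\n", attr(x, "case_id"), format_chain(x)))
  invisible(x)
}

#' A coded five-step accident record
#'
#' The five-step task-driven decomposition of one accident narrative: what
#' the casualty intended, what went wrong, the attempted recovery, the last
#' passive action before the accident, and the injurious interaction with
#' the machine. Each step holds zero or more hazard codes in narrative order.
#'
#' @param case_id case identifier.
#' @param intent,failure,recovery,last_action,interaction integer code
#'   vectors (possibly empty) for steps 1-5.
#' @param codebook optional `hazard_codebook`; when given, `last_action`
#'   codes must carry the `rider_last_passive` category.
#' @return an `ftdm_record`.
#' @export
ftdm_record <- function(case_id, intent = integer(), failure = integer(),
                        recovery = integer(), last_action = integer(),
                        interaction = integer(), codebook = NULL) {
  steps <- list(intent = as.integer(intent), failure = as.integer(failure),
                recovery = as.integer(recovery),
                last_action = as.integer(last_action),
                interaction = as.integer(interaction))
  if (all(lengths(steps) == 0L)) {
    stop("ftdm_record: all five steps are empty", call. = FALSE)
  }
  if (!is.null(codebook) && length(steps$last_action)) {
    cat4 <- codebook$category[match(steps$last_action, codebook$code)]
    bad <- steps$last_action[is.na(cat4) | cat4 != "rider_last_passive"]
    if (length(bad)) {
      stop(sprintf("step-4 (last passive action) codes must be in category 'rider_last_passive': %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(c(list(case_id = as.character(case_id)), steps),
            class = "ftdm_record")
}

#' Reduce a five-step record to its hazard chain
#'
#' Concatenates the five steps' code lists in step order, skipping empty
#' steps, so the record collapses to the ordered chain the network model
#' consumes.
#'
#' @param record an `ftdm_record`.
#' @return an `accident_chain`.
#' @export
chain_from_ftdm <- function(record) {
  stopifnot(inherits(record, "ftdm_record"))
  codes <- c(record$intent, record$failure, record$recovery,
             record$last_action, record$interaction)
  accident_chain(codes, record$case_id)
}

#' Read accident chains from a delimited file
#'
#' Expects columns `case_id,chain` (header optional), where `chain` is an
#' arrow-joined code sequence as accepted by [parse_chain()].
#'
#' @param source path or connection.
#' @param codebook optional `hazard_codebook` to validate codes against.
#' @param unknown what to do with codes absent from `codebook`:
#'   `"error"` (default) or `"warn"`.
#' @param sep field separator; `NULL` auto-detects comma vs tab.
#' @return list of `accident_chain` objects.
#' @export
read_chains <- function(source, codebook = NULL,
                        unknown = c("error", "warn"), sep = NULL) {
  unknown <- match.arg(unknown)
  lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  first <- scan(text = lines[[1L]], what = character(), sep = sep,
                quiet = TRUE, quote = "\"")
  if (length(first) < 2L) stop("chain file needs columns case_id,chain",
                               call. = FALSE)
  has_header <- !grepl("→|->", first[[2L]])
  tab <- utils::read.table(text = lines, sep = sep, header = has_header,
                           quote = "\"", stringsAsFactors = FALSE,
                           colClasses = "character", encoding = "UTF-8")
  chains <- mapply(parse_chain, tab[[2L]], tab[[1L]],
                   SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (!is.null(codebook)) {
    validate_chain_codes(chains, codebook, unknown)
  }
  chains
}

validate_chain_codes <- function(chains, codebook, unknown = "error") {
  seen <- sort(unique(unlist(lapply(chains, as.integer))))
  missing <- setdiff(seen, codebook$code)
  if (length(missing)) {
    msg <- sprintf("hazard code(s) not in codebook: %s",
                   paste(missing, collapse = ", "))
    if (identical(unknown, "warn")) warning(msg, call. = FALSE)
    else stop(msg, call. = FALSE)
  }
  invisible(chains)
}

#' Apply the chain validity filter
#'
#' A chain is analysable only if it records at least two hazards, since a
#' single code carries no transition. Shorter chains are counted, not
#' silently dropped.
#'
#' @param chains list of `accident_chain` objects (or integer vectors).
#' @return a `chain_corpus`: list with elements `chains` (the retained
#'   chains) and `excluded_count`.
#' @examples
#' corpus <- filter_valid(list(parse_chain("21→35→52"),
#'                             accident_chain(52)))
#' corpus$excluded_count
#' @export
filter_valid <- function(chains) {
  if (inherits(chains, "chain_corpus")) chains <- chains$chains
  keep <- vapply(chains, function(ch) length(as.integer(ch)) >= 2L, logical(1))
  structure(list(chains = chains[keep], excluded_count = sum(!keep)),
            class = "chain_corpus")
}

#' @export
print.chain_corpus <- function(x, ...) {
  cat(sprintf("<chain_corpus> %d chains retained, %d excluded by validity filter\n",
              length(x$chains), x$excluded_count))
  invisible(x)
}

#' Write a chain corpus to the standard chains CSV
#'
#' @param corpus a `chain_corpus` or list of chains.
#' @param path output file path.
#' @export
write_chains <- function(corpus, path) {
  chains <- if (inherits(corpus, "chain_corpus")) corpus$chains else corpus
  ids <- vapply(chains, function(ch) {
    id <- attr(ch, "case_id")
    if (is.null(id) || is.na(id)) NA_character_ else id
  }, character(1))
  ids[is.na(ids)] <- as.character(seq_along(chains))[is.na(ids)]
  tab <- data.frame(case_id = ids,
                    chain = vapply(chains, format_chain, character(1)),
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The 327 Beijing accident hazard chains
#'
#' The packaged corpus of coded hazard chains from the Beijing metro
#' escalator accident sample, transcribed verbatim from the published table.
#' Two transcription anomalies of the source table are preserved rather than
#' repaired: the printed case numbering skips 184 and 239, and the final
#' printed row carries two chains without case numbers, which are stored
#' under placeholder ids `"x1"` and `"x2"`. The total is exactly 327 chains,
#' each of length 3-6.
#'
#' @param codebook codebook used to validate codes; defaults to
#'   [beijing_codebook()].
#' @return a `chain_corpus` with 327 retained chains and
#'   `excluded_count = 0` (the published sample already had its 472
#'   single-hazard/undocumented records removed).
#' @export
beijing_chains <- function(codebook = beijing_codebook()) {
  chains <- read_chains(system.file("extdata", "beijing_chains.csv",
                                    package = "cehn", mustWork = TRUE),
                        codebook = codebook)
  filter_valid(chains)
}
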