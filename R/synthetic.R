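#' First-order chain generator model
#'
#' Accident chains are emulated as realizations of a memoryless transition
#' process: a start hazard is drawn from an initial distribution over
#' designated trigger hazards, then the chain steps through the row-stochastic
#' transition matrix until it reaches an absorbing (consequence) hazard or a
#' hard length cap. Chains in observed accident data are short (3-6
#' hazards) and the L-space network only encodes first-order structure, so
#' nothing higher-order is modelled.
#'
#' @param trans square numeric matrix with identical row/column names (the
#'   hazard codes). Each row either sums to 1 (transient hazard) or is all
#'   zero (absorbing hazard).
#' @param init named numeric vector summing to 1; names are hazard codes,
#'   all of which must be non-absorbing. Hazards with positive initial mass
#'   and zero in-probability are the designated triggers.
#' @param max_length hard cap on chain length (default 6, the longest chain
#'   in the packaged corpus); must be >= 2.
#' @param seed integer seed stored with the model and used by
#'   [generate_chains()] unless overridden.
#' @return a `generator_model` with derived `roles` (trigger /
#'   transitional / consequence per hazard).
#' @export
generator_model <- function(trans, init, max_length = 6L, seed = 1L) {
  stopifnot(is.matrix(trans), nrow(trans) == ncol(trans))
  codes <- rownames(trans)
  if (is.null(codes) || !identical(codes, colnames(trans))) {
    stop("trans must have identical row and column names (hazard codes)",
         call. = FALSE)
  }
  if (any(trans < 0)) stop("transition probabilities must be >= 0", call. = FALSE)
  rs <- rowSums(trans)
  ok <- abs(rs - 1) < 1e-8 | rs == 0
  if (!all(ok)) {
    stop(sprintf("transition rows must sum to 1 or be all zero (absorbing); offending hazard(s): %s",
                 paste(codes[!ok], collapse = ", ")), call. = FALSE)
  }
  if (max_length < 2L) stop("max_length must be >= 2", call. = FALSE)
  if (is.null(names(init)) || abs(sum(init) - 1) > 1e-8 || any(init < 0)) {
    stop("init must be a named non-negative vector summing to 1", call. = FALSE)
  }
  if (!all(names(init) %in% codes)) {
    stop("init names must be hazard codes of trans", call. = FALSE)
  }
  absorbing <- codes[rs == 0]
  if (any(names(init)[init > 0] %in% absorbing)) {
    stop("initial distribution must not place mass on absorbing hazards",
         call. = FALSE)
  }
  in_prob <- colSums(trans)
  start <- names(init)[init > 0]
  roles <- ifelse(codes %in% absorbing, "consequence",
                  ifelse(codes %in% start & in_prob[codes] == 0, "trigger",
                         "transitional"))
  structure(list(codes = codes, trans = trans, init = init,
                 absorbing = absorbing,
                 roles = stats::setNames(roles, codes),
                 max_length = as.integer(max_length),
                 seed = as.integer(seed)),
            class = "generator_model")
}

#' Default synthetic model of cascading escalator hazards
#'
#' A small, realistic scenario over real codebook hazards: cascades start
#' with a task-driven or health trigger (carrying bulk luggage 21,
#' attending to children 17, mobility-impaired older rider 40), pass
#' through transitional hazards (not holding the handrail 35, not standing
#' still 36, cannot lift the luggage 23, objects/riders falling 13), and
#' terminate in an absorbing consequence (loss of balance 52, crushed by
#' riders 49, pulled out of balance by suitcase 56). Transitional hazards
#' absorb with probability 0.45 per step, giving mean chain length about 4
#' with the cap at 6 — the length profile of observed corpora.
#'
#' @param seed stored seed (default 1).
#' @return a `generator_model`.
#' @export
default_generator_model <- function(seed = 1L) {
  codes <- c(21, 17, 40, 35, 36, 23, 13, 52, 49, 56)
  n <- length(codes)
  trans <- matrix(0, n, n, dimnames = list(codes, codes))
  tr <- c("21", "17", "40"); mid <- c("35", "36", "23", "13")
  cons <- c("52", "49", "56")
  trans[tr, mid] <- 1 / length(mid)
  for (m in mid) {
    others <- setdiff(mid, m)
    trans[m, others] <- 0.55 / length(others)
    trans[m, cons] <- 0.45 / length(cons)
  }
  init <- stats::setNames(c(0.5, 0.3, 0.2), tr)
  generator_model(trans, init, max_length = 6L, seed = seed)
}

#' Empirical bootstrap model from an observed corpus
#'
#' Builds a generator whose transition matrix is the corpus's empirical
#' conditional next-hazard frequency matrix and whose initial distribution
#' is the empirical distribution of chain-starting hazards, enabling
#' resampling of corpora that mimic the observed one. Hazards never seen
#' with an outgoing transition become absorbing.
#'
#' @param corpus a `chain_corpus`.
#' @param max_length,seed passed to [generator_model()].
#' @return a `generator_model`.
#' @export
model_from_corpus <- function(corpus, max_length = 6L, seed = 1L) {
  chains <- if (inherits(corpus, "chain_corpus")) corpus$chains else corpus
  stopifnot(length(chains) > 0L)
  trans <- empirical_transitions(corpus)
  firsts <- vapply(chains, function(ch) as.integer(ch)[[1L]], integer(1))
  # starts that are absorbing in the empirical matrix cannot seed a chain
  absorbing <- rownames(trans)[rowSums(trans) == 0]
  firsts <- firsts[!as.character(firsts) %in% absorbing]
  tab <- table(factor(as.character(firsts), levels = rownames(trans)))
  init <- as.numeric(tab) / sum(tab)
  names(init) <- rownames(trans)
  generator_model(trans, init[init > 0], max_length = max_length, seed = seed)
}

#' Generate a synthetic chain corpus
#'
#' Reproducible given the seed: identical seeds yield identical corpora.
#'
#' @param model a `generator_model`.
#' @param count number of chains to draw (>= 1).
#' @param seed overrides the model's stored seed when given.
#' @return a `chain_corpus` with `count` chains (all of length >= 2) and
#'   `excluded_count = 0`.
#' @export
generate_chains <- function(model, count, seed = NULL) {
  stopifnot(inherits(model, "generator_model"), count >= 1L)
  set.seed(if (is.null(seed)) model$seed else as.integer(seed))
  codes <- model$codes
  probs <- model$trans
  init_codes <- names(model$init)
  chains <- vector("list", count)
  for (i in seq_len(count)) {
    cur <- sample(init_codes, 1L, prob = model$init)
    seq_codes <- cur
    while (length(seq_codes) < model$max_length) {
      row <- probs[cur, ]
      if (sum(row) == 0) break
      cur <- sample(codes, 1L, prob = row)
      seq_codes <- c(seq_codes, cur)
    }
    chains[[i]] <- accident_chain(as.integer(seq_codes), paste0("sim", i))
  }
  structure(list(chains = chains, excluded_count = 0L),
            class = "chain_corpus")
}

#' Empirical transition frequencies of a corpus
#'
#' Conditional next-hazard relative frequencies: row `i`, column `j` is the
#' fraction of observed transitions out of hazard `i` that went to `j`.
#' Rows for hazards with no outgoing transitions are all zero.
#'
#' @param corpus a `chain_corpus` or list of chains (non-empty).
#' @return row-normalized numeric matrix with hazard codes as dimnames.
#' @export
empirical_transitions <- function(corpus) {
  chains <- if (inherits(corpus, "chain_corpus")) corpus$chains else corpus
  if (length(chains) == 0L) stop("empty corpus", call. = FALSE)
  net <- build_network(filter_valid(chains))
  W <- net$W
  rs <- rowSums(W)
  P <- W / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  P
}
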