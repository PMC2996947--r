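#' Richness: hypergeometric over-representation p-value
#'
#' The probability, under sampling without replacement, of seeing `Q` or more
#' nodes that are both predicted and observed to change, given `N` total
#' measurements, `M` total observed changes and `P` predictions. Richness does
#' not depend on direction agreement, so ambiguous predictions are included in
#' `P` and `Q`. Returns 1 when `Q = 0`.
#'
#' @param Q predicted-and-observed-changed count.
#' @param N total measurements (universe size).
#' @param M total observed changes.
#' @param P predictions over measured nodes.
#' @return upper-tail probability `Pr[X >= Q]`, in (0, 1]. Vectorised.
#' @export
richness_p <- function(Q, N, M, P) {
  n <- max(length(Q), length(N), length(M), length(P))
  Q <- rep_len(as.numeric(Q), n); N <- rep_len(as.numeric(N), n)
  M <- rep_len(as.numeric(M), n); P <- rep_len(as.numeric(P), n)
  if (any(Q < 0 | M < 0 | P < 0 | N < 1)) stop("counts must be non-negative, N >= 1")
  if (any(M > N | P > N)) stop("M and P cannot exceed N")
  if (any(Q > pmin(M, P))) stop("Q cannot exceed min(M, P)")
  p <- stats::phyper(Q - 1, M, N - M, P, lower.tail = FALSE)
  p[Q == 0] <- 1
  p
}

#' Concordance: binomial directional-agreement p-value
#'
#' Of the unambiguous predictions over observed changes, `K` support an
#' increased root and `J` a decreased root. Concordance is the probability of
#' making `H = max(J, K)` or more correct predictions out of `J + K` total
#' when each has null success probability 0.5. Returns 1 when `J + K = 0`.
#'
#' @param J state changes supporting a decreased root.
#' @param K state changes supporting an increased root.
#' @return upper-tail probability `Pr[X >= H]`, in (0, 1]. Vectorised.
#' @export
concordance_p <- function(J, K) {
  n <- max(length(J), length(K))
  J <- rep_len(as.numeric(J), n); K <- rep_len(as.numeric(K), n)
  if (any(J < 0 | K < 0)) stop("counts must be non-negative")
  tot <- J + K
  H <- pmax(J, K)
  p <- stats::pbinom(H - 1, tot, 0.5, lower.tail = FALSE)
  p[tot == 0] <- 1
  p
}

#' Select the supported root direction
#'
#' The direction of a hypothesis root is the one yielding the higher number of
#' successful predictions: `increase` when `K > J`, `decrease` when `J > K`.
#' Ties report `increase` with the `tie` flag set, so tied hypotheses remain
#' inspectable rather than being silently dropped.
#'
#' @param J,K supporting counts as in [concordance_p()].
#' @return data.frame with columns `direction`, `tie`. Vectorised.
#' @export
select_direction <- function(J, K) {
  n <- max(length(J), length(K))
  J <- rep_len(as.numeric(J), n); K <- rep_len(as.numeric(K), n)
  data.frame(direction = ifelse(K >= J, "increase", "decrease"),
             tie = J == K, stringsAsFactors = FALSE)
}

#' Classify hypothesis significance
#'
#' A hypothesis is `significant` when both Richness and Concordance p-values
#' are at or below `significant_cutoff` (default 0.05), `marginal` when both
#' are at or below `marginal_cutoff` (default 0.1), otherwise
#' `not_significant`.
#'
#' @param richness_p,concordance_p probabilities in (0, 1].
#' @param significant_cutoff,marginal_cutoff tier cutoffs.
#' @return character vector of tiers. Vectorised.
#' @export
classify_tier <- function(richness_p, concordance_p,
                          significant_cutoff = 0.05, marginal_cutoff = 0.1) {
  stopifnot(significant_cutoff <= marginal_cutoff)
  ifelse(richness_p <= significant_cutoff & concordance_p <= significant_cutoff,
         "significant",
         ifelse(richness_p <= marginal_cutoff & concordance_p <= marginal_cutoff,
                "marginal", "not_significant"))
}

## Shared counting core. universe_keys: character keys of measured nodes;
## changed_dir: named character vector key -> "increase"/"decrease".
## dn: data.frame from downstream_neighborhood.
.hyp_counts <- function(dn, universe_keys, changed_dir) {
  N <- length(universe_keys)
  M <- length(changed_dir)
  if (nrow(dn)) {
    dk <- node_key(dn$entity, dn$aspect)
    meas <- dk %in% universe_keys
    dn <- dn[meas, , drop = FALSE]
    dk <- dk[meas]
  } else dk <- character()
  P <- nrow(dn)
  if (P == 0L)
    return(list(predictions = dn, N = N, M = M, P = 0L, Q = 0L, J = 0L, K = 0L))
  polarity <- ifelse(dn$plus & dn$minus, "ambiguous",
                     ifelse(dn$plus, "increase", "decrease"))
  observed <- unname(changed_dir[dk])
  observed[is.na(observed)] <- "no_change"
  chg <- observed != "no_change"
  unamb <- polarity != "ambiguous"
  K <- sum(chg & unamb & polarity == observed)
  J <- sum(chg & unamb & polarity != observed)
  preds <- data.frame(entity = dn$entity, aspect = dn$aspect,
                      polarity = polarity, observed = observed,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(predictions = preds, N = N, M = M, P = P, Q = sum(chg), J = J, K = K)
}

.changed_map <- function(changes, universe_keys) {
  chg <- changes[changes$direction != "no_change", , drop = FALSE]
  ck <- node_key(chg$entity, chg$aspect)
  if (anyDuplicated(ck)) stop("duplicate changed node in state-change set")
  miss <- setdiff(ck, universe_keys)
  if (length(miss))
    stop("changed node(s) outside the measured universe: ",
         paste(utils::head(miss, 5), collapse = ", "))
  stats::setNames(chg$direction, ck)
}

#' Compose a mechanistic hypothesis for one root node
#'
#' The root is assumed `increased`; all causal simple paths of at most `depth`
#' steps are searched, and every measured node reached becomes a prediction
#' with polarity `increase` (+1 sign product), `decrease` (-1), or `ambiguous`
#' (reachable both ways). The prediction set is compared against the observed
#' state changes, yielding the counts that feed Richness and Concordance:
#' `N` measurements, `M` observed changes, `P` predictions, `Q` predicted and
#' observed changed (ambiguous included), `K` unambiguous matches (supporting
#' an increased root), `J` unambiguous mismatches (supporting a decreased
#' root). Ambiguous predictions never contribute to `J` or `K`.
#'
#' @param kam a [kam] object.
#' @param root_entity,root_aspect the hypothesis root node.
#' @param universe data.frame of measured nodes (`entity`, `aspect`).
#' @param changes a `state_change_set`; changed nodes must lie in the
#'   universe.
#' @param depth causal search depth (default 2).
#' @return list of class `rca_hypothesis`: `root_entity`, `root_aspect`,
#'   `predictions` (data.frame `entity`, `aspect`, `polarity`, `observed`),
#'   and counts `N`, `M`, `P`, `Q`, `J`, `K`.
#' @export
compose_hypothesis <- function(kam, root_entity, root_aspect, universe,
                               changes, depth = 2) {
  stopifnot(inherits(kam, "kam"), is.data.frame(universe))
  if (nrow(universe) == 0L) stop("measured universe is empty")
  uk <- unique(node_key(universe$entity, universe$aspect))
  cd <- .changed_map(changes, uk)
  dn <- downstream_neighborhood(kam, root_entity, root_aspect, depth)
  cnt <- .hyp_counts(dn, uk, cd)
  structure(c(list(root_entity = root_entity, root_aspect = root_aspect),
              cnt), class = "rca_hypothesis")
}

#' @export
print.rca_hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis> %s.%s: N=%d M=%d P=%d Q=%d J=%d K=%d\n",
              x$root_entity, x$root_aspect, x$N, x$M, x$P, x$Q, x$J, x$K))
  invisible(x)
}

#' Evaluate every graph node as a hypothesis
#'
#' Runs [compose_hypothesis()] for every node of the graph, scores each with
#' [richness_p()] and [concordance_p()], selects the supported direction and
#' significance tier, and ranks the result deterministically by
#' (tier, concordance ascending, richness ascending, `Q` descending, root id).
#' Nodes with no prediction in the universe are omitted. Measured entities
#' absent from the graph still count toward `N` (they are measurements); set
#' `restrict_to_kam = TRUE` to drop them from the universe instead.
#'
#' @param kam a [kam] object.
#' @param universe data.frame of measured nodes (`entity`, `aspect`).
#' @param changes a `state_change_set`.
#' @param depth causal search depth (default 2).
#' @param significant_cutoff,marginal_cutoff tier cutoffs (defaults 0.05/0.1).
#' @param adjust_across `"none"` (default: raw cutoffs, as the method
#'   defines) or `"BH"` to tier on BH-adjusted p-values across hypotheses.
#' @param restrict_to_kam drop measured nodes that are not graph nodes from
#'   the universe before counting (default `FALSE`).
#' @return data.frame of class `rca_hypotheses`, one ranked row per
#'   hypothesis: `root_entity`, `root_aspect`, `direction`, `tie`, `N`, `M`,
#'   `P`, `Q`, `J`, `K`, `richness_p`, `concordance_p`, `tier`.
#' @export
evaluate_all <- function(kam, universe, changes, depth = 2,
                         significant_cutoff = 0.05, marginal_cutoff = 0.1,
                         adjust_across = c("none", "BH"),
                         restrict_to_kam = FALSE) {
  stopifnot(inherits(kam, "kam"), is.data.frame(universe))
  adjust_across <- match.arg(adjust_across)
  uk <- unique(node_key(universe$entity, universe$aspect))
  if (restrict_to_kam)
    uk <- intersect(uk, node_key(kam$nodes$entity, kam$nodes$aspect))
  if (length(uk) == 0L) stop("measured universe is empty")
  cd <- .changed_map(changes, uk)
  index <- .kam_index(kam)
  nn <- nrow(kam$nodes)
  rows <- vector("list", nn)
  for (i in seq_len(nn)) {
    res <- .dn_search(index, i, depth)
    hit <- which(res$plus | res$minus)
    if (!length(hit)) next
    dn <- data.frame(entity = kam$nodes$entity[hit],
                     aspect = kam$nodes$aspect[hit],
                     plus = res$plus[hit], minus = res$minus[hit],
                     stringsAsFactors = FALSE)
    cnt <- .hyp_counts(dn, uk, cd)
    if (cnt$P == 0L) next
    rows[[i]] <- data.frame(root_entity = kam$nodes$entity[i],
                            root_aspect = kam$nodes$aspect[i],
                            N = cnt$N, M = cnt$M, P = cnt$P, Q = cnt$Q,
                            J = cnt$J, K = cnt$K, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(root_entity = character(), root_aspect = character(),
                      direction = character(), tie = logical(),
                      N = integer(), M = integer(), P = integer(),
                      Q = integer(), J = integer(), K = integer(),
                      richness_p = numeric(), concordance_p = numeric(),
                      tier = character(), stringsAsFactors = FALSE)
    class(out) <- c("rca_hypotheses", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$richness_p <- richness_p(out$Q, out$N, out$M, out$P)
  out$concordance_p <- concordance_p(out$J, out$K)
  dir <- select_direction(out$J, out$K)
  out$direction <- dir$direction
  out$tie <- dir$tie
  rp <- out$richness_p
  cp <- out$concordance_p
  if (adjust_across == "BH") {
    rp <- bh_adjust(rp)
    cp <- bh_adjust(cp)
  }
  out$tier <- classify_tier(rp, cp, significant_cutoff, marginal_cutoff)
  tier_rank <- match(out$tier, c("significant", "marginal", "not_significant"))
  o <- order(tier_rank, out$concordance_p, out$richness_p, -out$Q,
             out$root_entity, out$root_aspect)
  out <- out[o, c("root_entity", "root_aspect", "direction", "tie",
                  "N", "M", "P", "Q", "J", "K",
                  "richness_p", "concordance_p", "tier")]
  rownames(out) <- NULL
  class(out) <- c("rca_hypotheses", "data.frame")
  out
}

#' Per-hypothesis prediction detail table
#'
#' One row per measured prediction of the hypothesis, with its polarity, the
#' observed call, and a `flag` column marking inconsistent rows (unambiguous
#' prediction contradicted by an observed change) with `"X"`.
#'
#' @inheritParams compose_hypothesis
#' @return data.frame `entity`, `aspect`, `polarity`, `observed`,
#'   `consistent` (logical, `NA` when not applicable), `flag`.
#' @export
prediction_detail <- function(kam, root_entity, root_aspect, universe,
                              changes, depth = 2) {
  h <- compose_hypothesis(kam, root_entity, root_aspect, universe, changes, depth)
  p <- h$predictions
  if (!nrow(p)) {
    p$consistent <- logical()
    p$flag <- character()
    return(p)
  }
  applicable <- p$polarity != "ambiguous" & p$observed != "no_change"
  p$consistent <- ifelse(applicable, p$polarity == p$observed, NA)
  p$flag <- ifelse(applicable & !as.logical(p$consistent), "X", "")
  p[order(p$entity, p$aspect), , drop = FALSE]
}

#' Write a ranked hypothesis report as TSV
#'
#' Columns
#' `root_entity root_aspect direction tie N M P Q J K richness_p concordance_p tier`,
#' in the ranking produced by [evaluate_all()].
#'
#' @param hypotheses `rca_hypotheses` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hypothesis_report <- function(hypotheses, path) {
  utils::write.table(as.data.frame(hypotheses), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
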